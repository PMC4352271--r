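#' Left-align INDEL records against the reference
#'
#' Shifts each pure INDEL to the leftmost anchored representation that
#' yields the identical alternate haplotype (the parsimonious VCF
#' normalization). The operation is idempotent, and callers merged on
#' [indel_key()] therefore agree on a single canonical representation.
#'
#' An event can be shifted one base left whenever the anchor base equals
#' the last base of the inserted/deleted sequence; the sequence is then
#' rotated by that base. Shifting stops at the chromosome start, after
#' `max_shift` steps, or when the anchor base is `N` (ambiguity is treated
#' conservatively and the record is left where it is).
#'
#' @param records An [indel_records()] tibble.
#' @param ref_seqs Reference as returned by [load_reference()].
#' @param max_shift Maximum number of 1 bp shifts per record (default 300,
#'   far beyond the <100 bp allele limit).
#' @return The records tibble with `pos`, `ref`, `alt`, `seq` rewritten;
#'   row order and all other columns preserved.
#' @export
left_align <- function(records, ref_seqs, max_shift = 300L) {
  n <- nrow(records)
  if (n == 0L) return(records)
  pos <- records$pos
  seqs <- records$seq
  lens <- records$length
  for (i in seq_len(n)) {
    chrseq <- ref_seqs[[records$chrom[i]]]
    if (is.null(chrseq)) stop("chromosome absent from reference: ", records$chrom[i])
    p <- pos[i]
    s <- seqs[i]
    L <- nchar(s)
    check_record_ref(chrseq, p, records$ref[i], records$chrom[i])
    shifts <- 0L
    while (p > 1L && shifts < max_shift) {
      anchor <- substr(chrseq, p, p)
      if (anchor == "N" || anchor != substr(s, L, L)) break
      s <- paste0(anchor, substr(s, 1L, L - 1L))
      p <- p - 1L
      shifts <- shifts + 1L
    }
    pos[i] <- p
    seqs[i] <- s
  }
  anchor <- substr(mapply(function(ch, p) substr(ref_seqs[[ch]], p, p),
                          records$chrom, pos, USE.NAMES = FALSE), 1L, 1L)
  records$pos <- pos
  records$seq <- seqs
  records$ref <- ifelse(lens > 0L, anchor, paste0(anchor, seqs))
  records$alt <- ifelse(lens > 0L, paste0(anchor, seqs), anchor)
  records
}

check_record_ref <- function(chrseq, pos, ref_allele, chrom) {
  obs <- substr(chrseq, pos, pos + nchar(ref_allele) - 1L)
  if (obs != ref_allele) {
    stop(sprintf("reference mismatch at %s:%d (expected %s, reference has %s)",
                 chrom, pos, ref_allele, obs))
  }
  invisible(TRUE)
}

# Rightmost equivalent representation; used by the simulator to emit
# deliberately shifted encodings that exercise left_align.
right_shift <- function(records, ref_seqs, max_shift = 300L) {
  n <- nrow(records)
  if (n == 0L) return(records)
  pos <- records$pos
  seqs <- records$seq
  lens <- records$length
  for (i in seq_len(n)) {
    chrseq <- ref_seqs[[records$chrom[i]]]
    p <- pos[i]
    s <- seqs[i]
    L <- nchar(s)
    del <- lens[i] < 0L
    shifts <- 0L
    repeat {
      nxt_pos <- p + 1L + (if (del) L else 0L)
      nxt <- substr(chrseq, nxt_pos, nxt_pos)
      if (shifts >= max_shift || nxt == "" || nxt == "N" ||
            nxt != substr(s, 1L, 1L)) break
      s <- paste0(substr(s, 2L, L), nxt)
      p <- p + 1L
      shifts <- shifts + 1L
    }
    pos[i] <- p
    seqs[i] <- s
  }
  anchor <- mapply(function(ch, p) substr(ref_seqs[[ch]], p, p),
                   records$chrom, pos, USE.NAMES = FALSE)
  records$pos <- pos
  records$seq <- seqs
  records$ref <- ifelse(lens > 0L, anchor, paste0(anchor, seqs))
  records$alt <- ifelse(lens > 0L, paste0(anchor, seqs), anchor)
  records
}

#' Split a complex variant into primitive components
#'
#' Decomposes a REF/ALT pair of arbitrary lengths into SNP components and
#' at most one pure-INDEL component by end-anchored trimming: bases equal
#' at both ends are trimmed away, the remaining cores are aligned from
#' their left edge (mismatching aligned bases become SNPs) and the length
#' difference becomes a single insertion or deletion. Applied jointly, the
#' components reconstruct the original alternate haplotype. Downstream
#' stages keep only the INDEL component; the pipeline is INDEL-only and
#' discards co-occurring SNP components.
#'
#' @param chrom Chromosome name.
#' @param pos 1-based position of the first base of `ref`.
#' @param ref,alt Allele strings (any lengths >= 1).
#' @return A tibble with columns `type` (`"SNP"`, `"INS"`, `"DEL"`),
#'   `chrom`, `pos`, `ref`, `alt`. SNP rows use the mismatching base pair;
#'   INDEL rows use the anchored VCF representation. A pure SNP input
#'   yields only SNP rows; identical alleles yield zero rows.
#' @examples
#' split_complex("chr1", 5L, "CTTG", "CAG")  # one SNP + one 1 bp deletion
#' @export
split_complex <- function(chrom, pos, ref, alt) {
  ref <- toupper(ref)
  alt <- toupper(alt)
  stopifnot(nzchar(ref), nzchar(alt))
  empty <- tibble::tibble(type = character(), chrom = character(),
                          pos = integer(), ref = character(), alt = character())
  if (ref == alt) return(empty)
  # trim common suffix (keep at least one base on each side)
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
           substr(ref, nchar(ref), nchar(ref)) == substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1L, nchar(ref) - 1L)
    alt <- substr(alt, 1L, nchar(alt) - 1L)
  }
  # trim common prefix, tracking the anchor just left of the cores
  off <- 0L
  while (off < min(nchar(ref), nchar(alt)) &&
           substr(ref, off + 1L, off + 1L) == substr(alt, off + 1L, off + 1L)) {
    off <- off + 1L
  }
  r <- substr(ref, off + 1L, nchar(ref))
  a <- substr(alt, off + 1L, nchar(alt))
  core_pos <- pos + off
  out <- empty
  nr <- nchar(r)
  na <- nchar(a)
  m <- min(nr, na)
  if (m > 0L) {
    rb <- strsplit(substr(r, 1L, m), "", fixed = TRUE)[[1]]
    ab <- strsplit(substr(a, 1L, m), "", fixed = TRUE)[[1]]
    mis <- which(rb != ab)
    if (length(mis)) {
      out <- dplyr::bind_rows(out, tibble::tibble(
        type = "SNP", chrom = chrom, pos = core_pos + mis - 1L,
        ref = rb[mis], alt = ab[mis]
      ))
    }
  }
  if (nr != na) {
    # the anchored base precedes the indel tail; it is the last aligned
    # reference base, or the trimmed prefix base when a core is empty
    anchor_pos <- core_pos + m - 1L
    anchor <- if (m > 0L) substr(r, m, m) else substr(ref, off, off)
    if (anchor_pos < pos) stop("cannot anchor an indel before the variant start")
    if (nr > na) {
      tail <- substr(r, m + 1L, nr)
      out <- dplyr::bind_rows(out, tibble::tibble(
        type = "DEL", chrom = chrom, pos = anchor_pos,
        ref = paste0(anchor, tail), alt = anchor
      ))
    } else {
      tail <- substr(a, m + 1L, na)
      out <- dplyr::bind_rows(out, tibble::tibble(
        type = "INS", chrom = chrom, pos = anchor_pos,
        ref = anchor, alt = paste0(anchor, tail)
      ))
    }
  }
  out
}
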