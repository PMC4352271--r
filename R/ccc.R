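#' Smallest repeat motif of an allele sequence
#'
#' Returns the shortest prefix `m` of `seq` such that `seq` is `m`
#' repeated an integer number of times; `seq` itself when no proper
#' tiling exists (a primitive sequence).
#'
#' @param seq Character vector of sequences over \{A,C,G,T\}.
#' @return Character vector of motifs.
#' @examples
#' smallest_motif(c("AGAG", "AAA", "AGC"))  # "AG" "A" "AGC"
#' @export
smallest_motif <- function(seq) {
  seq <- toupper(seq)
  if (any(!nzchar(seq)) || any(grepl("[^ACGT]", seq))) {
    stop("sequences must be non-empty over {A,C,G,T}")
  }
  vapply(seq, function(s) {
    L <- nchar(s)
    for (m in seq_len(L)) {
      if (L %% m != 0L) next
      unit <- substr(s, 1L, m)
      if (paste(rep(unit, L %/% m), collapse = "") == s) return(unit)
    }
    s
  }, character(1), USE.NAMES = FALSE)
}

#' Classify INDELs as change-in-copy-count (CCC) or not (NCCC)
#'
#' An INDEL is CCC -- the polymerase-slippage signature -- when the
#' smallest repeat motif of its allele sequence is an expansion or a
#' contraction of the adjacent reference bases: the `nchar(motif)` bases
#' immediately left of the event, or immediately right of it, equal the
#' motif. For a deletion this means at least one copy of the motif remains
#' adjacent after the contraction. Both sides are inspected so the verdict
#' does not depend on which equivalent representation was supplied; it is
#' invariant under left alignment.
#'
#' Allele sequences that are not an integer number of motif copies use the
#' whole sequence as motif (copy count 1 to 2, or 2 to 1). Any `N` in the
#' inspected context yields NCCC with the `ccc_ambiguous` flag set.
#'
#' @param records Left-aligned [indel_records()] tibble.
#' @param ref_seqs Reference as from [load_reference()].
#' @return The records tibble with columns `motif`, `ccc` (logical) and
#'   `ccc_ambiguous` (logical) appended.
#' @export
classify_ccc <- function(records, ref_seqs) {
  n <- nrow(records)
  motif <- smallest_motif(records$seq)
  lm <- nchar(motif)
  L <- abs(records$length)
  is_del <- records$length < 0L
  left <- character(n)
  right <- character(n)
  for (ch in unique(records$chrom)) {
    idx <- which(records$chrom == ch)
    chrseq <- ref_seqs[[ch]]
    if (is.null(chrseq)) stop("chromosome absent from reference: ", ch)
    p <- records$pos[idx]
    # event occupies (p, p+1) for insertions, bases p+1..p+L for deletions
    left[idx] <- substr(rep(chrseq, length(idx)), p - lm[idx] + 1L, p)
    rs <- p + 1L + ifelse(is_del[idx], L[idx], 0L)
    right[idx] <- substr(rep(chrseq, length(idx)), rs, rs + lm[idx] - 1L)
  }
  ambiguous <- grepl("N", left, fixed = TRUE) | grepl("N", right, fixed = TRUE)
  ccc <- !ambiguous &
    ((nchar(left) == lm & left == motif) | (nchar(right) == lm & right == motif))
  records$motif <- motif
  records$ccc <- ccc
  records$ccc_ambiguous <- ambiguous
  records
}

#' Population- and individual-level CCC composition
#'
#' Splits a call set four ways -- CCC insertions, NCCC insertions, CCC
#' deletions, NCCC deletions -- as percentages of loci (population level),
#' and repeats the same split over each individual's non-reference loci,
#' averaging the per-individual percentages.
#'
#' @param gm A [genotype_matrix()] whose loci have been classified with
#'   [classify_ccc()] (or will be, when `ref_seqs` is given).
#' @param ref_seqs Reference; required unless `gm$loci` already carries a
#'   `ccc` column.
#' @return A list with `population` and `individual`, each a named numeric
#'   vector of percentages (`ccc_ins`, `nccc_ins`, `ccc_del`, `nccc_del`)
#'   summing to 100, plus `n_loci` and `n_samples`.
#' @export
ccc_profile <- function(gm, ref_seqs = NULL) {
  loci <- gm$loci
  if (nrow(loci) == 0L) stop("empty call set")
  if (is.null(loci$ccc)) {
    if (is.null(ref_seqs)) stop("loci lack a ccc column; supply ref_seqs")
    loci <- classify_ccc(loci, ref_seqs)
  }
  cls <- ccc_class(loci)
  pop <- 100 * prop.table(table(factor(cls, levels = CCC_CLASSES)))
  carried <- !is.na(gm$gt) & gm$gt > 0L
  per_ind <- apply(carried, 2L, function(cw) {
    if (!any(cw)) return(rep(NA_real_, 4L))
    100 * prop.table(table(factor(cls[cw], levels = CCC_CLASSES)))
  })
  ind <- rowMeans(per_ind, na.rm = TRUE)
  list(
    population = stats::setNames(as.numeric(pop), CCC_CLASSES),
    individual = stats::setNames(as.numeric(ind), CCC_CLASSES),
    n_loci = nrow(loci), n_samples = ncol(gm$gt)
  )
}

CCC_CLASSES <- c("ccc_ins", "nccc_ins", "ccc_del", "nccc_del")

ccc_class <- function(loci) {
  paste0(ifelse(loci$ccc, "ccc_", "nccc_"),
         ifelse(loci$length > 0L, "ins", "del"))
}

#' Random length-matched INDEL call set (null control)
#'
#' Draws `n` signed lengths i.i.d. from an empirical length histogram and
#' places each event uniformly at random within the target regions; this
#' is the null model for what CCC fractions arise by chance for a call set
#' with a given length distribution. Deletions take their allele sequence
#' from the reference; insertion sequences are i.i.d. uniform over
#' \{A,C,G,T\} (a clean analytic null: 1 bp insertions on an i.i.d.
#' uniform reference are CCC with probability 7/16).
#'
#' @param length_distribution A table or named numeric vector: names are
#'   signed lengths (no zero), values are weights.
#' @param targets A [GenomicRanges::GRanges] of target intervals.
#' @param ref_seqs Reference sequences.
#' @param n Number of events to draw.
#' @param seed Integer seed (mandatory; the draw is reproducible).
#' @return An [indel_records()] tibble of left-aligned simulated events.
#' @export
simulate_random_indels <- function(length_distribution, targets, ref_seqs, n, seed) {
  lens <- as.integer(names(length_distribution))
  w <- as.numeric(length_distribution)
  stopifnot(length(lens) > 0L, all(lens != 0L), all(w >= 0), n >= 0L)
  if (n == 0L) {
    return(indel_records(character(), integer(), character(), character()))
  }
  withr::local_seed(seed)
  drawn <- sample(lens, n, replace = TRUE, prob = w)
  placed <- place_events(drawn, targets, ref_seqs)
  left_align(placed, ref_seqs)
}

# Uniform placement of signed lengths into targets; a deletion whose run
# would extend past its interval (or hit an N) is resampled.
place_events <- function(lens, targets, ref_seqs) {
  starts <- GenomicRanges::start(targets)
  ends <- GenomicRanges::end(targets)
  chroms <- as.character(GenomicRanges::seqnames(targets))
  widths <- ends - starts + 1L
  n <- length(lens)
  chrom <- character(n)
  pos <- integer(n)
  seq <- character(n)
  for (i in seq_len(n)) {
    L <- lens[i]
    repeat {
      iv <- sample.int(length(widths), 1L, prob = widths)
      p <- starts[iv] + sample.int(widths[iv], 1L) - 1L
      if (L < 0L) {
        if (p - L > ends[iv]) next  # deletion extends past the interval
        s <- ref_window(ref_seqs, chroms[iv], p + 1L, p - L)
        if (nchar(s) < -L || grepl("N", s, fixed = TRUE)) next
      } else {
        s <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
      }
      if (substr(ref_seqs[[chroms[iv]]], p, p) == "N") next
      chrom[i] <- chroms[iv]
      pos[i] <- p
      seq[i] <- s
      break
    }
  }
  anchor <- mapply(function(ch, p) substr(ref_seqs[[ch]], p, p), chrom, pos,
                   USE.NAMES = FALSE)
  ins <- lens > 0L
  indel_records(chrom, pos,
                ref = ifelse(ins, anchor, paste0(anchor, seq)),
                alt = ifelse(ins, paste0(anchor, seq), anchor))
}
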