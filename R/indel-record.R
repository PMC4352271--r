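#' Construct a table of normalized INDEL records
#'
#' The package represents an INDEL allele the way a VCF line does: a 1-based
#' anchor position whose reference base precedes the inserted or deleted
#' sequence, with the anchor base included in both alleles. Exactly one of
#' `ref`/`alt` has length 1 at this layer (pure INDELs only; complex events
#' must first pass through [split_complex()]).
#'
#' @param chrom Character vector of chromosome names.
#' @param pos Integer vector, 1-based anchor positions.
#' @param ref Character vector of reference alleles (anchor base included).
#' @param alt Character vector of alternate alleles (anchor base included).
#' @param qual Optional numeric caller-reported quality scores.
#' @param caller Optional character caller identifiers.
#'
#' @return A tibble with one row per allele and columns `chrom`, `pos`,
#'   `ref`, `alt`, `length` (signed: insertions positive, deletions
#'   negative), `seq` (the inserted/deleted bases without the anchor),
#'   `qual` and `caller`.
#'
#' @details Alleles with `|length| >= 100` are rejected: the analysis is
#'   restricted to short INDELs, with structural variants out of scope.
#'
#' @examples
#' indel_records("chr1", 10L, "A", "AT")    # 1 bp insertion of "T"
#' indel_records("chr1", 10L, "ACA", "A")   # 2 bp deletion of "CA"
#' @export
indel_records <- function(chrom, pos, ref, alt, qual = NA_real_, caller = NA_character_) {
  ref <- toupper(ref)
  alt <- toupper(alt)
  n <- length(pos)
  stopifnot(length(chrom) %in% c(1L, n), length(ref) == n, length(alt) == n)
  len <- signed_length(ref, alt)
  nr <- nchar(ref)
  na <- nchar(alt)
  if (any(pmin(nr, na) != 1L)) {
    stop("not a pure INDEL: exactly one of ref/alt must be the single anchor base")
  }
  if (any(abs(len) >= 100L)) {
    stop("allele length must be below 100 bp (short INDELs only)")
  }
  if (any(substr(ref, 1L, 1L) != substr(alt, 1L, 1L))) {
    stop("ref and alt must share the anchor base")
  }
  seq <- as.character(ifelse(len > 0L, substr(alt, 2L, na), substr(ref, 2L, nr)))
  tibble::tibble(
    chrom = as.character(chrom), pos = as.integer(pos),
    ref = ref, alt = alt,
    length = len, seq = seq,
    qual = as.numeric(qual), caller = as.character(caller)
  )
}

#' Signed length of an INDEL allele pair
#'
#' Insertions are positive, deletions negative (so a 3 bp deletion has
#' length -3). Equal-length allele pairs are not INDELs and raise an error.
#'
#' @param ref,alt Character vectors of REF/ALT allele strings over
#'   \{A,C,G,T,N\}.
#' @return Integer vector `nchar(alt) - nchar(ref)`.
#' @examples
#' signed_length("A", "AT")    #  1
#' signed_length("ACAG", "A")  # -3
#' @export
signed_length <- function(ref, alt) {
  if (any(!nzchar(ref)) || any(!nzchar(alt))) stop("empty allele string")
  bad <- grepl("[^ACGTNacgtn]", ref) | grepl("[^ACGTNacgtn]", alt)
  if (any(bad)) stop("allele strings must be over {A,C,G,T,N}")
  len <- nchar(alt) - nchar(ref)
  if (any(len == 0L)) stop("equal-length alleles are not an INDEL")
  as.integer(len)
}

#' Is an INDEL length frameshift?
#'
#' A coding INDEL shifts the reading frame unless its length is a multiple
#' of three bases.
#'
#' @param length Integer vector of signed (or absolute) INDEL lengths;
#'   zero is invalid.
#' @return Logical vector, `TRUE` for frameshift lengths.
#' @examples
#' is_frameshift(c(1, 3, -84))  # TRUE FALSE FALSE
#' @export
is_frameshift <- function(length) {
  if (any(length == 0L)) stop("length must be non-zero")
  abs(length) %% 3L != 0L
}

#' Matching key for a normalized INDEL allele
#'
#' Two records from different callers denote the same allele iff their keys
#' are equal after left alignment. Keys are only meaningful for left-aligned
#' records; pass the reference to have this checked.
#'
#' @param records An [indel_records()] tibble.
#' @param ref_seqs Optional reference (named character vector of chromosome
#'   sequences); when supplied, non-left-aligned records raise an error.
#' @return Character vector `"chrom:pos:ref:alt"`.
#' @export
indel_key <- function(records, ref_seqs = NULL) {
  if (!is.null(ref_seqs)) {
    shifted <- left_align(records, ref_seqs)
    if (!all(shifted$pos == records$pos & shifted$ref == records$ref &
               shifted$alt == records$alt)) {
      stop("records are not left-aligned; normalize with left_align() first")
    }
  }
  paste(records$chrom, records$pos, records$ref, records$alt, sep = ":")
}

AUTOSOME_RE <- "^(chr)?([1-9]|1[0-9]|2[0-2])$"

#' Test whether chromosome names are autosomal
#'
#' All pipeline outputs are restricted to autosomes; sex chromosomes,
#' mitochondria and unplaced contigs are dropped at the union-merge stage.
#'
#' @param chrom Character vector of chromosome names (with or without a
#'   `chr` prefix).
#' @return Logical vector.
#' @export
is_autosome <- function(chrom) {
  grepl(AUTOSOME_RE, chrom)
}
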