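#' Load a reference genome as in-memory chromosome strings
#'
#' Reads a FASTA file with [Biostrings::readDNAStringSet()] and returns a
#' named character vector, one uppercase string per chromosome. All
#' window-based operations in the package (left alignment, repeat context,
#' covariates) take this representation.
#'
#' @param fasta Path to a FASTA file.
#' @return Named character vector of chromosome sequences.
#' @export
load_reference <- function(fasta) {
  ss <- Biostrings::readDNAStringSet(fasta)
  seqs <- toupper(as.character(ss))
  # FASTA headers may carry descriptions after the first token
  names(seqs) <- sub("\\s.*$", "", names(ss))
  seqs
}

ref_window <- function(ref_seqs, chrom, start, end) {
  s <- ref_seqs[[chrom]]
  start <- max(1L, start)
  end <- min(nchar(s), end)
  if (start > end) return("")
  substr(s, start, end)
}

#' Apply a variant to a reference sequence
#'
#' Replaces the reference allele at `pos` with the alternate allele and
#' returns the resulting haplotype string. Used as the ground-truth oracle
#' for normalization: two representations are equivalent iff they produce
#' the identical alternate sequence.
#'
#' @param seq Reference sequence (single character string).
#' @param pos 1-based position of the first base of `ref` within `seq`.
#' @param ref,alt Allele strings.
#' @return The alternate haplotype as a character string.
#' @export
apply_variant <- function(seq, pos, ref, alt) {
  if (substr(seq, pos, pos + nchar(ref) - 1L) != ref) {
    stop("reference allele does not match the sequence at pos ", pos)
  }
  paste0(substr(seq, 1L, pos - 1L), alt, substr(seq, pos + nchar(ref), nchar(seq)))
}
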