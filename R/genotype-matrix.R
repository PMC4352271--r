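#' Genotype matrix: loci x samples genotypes with read evidence
#'
#' The package's container for a multi-sample call set: a loci table (an
#' [indel_records()] tibble, one row per INDEL allele) together with three
#' loci-by-samples matrices -- `gt` (alternate allele count per diploid
#' genotype: 0, 1, 2 or `NA` for missing), `dp` (total reads) and `vr`
#' (reads supporting the alternate allele).
#'
#' @param loci An [indel_records()] tibble.
#' @param samples Character vector of sample identifiers.
#' @param gt,dp,vr Matrices of dimension `nrow(loci)` x `length(samples)`;
#'   `dp`/`vr` may be `NULL` when read evidence is unavailable.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(loci, samples, gt, dp = NULL, vr = NULL) {
  stopifnot(is.matrix(gt), nrow(gt) == nrow(loci), ncol(gt) == length(samples))
  if (!is.null(dp)) stopifnot(all(dim(dp) == dim(gt)))
  if (!is.null(vr)) {
    stopifnot(all(dim(vr) == dim(gt)))
    both <- !is.na(vr) & !is.na(dp)
    if (any(vr[both] > dp[both])) stop("variant_reads exceed depth")
  }
  dimnames(gt) <- list(NULL, samples)
  structure(list(loci = loci, samples = samples, gt = gt, dp = dp, vr = vr),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d loci x %d samples\n",
              nrow(x$loci), length(x$samples)))
  cat(sprintf("  insertions: %d  deletions: %d  evidence: %s\n",
              sum(x$loci$length > 0), sum(x$loci$length < 0),
              if (is.null(x$dp)) "absent" else "DP/AD present"))
  invisible(x)
}

#' Subset a genotype matrix by locus
#'
#' @param gm A [genotype_matrix()].
#' @param i Integer or logical index over loci.
#' @return A `genotype_matrix` with the selected loci.
#' @export
subset_loci <- function(gm, i) {
  genotype_matrix(gm$loci[i, , drop = FALSE], gm$samples,
                  gm$gt[i, , drop = FALSE],
                  if (!is.null(gm$dp)) gm$dp[i, , drop = FALSE],
                  if (!is.null(gm$vr)) gm$vr[i, , drop = FALSE])
}

# per-sample count of carried (non-reference, non-missing) loci
carrier_matrix <- function(gm) !is.na(gm$gt) & gm$gt > 0L
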