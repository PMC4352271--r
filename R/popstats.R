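#' Alternate allele frequency per locus
#'
#' AAF = alternate allele count / (2 x called samples); samples with a
#' missing genotype are excluded from the denominator. The minor allele
#' frequency is `pmin(aaf, 1 - aaf)`.
#'
#' @param gm A [genotype_matrix()].
#' @return A tibble with `key`, `n_called`, `aaf`, `maf`; loci with no
#'   called genotype get `NA` frequencies (and are skipped downstream).
#' @export
alt_allele_frequency <- function(gm) {
  called <- rowSums(!is.na(gm$gt))
  ac <- rowSums(gm$gt, na.rm = TRUE)
  aaf <- ifelse(called > 0L, ac / (2 * called), NA_real_)
  if (any(called == 0L)) {
    message(sum(called == 0L), " locus/loci with all genotypes missing: AAF undefined, skipped")
  }
  tibble::tibble(key = indel_key(gm$loci), n_called = as.integer(called),
                 aaf = aaf, maf = pmin(aaf, 1 - aaf))
}

#' Variant density in variants per megabase
#'
#' Density is the number of called variants divided by the number of
#' base-pairs analyzed, scaled to 1 Mb. Given a vector of per-individual
#' counts, returns per-individual densities (average them for the
#' population summary).
#'
#' @param counts Numeric vector of variant counts (typically one per
#'   individual).
#' @param region_bp Size of the analyzed region in bp (> 0).
#' @return Numeric vector of densities (variants/Mb).
#' @examples
#' variant_density(11, 2e6)  # 5.5
#' @export
variant_density <- function(counts, region_bp) {
  if (any(region_bp <= 0)) stop("region_bp must be positive")
  counts / (region_bp / 1e6)
}

AF_BIN_EDGES <- c(0, 0.001, 0.005, 0.01, 0.05, 0.10, 0.50, 1)

#' Assign allele frequencies to the 7 logarithmic AF bins
#'
#' Bins are left-open, right-closed intervals over (0, 1] with edges
#' 0.1%, 0.5%, 1%, 5%, 10% and 50%; bin 1 is (0, 0.001] and bin 7 is
#' (0.5, 1]. Summing bins reproduces the standard reporting thresholds
#' (rare < 1%, intermediate 1-10%, common >= 10%).
#'
#' @param aaf Numeric vector of frequencies in (0, 1].
#' @param edges Bin edges (8 ascending values spanning 0 to 1).
#' @return Integer bin index 1..7.
#' @examples
#' af_bin(c(0.009, 0.25, 1))  # 3 6 7
#' @export
af_bin <- function(aaf, edges = AF_BIN_EDGES) {
  if (any(is.na(aaf)) || any(aaf <= 0 | aaf > 1)) {
    stop("allele frequencies must lie in (0, 1]")
  }
  idx <- findInterval(aaf, edges, left.open = TRUE, rightmost.closed = TRUE)
  as.integer(idx)
}

#' Mean per-individual density stratified by allele-frequency bin
#'
#' Computes each individual's variant density within every AF bin and
#' averages across individuals; the per-bin densities sum to the
#' unstratified density (the bins partition (0, 1]).
#'
#' @param gm A [genotype_matrix()].
#' @param region_bp Analyzed region size in bp.
#' @param edges AF bin edges (see [af_bin()]).
#' @return A tibble with `bin`, `af_low`, `af_high`, `density` (mean
#'   variants/Mb per individual).
#' @export
density_by_af_bin <- function(gm, region_bp, edges = AF_BIN_EDGES) {
  af <- alt_allele_frequency(gm)
  ok <- !is.na(af$aaf) & af$aaf > 0
  gm2 <- subset_loci(gm, ok)
  bins <- af_bin(af$aaf[ok], edges)
  cw <- carrier_matrix(gm2)
  nb <- length(edges) - 1L
  per_bin <- vapply(seq_len(nb), function(b) {
    mean(variant_density(colSums(cw[bins == b, , drop = FALSE]), region_bp))
  }, numeric(1))
  tibble::tibble(bin = seq_len(nb), af_low = edges[-length(edges)],
                 af_high = edges[-1], density = per_bin)
}

#' Mean per-individual density stratified by signed INDEL length
#'
#' @param gm A [genotype_matrix()].
#' @param region_bp Analyzed region size in bp.
#' @return A tibble with `length` (signed bp) and `density` (mean
#'   variants/Mb per individual).
#' @export
density_by_length <- function(gm, region_bp) {
  cw <- carrier_matrix(gm)
  lens <- sort(unique(gm$loci$length))
  dens <- vapply(lens, function(L) {
    mean(variant_density(colSums(cw[gm$loci$length == L, , drop = FALSE]),
                         region_bp))
  }, numeric(1))
  tibble::tibble(length = lens, density = dens)
}

#' Average percent heterozygous across individuals
#'
#' Per individual, the number of heterozygous calls divided by the total
#' number of called variants (het + hom-alt), as a percentage; averaged
#' over individuals. Individuals with no variant calls are excluded.
#'
#' @param gm A [genotype_matrix()].
#' @return Scalar percentage.
#' @export
percent_heterozygous <- function(gm) {
  het <- colSums(gm$gt == 1L, na.rm = TRUE)
  hom <- colSums(gm$gt == 2L, na.rm = TRUE)
  any_var <- het + hom > 0L
  if (!any(any_var)) stop("no individual carries a variant call")
  mean(100 * het[any_var] / (het + hom)[any_var])
}

#' Compare two MAF distributions with the Wilcoxon rank-sum test
#'
#' Two-sided rank-sum test (normal approximation with tie correction at
#' large n; the exact method at small, tie-free n) of whether two variant
#' classes differ in minor allele frequency.
#'
#' @param maf_a,maf_b Non-empty numeric vectors of frequencies.
#' @return A list with `statistic` (W), `p_value` and the `method` used.
#' @export
compare_maf_distributions <- function(maf_a, maf_b) {
  if (length(maf_a) == 0L || length(maf_b) == 0L) stop("empty MAF vector")
  wt <- stats::wilcox.test(maf_a, maf_b, alternative = "two.sided")
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       method = wt$method)
}

#' Per-individual deletion:insertion ratio
#'
#' For each individual, the number of deletion loci carried divided by the
#' number of insertion loci carried; averaged over individuals.
#' Individuals carrying no insertion are excluded (logged).
#'
#' @param gm A [genotype_matrix()].
#' @return Scalar mean ratio.
#' @export
deletion_insertion_ratio <- function(gm) {
  cw <- carrier_matrix(gm)
  dels <- colSums(cw[gm$loci$length < 0L, , drop = FALSE])
  inss <- colSums(cw[gm$loci$length > 0L, , drop = FALSE])
  ok <- inss > 0L
  if (!any(ok)) stop("no individual carries an insertion")
  if (any(!ok)) {
    message(sum(!ok), " individual(s) with zero insertions excluded from the ratio")
  }
  mean(dels[ok] / inss[ok])
}

#' Frameshift fraction of a set of loci
#'
#' @param records An [indel_records()] tibble (or any tibble with a signed
#'   `length` column).
#' @return Fraction of loci whose length is not a multiple of three.
#' @export
frameshift_rate <- function(records) {
  mean(is_frameshift(records$length))
}
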