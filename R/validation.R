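#' Position/length matching of a candidate against validated INDELs
#'
#' A candidate matches a validated INDEL when both lie on the same
#' chromosome, have the exact same signed length, and their anchor
#' positions differ by at most 30 bp -- tightened to 5 bp for 1 bp INDELs,
#' whose dense occurrence in homopolymers makes loose windows ambiguous.
#'
#' @param cand_pos,cand_len Candidate anchor position(s) and signed
#'   length(s).
#' @param val_pos,val_len Validated positions and lengths (same length as
#'   the candidate vectors, or length 1).
#' @param cand_chrom,val_chrom Optional chromosome names; differing
#'   chromosomes yield `FALSE` (not an error).
#' @return Logical vector.
#' @export
match_indel <- function(cand_pos, cand_len, val_pos, val_len,
                        cand_chrom = NULL, val_chrom = NULL) {
  window <- ifelse(abs(cand_len) == 1L, 5L, 30L)
  ok <- cand_len == val_len & abs(cand_pos - val_pos) <= window
  if (!is.null(cand_chrom)) ok <- ok & cand_chrom == val_chrom
  ok
}

#' Classify validation read evidence into site statuses
#'
#' Applies the amplicon-resequencing decision rules. With
#' `r = variant_reads / total_reads` and the 1 bp-INDEL thresholds in
#' parentheses:
#' \itemize{
#'   \item FAILED -- design/PCR failure, or fewer than 20 covering reads;
#'   \item CONFIRMED -- `r >= 0.20` (0.40) and mean base quality
#'     `>= 10` (20);
#'   \item FALSE_POSITIVE -- `r < 0.03` (0.05);
#'   \item AMBIGUOUS -- everything in between, including sites meeting the
#'     ratio floor but failing the base-quality floor (the false-positive
#'     rule is stated solely in terms of the ratio).
#' }
#'
#' @param evidence A tibble with columns `length` (signed INDEL length),
#'   `variant_reads`, `total_reads`, `mean_base_quality` and
#'   `design_failed`.
#' @return Character vector of statuses (`"CONFIRMED"`,
#'   `"FALSE_POSITIVE"`, `"AMBIGUOUS"`, `"FAILED"`), one per row.
#' @export
validation_status <- function(evidence) {
  stopifnot(all(c("length", "variant_reads", "total_reads",
                  "mean_base_quality", "design_failed") %in% names(evidence)))
  if (any(evidence$variant_reads > evidence$total_reads, na.rm = TRUE)) {
    stop("variant_reads exceed total_reads")
  }
  one_bp <- abs(evidence$length) == 1L
  conf_ratio <- ifelse(one_bp, 0.40, 0.20)
  conf_bq <- ifelse(one_bp, 20, 10)
  fp_ratio <- ifelse(one_bp, 0.05, 0.03)
  failed <- evidence$design_failed | evidence$total_reads < 20L
  r <- ifelse(evidence$total_reads > 0L,
              evidence$variant_reads / evidence$total_reads, 0)
  status <- ifelse(
    failed, "FAILED",
    ifelse(r >= conf_ratio & evidence$mean_base_quality >= conf_bq, "CONFIRMED",
           ifelse(r < fp_ratio, "FALSE_POSITIVE", "AMBIGUOUS")))
  status
}

#' Tally validation statuses into counts
#'
#' @param status Character vector from [validation_status()].
#' @param scope Label for the assessed set (e.g. `"union"`,
#'   `"consensus"`).
#' @return A list with `TP`, `FP`, `AMBG`, `FAIL` and `scope`; the four
#'   counts sum to `length(status)`.
#' @export
validation_counts <- function(status, scope = "union") {
  list(TP = sum(status == "CONFIRMED"),
       FP = sum(status == "FALSE_POSITIVE"),
       AMBG = sum(status == "AMBIGUOUS"),
       FAIL = sum(status == "FAILED"),
       scope = scope)
}

#' False discovery rate from validation counts
#'
#' `FDR = FP / (TP + FP)`: the fraction of decided (confirmed or
#' false-positive) sites that failed validation. Ambiguous and failed
#' sites carry no information and are excluded.
#'
#' @param counts A list with elements `TP` and `FP` (see
#'   [validation_counts()]).
#' @return FDR in [0, 1].
#' @examples
#' estimate_fdr(list(TP = 93, FP = 7))   # 0.07
#' estimate_fdr(list(TP = 64, FP = 36))  # 0.36
#' @export
estimate_fdr <- function(counts) {
  if (counts$TP + counts$FP == 0L) stop("no decided sites: FDR undefined")
  counts$FP / (counts$TP + counts$FP)
}

#' Relative sensitivity of the consensus versus the union
#'
#' The fraction of union true positives retained by the consensus:
#' `S_consensus = TP_consensus / TP_union`.
#'
#' @param tp_consensus,tp_union Confirmed-site counts, with
#'   `tp_consensus <= tp_union` and `tp_union > 0`.
#' @return Relative sensitivity in [0, 1].
#' @examples
#' relative_sensitivity(86, 100)  # 0.86
#' @export
relative_sensitivity <- function(tp_consensus, tp_union) {
  if (tp_union <= 0L) stop("tp_union must be positive")
  if (tp_consensus > tp_union) stop("tp_consensus cannot exceed tp_union")
  tp_consensus / tp_union
}

#' Estimated number of INDELs detectable in the data
#'
#' `TP_union + (AMBG_consensus + FAIL_consensus) * (1 - S_consensus)`:
#' the confirmed union INDELs plus the expected yield among consensus
#' sites whose validation was uninformative. An alternate estimator
#' multiplying the uninformative term additionally by `1 - FDR_consensus`
#' is available via `fdr_consensus` (the two readings of the published
#' procedure differ in whether that term is applied).
#'
#' @param tp_union Confirmed union sites.
#' @param ambg_consensus,fail_consensus Ambiguous and failed consensus
#'   sites.
#' @param s_consensus Relative sensitivity in [0, 1].
#' @param fdr_consensus Optional consensus FDR; when supplied the
#'   uninformative term is scaled by `1 - fdr_consensus` as well.
#' @return Estimated detectable INDEL count (`>= tp_union`).
#' @examples
#' detectable_indels(500, 20, 30, 0.86)  # 507
#' @export
detectable_indels <- function(tp_union, ambg_consensus, fail_consensus,
                              s_consensus, fdr_consensus = NULL) {
  stopifnot(tp_union >= 0, ambg_consensus >= 0, fail_consensus >= 0,
            s_consensus >= 0, s_consensus <= 1)
  extra <- (ambg_consensus + fail_consensus) * (1 - s_consensus)
  if (!is.null(fdr_consensus)) extra <- extra * (1 - fdr_consensus)
  tp_union + extra
}

#' Per-individual confirmation and rediscovery rates
#'
#' In-silico comparison of a query call set against an orthogonal
#' reference call set, one overlapping individual at a time. For each
#' individual, matching is by genomic position of the carried loci:
#' confirmation = |query matched in reference| / |query|, rediscovery =
#' |reference matched in query| / |reference|. Rates are averaged across
#' individuals with at least one carried locus on the relevant side.
#'
#' @param query,reference [genotype_matrix()] objects, both left-aligned
#'   and restricted to the shared target regions.
#' @return A list with `confirmation`, `rediscovery` (mean rates) and
#'   `n_individuals` compared.
#' @export
insilico_rates <- function(query, reference) {
  shared <- intersect(query$samples, reference$samples)
  if (length(shared) == 0L) stop("no overlapping individuals between call sets")
  qpos <- paste(query$loci$chrom, query$loci$pos)
  rpos <- paste(reference$loci$chrom, reference$loci$pos)
  qc <- carrier_matrix(query)[, shared, drop = FALSE]
  rc <- carrier_matrix(reference)[, shared, drop = FALSE]
  conf <- redis <- rep(NA_real_, length(shared))
  for (i in seq_along(shared)) {
    q <- unique(qpos[qc[, i]])
    r <- unique(rpos[rc[, i]])
    if (length(q)) conf[i] <- mean(q %in% r)
    if (length(r)) redis[i] <- mean(r %in% q)
  }
  list(confirmation = mean(conf, na.rm = TRUE),
       rediscovery = mean(redis, na.rm = TRUE),
       n_individuals = length(shared))
}

#' Select validation sites preserving the allele-frequency distribution
#'
#' Samples `n` sites from a call set, stratified by AF bin so that the
#' selected sites' bin proportions match the full set's (largest-remainder
#' rounding), and for each site picks up to `max_carriers` carrier
#' individuals uniformly at random (all of them when fewer carry the
#' allele).
#'
#' @param gm A [genotype_matrix()] of the candidate sites (typically the
#'   union).
#' @param n Number of sites to select (`<= nrow(gm$loci)`).
#' @param max_carriers Carriers per site (default 5).
#' @param seed Integer seed.
#' @return A list: `sites` (integer locus indices) and `carriers` (list of
#'   character sample vectors, one per selected site).
#' @export
select_validation_sites <- function(gm, n, max_carriers = 5L, seed = 1L) {
  total <- nrow(gm$loci)
  if (n > total) stop("cannot select more sites than the call set contains")
  withr::local_seed(seed)
  af <- alt_allele_frequency(gm)
  bins <- rep(NA_integer_, total)
  ok <- !is.na(af$aaf) & af$aaf > 0
  bins[ok] <- af_bin(af$aaf[ok])
  bins[!ok] <- 0L  # uncalled sites form their own stratum
  tab <- table(bins)
  quota <- n * as.numeric(tab) / total
  take <- floor(quota)
  rem <- n - sum(take)
  if (rem > 0L) {
    extra <- order(quota - take, decreasing = TRUE)[seq_len(rem)]
    take[extra] <- take[extra] + 1L
  }
  picked <- integer(0)
  for (b in seq_along(tab)) {
    pool <- which(bins == as.integer(names(tab)[b]))
    k <- min(take[b], length(pool))
    if (k > 0L) picked <- c(picked, sample(pool, k))
  }
  picked <- sort(picked)
  cw <- carrier_matrix(gm)
  carriers <- lapply(picked, function(i) {
    cs <- gm$samples[cw[i, ]]
    if (length(cs) <= max_carriers) cs else sample(cs, max_carriers)
  })
  list(sites = picked, carriers = carriers)
}
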