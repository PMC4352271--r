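#' Simulate caller call sets from the truth
#'
#' Emulates K independent variant-calling pipelines. Each caller reports
#' each true site with its sensitivity and contributes false positives
#' whose total load across callers is derived from the configured union
#' FDR; false positives are biased toward planted repeat tracts. True
#' calls carry quality scores drawn from the caller's true-call
#' distribution, false calls from the (stochastically lower) false-call
#' distribution. A fraction of records is emitted right-shifted and a
#' fraction as complex events (an adjacent substitution folded into the
#' allele strings) to exercise ingest normalization. Per-sample read
#' evidence (depth, variant reads) is attached: binomial reads at the
#' genotype's expected variant fraction for true sites, at a low
#' artifact ratio in the claimed carriers of false sites.
#'
#' @param truth A truth [genotype_matrix()] from [simulate_truth()].
#' @param simref A `sim_reference`.
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A named list of caller call sets; each is a
#'   [genotype_matrix()] whose loci additionally carry `qual`, `caller`
#'   and the ground-truth label `is_true`. Loci may be right-shifted or
#'   complex-encoded; normalize with [normalize_callset()] before
#'   merging.
#' @export
simulate_callers <- function(truth, simref, config, seed) {
  if (length(config$sensitivities) < 2L) stop("need at least two caller profiles")
  withr::local_seed(seed)
  ref_seqs <- simref$reference
  callers <- names(config$sensitivities)
  n_true <- nrow(truth$loci)
  # derive the per-caller FP load from the planted union FDR
  exp_tp_union <- n_true * (1 - prod(1 - config$sensitivities))
  f <- config$target_union_fdr
  n_fp_total <- round(exp_tp_union * f / (1 - f))
  n_fp_caller <- diff(round(seq(0, n_fp_total, length.out = length(callers) + 1L)))
  out <- vector("list", length(callers))
  names(out) <- callers
  for (k in seq_along(callers)) {
    sens <- config$sensitivities[k]
    hit <- stats::runif(n_true) < sens
    tp_loci <- truth$loci[hit, c("chrom", "pos", "ref", "alt", "length", "seq")]
    tp_loci$qual <- stats::rlnorm(sum(hit), config$qual_tp[1], config$qual_tp[2])
    tp_gt <- truth$gt[hit, , drop = FALSE]
    fp <- simulate_false_calls(n_fp_caller[k], simref, config)
    fp_gt <- matrix(0L, nrow(fp), ncol(truth$gt))
    for (j in seq_len(nrow(fp))) {
      fp_gt[j, sample.int(ncol(fp_gt), sample(1:3, 1L))] <- 1L
    }
    loci <- dplyr::bind_rows(
      dplyr::mutate(tp_loci, is_true = TRUE),
      dplyr::mutate(fp, is_true = FALSE))
    gt <- rbind(tp_gt, fp_gt)
    ns <- ncol(gt)
    nl <- nrow(gt)
    dp <- matrix(stats::rpois(nl * ns, config$depth_mean), nl, ns)
    pvar <- matrix(0, nl, ns)
    e <- config$seq_error
    pvar[gt == 0L] <- e
    pvar[gt == 1L] <- 0.5 * (1 - e) + 0.5 * e / 3
    pvar[gt == 2L] <- 1 - e
    art <- stats::rbeta(nl, config$artifact_ratio[1], config$artifact_ratio[2])
    fp_rows <- !loci$is_true
    pvar[fp_rows & gt > 0L] <-
      matrix(art, nl, ns)[fp_rows & gt > 0L]
    vr <- matrix(stats::rbinom(nl * ns, dp, pvar), nl, ns)
    loci$caller <- callers[k]
    # non-canonical encodings exercising the normalization path
    u <- stats::runif(nl)
    shift_i <- which(u < config$right_shift_frac)
    if (length(shift_i)) {
      loci[shift_i, c("chrom", "pos", "ref", "alt", "length", "seq")] <-
        right_shift(loci[shift_i, ], ref_seqs)[
          , c("chrom", "pos", "ref", "alt", "length", "seq")]
    }
    cplx_i <- which(u >= config$right_shift_frac &
                      u < config$right_shift_frac + config$complex_frac &
                      loci$pos > 1L)
    for (j in cplx_i) {
      prev <- substr(ref_seqs[[loci$chrom[j]]], loci$pos[j] - 1L, loci$pos[j] - 1L)
      if (prev == "N") next
      sub <- sample(setdiff(c("A", "C", "G", "T"), prev), 1L)
      loci$pos[j] <- loci$pos[j] - 1L
      loci$ref[j] <- paste0(prev, loci$ref[j])
      loci$alt[j] <- paste0(sub, loci$alt[j])
    }
    ord <- order(loci$chrom, loci$pos)
    out[[k]] <- genotype_matrix(loci[ord, ], truth$samples,
                                gt[ord, , drop = FALSE],
                                dp[ord, , drop = FALSE],
                                vr[ord, , drop = FALSE])
  }
  out
}

# false calls: short noise lengths, placed next to repeat tracts with
# probability repeat_fp_bias, uniformly in targets otherwise
simulate_false_calls <- function(n_fp, simref, config) {
  ref_seqs <- simref$reference
  noise_lens <- c(-3L, -2L, -1L, 1L, 2L, 3L)
  noise_w <- c(0.08, 0.15, 0.45, 0.22, 0.07, 0.03)
  tstarts <- GenomicRanges::start(simref$targets)
  tends <- GenomicRanges::end(simref$targets)
  tchroms <- as.character(GenomicRanges::seqnames(simref$targets))
  twidths <- tends - tstarts + 1L
  in_t <- anchor_in_targets(
    tibble::tibble(chrom = simref$tracts$chrom, pos = simref$tracts$start),
    simref$targets)
  tracts <- simref$tracts[in_t, ]
  chrom <- character(n_fp); pos <- integer(n_fp); lens <- integer(n_fp)
  seq <- character(n_fp)
  for (i in seq_len(n_fp)) {
    L <- sample(noise_lens, 1L, prob = noise_w)
    repeat {
      if (nrow(tracts) > 0L && stats::runif(1) < config$repeat_fp_bias) {
        tr <- sample.int(nrow(tracts), 1L)
        ch <- tracts$chrom[tr]
        p <- tracts$start[tr] - 1L + sample.int(3L, 1L) - 1L
      } else {
        iv <- sample.int(length(twidths), 1L, prob = twidths)
        ch <- tchroms[iv]
        p <- tstarts[iv] + sample.int(twidths[iv], 1L) - 1L
      }
      if (p < 2L) next
      if (L < 0L) {
        s <- substr(ref_seqs[[ch]], p + 1L, p - L)
        if (nchar(s) < -L || grepl("N", s, fixed = TRUE)) next
      } else {
        s <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
      }
      if (substr(ref_seqs[[ch]], p, p) == "N") next
      chrom[i] <- ch; pos[i] <- p; lens[i] <- L; seq[i] <- s
      break
    }
  }
  anchor <- mapply(anchor_base, chrom = chrom, pos = pos,
                   MoreArgs = list(ref_seqs = ref_seqs), USE.NAMES = FALSE)
  ins <- lens > 0L
  rec <- indel_records(chrom, pos,
                       ref = ifelse(ins, anchor, paste0(anchor, seq)),
                       alt = ifelse(ins, paste0(anchor, seq), anchor),
                       qual = stats::rlnorm(n_fp, config$qual_fp[1], config$qual_fp[2]))
  rec[c("chrom", "pos", "ref", "alt", "length", "seq", "qual")]
}

#' Normalize a raw caller call set
#'
#' Ingest-style normalization of a simulated (or parsed) call set:
#' complex records are split into primitives keeping only the INDEL
#' component, pure records are validated, everything is left-aligned,
#' non-INDELs and alleles of 100 bp or longer are dropped, and duplicate
#' keys are collapsed (first record wins).
#'
#' @param cs A [genotype_matrix()] whose loci have `chrom`, `pos`,
#'   `ref`, `alt`, `qual` (other columns preserved where possible).
#' @param ref_seqs Reference sequences.
#' @return A [genotype_matrix()] with normalized loci.
#' @export
normalize_callset <- function(cs, ref_seqs) {
  loci <- cs$loci
  n <- nrow(loci)
  keep <- logical(n)
  chrom <- character(n); pos <- integer(n); ref <- character(n); alt <- character(n)
  for (i in seq_len(n)) {
    r <- loci$ref[i]; a <- loci$alt[i]
    if (nchar(r) == nchar(a)) next  # SNP/MNP: not an INDEL
    if (min(nchar(r), nchar(a)) == 1L && substr(r, 1, 1) == substr(a, 1, 1)) {
      chrom[i] <- loci$chrom[i]; pos[i] <- loci$pos[i]; ref[i] <- r; alt[i] <- a
    } else {
      prim <- split_complex(loci$chrom[i], loci$pos[i], r, a)
      ind <- prim[prim$type != "SNP", ]
      if (nrow(ind) == 0L) next
      chrom[i] <- ind$chrom[1]; pos[i] <- ind$pos[1]
      ref[i] <- ind$ref[1]; alt[i] <- ind$alt[1]
    }
    if (abs(nchar(alt[i]) - nchar(ref[i])) >= 100L) next
    keep[i] <- TRUE
  }
  idx <- which(keep)
  rec <- indel_records(chrom[idx], pos[idx], ref[idx], alt[idx],
                       qual = loci$qual[idx])
  extra <- setdiff(names(loci), names(rec))
  for (col in extra) rec[[col]] <- loci[[col]][idx]
  rec <- left_align(rec, ref_seqs)
  dup <- duplicated(indel_key(rec))
  idx <- idx[!dup]
  rec <- rec[!dup, ]
  ord <- order(rec$chrom, rec$pos, rec$ref, rec$alt)
  genotype_matrix(rec[ord, ], cs$samples,
                  cs$gt[idx[ord], , drop = FALSE],
                  if (!is.null(cs$dp)) cs$dp[idx[ord], , drop = FALSE],
                  if (!is.null(cs$vr)) cs$vr[idx[ord], , drop = FALSE])
}

#' Simulate regenotyping read evidence at a set of sites
#'
#' Emulates returning to the alignments for fresh per-sample evidence at
#' arbitrary sites. Sites present in the truth emit reads according to
#' each sample's true genotype; sites absent from the truth emit
#' error-rate reads except in the samples claimed as carriers, which
#' show the artifact's variant-read ratio (sequencing artifacts are
#' reproducible in the reads, which is what makes consensus filtering
#' non-trivial).
#'
#' @param gm A [genotype_matrix()] of the sites needing evidence (its
#'   `gt` holds the claimed genotypes).
#' @param truth The truth [genotype_matrix()].
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return `gm` with fresh `dp`/`vr` matrices.
#' @export
simulate_read_evidence <- function(gm, truth, config, seed) {
  withr::local_seed(seed)
  nl <- nrow(gm$loci)
  ns <- length(gm$samples)
  truth_idx <- match(indel_key(gm$loci), indel_key(truth$loci))
  dp <- matrix(stats::rpois(nl * ns, config$depth_mean), nl, ns)
  e <- config$seq_error
  pvar <- matrix(e, nl, ns)
  art <- stats::rbeta(nl, config$artifact_ratio[1], config$artifact_ratio[2])
  for (i in seq_len(nl)) {
    if (!is.na(truth_idx[i])) {
      g <- truth$gt[truth_idx[i], match(gm$samples, truth$samples)]
      pvar[i, g == 1L] <- 0.5 * (1 - e) + 0.5 * e / 3
      pvar[i, g == 2L] <- 1 - e
    } else {
      claimed <- !is.na(gm$gt[i, ]) & gm$gt[i, ] > 0L
      pvar[i, claimed] <- art[i]
    }
  }
  vr <- matrix(stats::rbinom(nl * ns, dp, pvar), nl, ns)
  genotype_matrix(gm$loci, gm$samples, gm$gt, dp, vr)
}

#' Simulate amplicon validation read evidence
#'
#' Emulates deep amplicon resequencing of selected sites in selected
#' carrier individuals. True sites emit variant reads at the carrier
#' genotype's expected fraction (het `0.5 * (1 - e)`, hom-alt `1 - e`);
#' false sites at the assay error rate. Mean base quality is drawn high
#' for real signal and low for noise, and a configured fraction of
#' assays fails by design.
#'
#' @param sites A tibble with columns `key`, `length`, `is_true` and
#'   `carrier_gt` (1 het, 2 hom-alt; ignored for false sites).
#' @param depth Amplicon read depth (fixed per assay).
#' @param error_rate Per-read error rate of the assay.
#' @param seed Integer seed.
#' @param design_fail_rate Fraction of assays flagged as design failures.
#' @return The sites tibble with `variant_reads`, `total_reads`,
#'   `mean_base_quality` and `design_failed` appended.
#' @export
simulate_validation_evidence <- function(sites, depth, error_rate, seed,
                                         design_fail_rate = 0) {
  stopifnot(depth >= 1L)
  withr::local_seed(seed)
  n <- nrow(sites)
  p <- ifelse(sites$is_true,
              ifelse(sites$carrier_gt >= 2L, 1 - error_rate,
                     0.5 * (1 - error_rate)),
              error_rate)
  sites$total_reads <- rep(as.integer(depth), n)
  sites$variant_reads <- stats::rbinom(n, sites$total_reads, p)
  sites$mean_base_quality <- ifelse(sites$is_true,
                                    stats::rnorm(n, 30, 3),
                                    stats::rnorm(n, 12, 4))
  sites$design_failed <- stats::runif(n) < design_fail_rate
  sites
}
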