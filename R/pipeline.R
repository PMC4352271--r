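#' Run the full synthetic consensus pipeline
#'
#' Executes every stage end to end on synthetic data with known ground
#' truth: reference simulation, truth and caller simulation, ingest
#' normalization, union merge, random-forest consensus at the
#' probability cutoff, regenotyping with empty-locus pruning,
#' change-in-copy-count classification, population statistics, and the
#' validation experiment (site selection preserving the allele-frequency
#' distribution, simulated amplicon evidence, FDR / relative-sensitivity
#' / detectable-INDEL estimates, in-silico confirmation and rediscovery
#' against the truth). All randomness derives from `seed`.
#'
#' @param config A [sim_config()].
#' @param seed Integer master seed; stage seeds are derived from it.
#' @param out_dir Output directory for stage artifacts (VCF/BED/FASTA/
#'   TSV/JSON plus a run manifest); `NULL` runs in memory only.
#' @param threshold Consensus probability cutoff in [0, 1] (default 0.4).
#' @param n_validation Number of union sites submitted to the simulated
#'   validation experiment (capped at the union size).
#' @return A list with the stage objects (`simref`, `truth`, `callsets`,
#'   `union`, `model`, `consensus`, `ccc`, `stats`, `validation`) and
#'   `summary`, a flat named list of headline numbers.
#' @export
run_pipeline <- function(config = sim_config(), seed = 1L, out_dir = NULL,
                         threshold = 0.4, n_validation = 800L) {
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  stopifnot(inherits(config, "sim_config"))
  seed <- as.integer(seed)
  sseed <- function(k) (seed * 97L + k) %% .Machine$integer.max

  simref <- make_reference(config, sseed(1L))
  truth <- simulate_truth(simref, config, sseed(2L))
  raw <- simulate_callers(truth, simref, config, sseed(3L))
  callsets <- lapply(raw, normalize_callset, ref_seqs = simref$reference)
  union <- merge_union(callsets, simref$targets)

  truth_keys <- indel_key(truth$loci)
  cov <- consensus_covariates(union, simref$reference)
  labeled <- label_training(cov, truth_keys)
  model <- train_consensus_model(labeled, seed = sseed(4L))
  consensus <- apply_consensus(union, model, simref$reference, threshold)

  evidence <- simulate_read_evidence(consensus$genotypes, truth, config, sseed(5L))
  regen <- regenotype(evidence)
  kept <- consensus$records$key %in% indel_key(regen$loci)
  consensus$records <- consensus$records[kept, ]
  consensus$genotypes <- regen

  cons_loci <- classify_ccc(consensus$genotypes$loci, simref$reference)
  consensus$genotypes$loci <- cons_loci
  ccc <- ccc_profile(consensus$genotypes)

  region_bp <- sum(GenomicRanges::width(simref$targets))
  cw <- carrier_matrix(consensus$genotypes)
  stats_out <- list(
    density = mean(variant_density(colSums(cw), region_bp)),
    density_by_af = density_by_af_bin(consensus$genotypes, region_bp),
    density_by_length = density_by_length(consensus$genotypes, region_bp),
    pct_het = percent_heterozygous(consensus$genotypes),
    del_ins_ratio = deletion_insertion_ratio(consensus$genotypes),
    frameshift_pct = 100 * frameshift_rate(consensus$genotypes$loci),
    af = alt_allele_frequency(consensus$genotypes)
  )

  val <- run_validation_experiment(union, consensus, truth, config,
                                   n_validation, sseed(6L))
  insilico <- insilico_rates(consensus$genotypes, truth)

  summary <- list(
    n_truth = nrow(truth$loci),
    n_union = nrow(union$records),
    n_consensus = nrow(consensus$records),
    union_fdr_planted = mean(!(union$records$key %in% truth_keys)),
    consensus_fdr_planted = mean(!(consensus$records$key %in% truth_keys)),
    union_fdr_validated = val$fdr_union,
    consensus_fdr_validated = val$fdr_consensus,
    relative_sensitivity = val$s_consensus,
    detectable_indels = val$detectable,
    ccc_pct = ccc$population[["ccc_ins"]] + ccc$population[["ccc_del"]],
    ccc_profile_population = ccc$population,
    ccc_profile_individual = ccc$individual,
    density_per_mb = stats_out$density,
    del_ins_ratio = stats_out$del_ins_ratio,
    frameshift_pct = stats_out$frameshift_pct,
    pct_het = stats_out$pct_het,
    confirmation_rate = insilico$confirmation,
    rediscovery_rate = insilico$rediscovery
  )

  result <- list(simref = simref, truth = truth, callsets = callsets,
                 union = union, model = model, consensus = consensus,
                 ccc = ccc, stats = stats_out, validation = val,
                 insilico = insilico, summary = summary,
                 seed = seed, threshold = threshold)
  if (!is.null(out_dir)) write_pipeline_artifacts(result, config, out_dir)
  result
}

#' Simulated validation experiment over union sites
#'
#' Selects sites from the union preserving its allele-frequency
#' distribution, simulates amplicon read evidence with the configured
#' assay depth and error, classifies site statuses, and computes the
#' validation formulas for the union and its consensus subset.
#'
#' @param union A `union_set`.
#' @param consensus The consensus `union_set` (subset of `union`).
#' @param truth Truth [genotype_matrix()].
#' @param config A [sim_config()].
#' @param n_sites Sites to validate (capped at the union size).
#' @param seed Integer seed.
#' @return A list: per-site `table` (key, status, is_true), `counts_union`,
#'   `counts_consensus`, `fdr_union`, `fdr_consensus`, `s_consensus`,
#'   `detectable`, `planted_fp_fraction`.
#' @export
run_validation_experiment <- function(union, consensus, truth, config,
                                      n_sites, seed) {
  n_sites <- min(n_sites, nrow(union$records))
  sel <- select_validation_sites(union$genotypes, n_sites,
                                 max_carriers = 5L, seed = seed)
  keys <- union$records$key[sel$sites]
  truth_keys <- indel_key(truth$loci)
  is_true <- keys %in% truth_keys
  carrier_gt <- vapply(seq_along(sel$sites), function(i) {
    site <- sel$sites[i]
    cars <- sel$carriers[[i]]
    if (!is_true[i] || length(cars) == 0L) return(1L)
    ti <- match(keys[i], truth_keys)
    g <- truth$gt[ti, match(cars, truth$samples)]
    g <- g[!is.na(g) & g > 0L]
    if (length(g) == 0L) 1L else as.integer(sample(rep(g, 2L), 1L))
  }, integer(1))
  sites <- tibble::tibble(key = keys,
                          length = union$records$length[sel$sites],
                          is_true = is_true, carrier_gt = carrier_gt)
  ev <- simulate_validation_evidence(sites, config$validation_depth,
                                     config$validation_error, seed + 1L,
                                     config$design_fail_rate)
  ev$status <- validation_status(ev)
  cu <- validation_counts(ev$status, "union")
  in_cons <- ev$key %in% consensus$records$key
  cc <- validation_counts(ev$status[in_cons], "consensus")
  fdr_u <- estimate_fdr(cu)
  fdr_c <- estimate_fdr(cc)
  s_cons <- relative_sensitivity(cc$TP, cu$TP)
  det <- detectable_indels(cu$TP, cc$AMBG, cc$FAIL, s_cons)
  list(table = ev, counts_union = cu, counts_consensus = cc,
       fdr_union = fdr_u, fdr_consensus = fdr_c,
       s_consensus = s_cons, detectable = det,
       planted_fp_fraction = mean(!is_true))
}

write_pipeline_artifacts <- function(result, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  simref <- result$simref
  write_fasta(simref$reference, p("reference.fa"))
  write_targets(simref$targets, p("targets.bed"))
  write_vcf(result$truth, p("truth.vcf.gz"), ref_seqs = simref$reference)
  for (nm in names(result$callsets)) {
    write_vcf(result$callsets[[nm]], p(paste0("calls_", nm, ".vcf.gz")),
              ref_seqs = simref$reference)
  }
  write_vcf(result$union$genotypes, p("union.vcf.gz"),
            info = list(CALLERS = result$union$records$callers,
                        NQUAL = round(result$union$records$norm_qual_mean, 4)),
            ref_seqs = simref$reference)
  cov <- consensus_covariates(result$union, simref$reference)
  utils::write.table(cov, p("union_covariates.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_vcf(result$consensus$genotypes, p("consensus.vcf.gz"),
            info = list(PROB = round(result$consensus$records$prob, 4),
                        CCC = as.integer(result$consensus$genotypes$loci$ccc),
                        MOTIF = result$consensus$genotypes$loci$motif),
            ref_seqs = simref$reference)
  ccc_tab <- rbind(population = result$ccc$population,
                   individual = result$ccc$individual)
  utils::write.table(cbind(level = rownames(ccc_tab), as.data.frame(ccc_tab)),
                     p("ccc_profile.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(result$stats$density_by_af, p("density_by_af_bin.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(result$stats$density_by_length, p("density_by_length.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(result$validation$table, p("validation_sites.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(result$summary, p("summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- list.files(out_dir, full.names = TRUE)
  manifest <- list(
    package = as.character(utils::packageVersion("indelcons")),
    seed = result$seed, threshold = result$threshold,
    config = config[c("ref_length", "n_samples", "n_true_indels",
                      "ccc_fraction", "target_union_fdr")],
    counts = result$summary[c("n_truth", "n_union", "n_consensus")],
    files = stats::setNames(as.list(unname(tools::md5sum(files))),
                            basename(files)))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(out_dir)
}
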