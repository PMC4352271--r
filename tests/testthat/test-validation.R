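test_that("matching requires identical length within the position window", {
  # 1 bp INDELs use the tight 5 bp window
  expect_true(match_indel(100L, -1L, 104L, -1L))
  expect_false(match_indel(100L, -1L, 106L, -1L))
  # longer INDELs use 30 bp
  expect_true(match_indel(100L, -3L, 130L, -3L))
  expect_false(match_indel(100L, -3L, 131L, -3L))
  # exact same length required
  expect_false(match_indel(100L, -3L, 100L, -2L))
  # different chromosomes: no match, not an error
  expect_false(match_indel(100L, 2L, 100L, 2L, "chr1", "chr2"))
})

test_that("status rules reproduce the validation thresholds exactly", {
  ev <- tibble::tibble(
    length            = c(-3L, -3L, -3L, -3L, -1L, -1L, -1L, -1L,  2L, -1L, 5L),
    variant_reads     = c(25L,  2L, 10L, 25L, 40L, 39L,  4L,  5L,  3L, 40L, 0L),
    total_reads       = c(100L, 100L, 100L, 100L, 100L, 100L, 100L, 100L, 100L, 100L, 0L),
    mean_base_quality = c(15,   15,  15,   9,  25,  25,  25,  25,  15,  19, 30),
    design_failed     = c(rep(FALSE, 10), FALSE))
  ev$total_reads[9] <- 15L  # fewer than 20 covering reads
  expect_identical(validation_status(ev), c(
    "CONFIRMED",        # 25% ratio, bq 15
    "FALSE_POSITIVE",   # 2% < 3%
    "AMBIGUOUS",        # 10% between 3% and 20%
    "AMBIGUOUS",        # ratio confirmed but bq below 10: not an FP
    "CONFIRMED",        # 1 bp, 40% >= 40%, bq 25 >= 20
    "AMBIGUOUS",        # 1 bp, 39% just below the 40% floor
    "FALSE_POSITIVE",   # 1 bp, 4% < 5%
    "AMBIGUOUS",        # 1 bp, 5% is not below 5%
    "FAILED",           # < 20 reads
    "AMBIGUOUS",        # 1 bp ratio ok, bq 19 below 20
    "FAILED"))          # zero depth
  counts <- validation_counts(validation_status(ev))
  expect_identical(counts$TP + counts$FP + counts$AMBG + counts$FAIL, nrow(ev))
})

test_that("the FDR is the false fraction of decided sites", {
  expect_equal(estimate_fdr(list(TP = 93, FP = 7)), 0.07)
  expect_equal(estimate_fdr(list(TP = 64, FP = 36)), 0.36)
  expect_equal(estimate_fdr(list(TP = 10, FP = 0)), 0)
  expect_error(estimate_fdr(list(TP = 0, FP = 0)), "undefined")
})

test_that("relative sensitivity divides consensus TPs by union TPs", {
  expect_equal(relative_sensitivity(86, 100), 0.86)
  expect_equal(relative_sensitivity(50, 50), 1)
  expect_equal(relative_sensitivity(0, 100), 0)
  expect_error(relative_sensitivity(10, 0), "positive")
  expect_error(relative_sensitivity(11, 10), "exceed")
})

test_that("detectable INDELs follow the published estimator", {
  expect_equal(detectable_indels(500, 20, 30, 0.86), 507)
  expect_equal(detectable_indels(500, 20, 30, 1), 500)
  expect_equal(detectable_indels(500, 0, 0, 0.3), 500)
  expect_gte(detectable_indels(10, 5, 5, 0.5), 10)
  # the alternate estimator scales the uninformative term by 1 - FDR
  expect_equal(detectable_indels(500, 20, 30, 0.86, fdr_consensus = 0.1),
               500 + 50 * 0.14 * 0.9)
})

test_that("in-silico rates are per-individual confirmation and rediscovery", {
  loci <- indel_records("chr1", c(10L, 60L, 110L, 160L, 210L),
                        rep("A", 5), rep("AT", 5))
  gt <- matrix(1L, 5, 2)
  q <- genotype_matrix(loci, c("S1", "S2"), gt)
  expect_equal(insilico_rates(q, q)$confirmation, 1)
  expect_equal(insilico_rates(q, q)$rediscovery, 1)
  other <- genotype_matrix(
    indel_records("chr2", c(10L, 60L), c("A", "A"), c("AT", "AT")),
    c("S1", "S2"), matrix(1L, 2, 2))
  expect_equal(insilico_rates(q, other)$confirmation, 0)
  expect_equal(insilico_rates(q, other)$rediscovery, 0)
  # planted 80%: S1 carries 4 of 5 reference loci plus one private locus
  ref_gm <- genotype_matrix(loci, "S1", matrix(1L, 5, 1))
  qloci <- dplyr::bind_rows(
    loci[1:4, ],
    indel_records("chr1", 500L, "A", "AT"))
  qgm <- genotype_matrix(qloci, "S1", matrix(1L, 5, 1))
  rates <- insilico_rates(qgm, ref_gm)
  expect_equal(rates$confirmation, 0.8)
  expect_equal(rates$rediscovery, 0.8)
  expect_error(insilico_rates(q, genotype_matrix(loci, "Z1", matrix(1L, 5, 1))),
               "overlapping")
})

test_that("validation site selection preserves the AF-bin mix", {
  withr::local_seed(17)
  n <- 600
  gt <- matrix(0L, n, 40)
  for (i in seq_len(n)) {
    ac <- sample(c(1L, 2L, 8L, 40L), 1, prob = c(0.5, 0.2, 0.2, 0.1))
    idx <- sample(40L * 2L, ac)
    gt[i, ] <- tabulate((idx - 1L) %/% 2L + 1L, nbins = 40L)
  }
  loci <- indel_records("chr1", seq(10L, by = 40L, length.out = n),
                        rep("A", n), rep("AT", n))
  gm <- genotype_matrix(loci, paste0("S", 1:40), gt)
  sel <- select_validation_sites(gm, 300L, seed = 18)
  expect_identical(length(sel$sites), 300L)
  bins_all <- af_bin(alt_allele_frequency(gm)$aaf)
  bins_sel <- bins_all[sel$sites]
  prop_all <- prop.table(table(factor(bins_all, levels = 1:7)))
  prop_sel <- prop.table(table(factor(bins_sel, levels = 1:7)))
  expect_lt(max(abs(prop_all - prop_sel)), 0.01)
  # carriers: at most 5, all of them when fewer carry the allele
  n_carriers <- rowSums(gt > 0L)[sel$sites]
  got <- lengths(sel$carriers)
  expect_true(all(got == pmin(n_carriers, 5L)))
  # selecting everything returns every site
  all_sel <- select_validation_sites(gm, n, seed = 19)
  expect_identical(sort(all_sel$sites), seq_len(n))
  expect_error(select_validation_sites(gm, n + 1L, seed = 1), "more sites")
})

test_that("simulated evidence respects the binomial tail bounds", {
  withr::local_seed(23)
  n <- 400
  # true hom-alt sites at depth 100, error 1%: confirmed essentially always
  sites <- tibble::tibble(key = sprintf("k%d", 1:n), length = 3L,
                          is_true = TRUE, carrier_gt = 2L)
  ev <- simulate_validation_evidence(sites, depth = 100L, error_rate = 0.01,
                                     seed = 24)
  expect_gt(mean(validation_status(ev) == "CONFIRMED"), 0.99)
  # false 1 bp sites at the same depth: ratio below the 5% floor essentially
  # always (the binomial tail above 5 of 100 reads at p = 0.01 is ~0.3%)
  sites$is_true <- FALSE
  sites$length <- -1L
  ev <- simulate_validation_evidence(sites, depth = 100L, error_rate = 0.01,
                                     seed = 25)
  # the per-site probability is ~0.997; allow 3 s.e. of sampling noise
  expect_gt(mean(validation_status(ev) == "FALSE_POSITIVE"), 0.98)
  # depth 10 always fails the 20-read floor
  ev10 <- simulate_validation_evidence(sites, depth = 10L, error_rate = 0.01,
                                       seed = 26)
  expect_true(all(validation_status(ev10) == "FAILED"))
})
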