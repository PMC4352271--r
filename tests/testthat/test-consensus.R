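# Separable synthetic training table: true alleles have multi-caller
# support and high normalized quality, false ones single-caller low
# quality, with the remaining covariates drawn from overlapping noise.
separable_table <- function(n, seed) {
  withr::local_seed(seed)
  lab <- rep(0:1, length.out = n)
  tibble::tibble(
    key = sprintf("chr1:%d:A:AT", seq_len(n)),
    n_callers = ifelse(lab == 1, 3, 1),
    norm_qual_mean = ifelse(lab == 1, runif(n, 0.6, 1), runif(n, 0, 0.4)),
    site_depth = rpois(n, 60),
    variant_read_ratio = runif(n, 0, 1),
    homopolymer_run = sample(1:12, n, replace = TRUE),
    abs_length = sample(1:10, n, replace = TRUE),
    label = lab
  )
}

test_that("truth-overlap labeling marks present keys true and refuses one class", {
  cov <- separable_table(10, 1)[, -8]
  lab <- label_training(cov, cov$key[c(1, 3)])
  expect_identical(lab$label, as.integer(seq_len(10) %in% c(1, 3)))
  expect_warning(lab0 <- label_training(cov, character(0)), "empty truth")
  expect_error(train_consensus_model(lab0, seed = 1), "single class")
})

test_that("the forest separates well-separated classes on held-out data", {
  train <- separable_table(2000, 10)
  test <- separable_table(1000, 11)
  m <- train_consensus_model(train, seed = 99)
  p <- consensus_probability(m, test)
  acc <- mean((p >= 0.5) == (test$label == 1))
  expect_gt(acc, 0.95)
})

test_that("with uninformative features the probability approximates the class prior", {
  withr::local_seed(2)
  n <- 600
  # identically distributed covariates for both classes: no signal
  tab <- tibble::tibble(
    key = sprintf("k%d", 1:n),
    n_callers = sample(1:3, n, replace = TRUE),
    norm_qual_mean = runif(n),
    site_depth = rpois(n, 50),
    variant_read_ratio = runif(n),
    homopolymer_run = sample(1:10, n, replace = TRUE),
    abs_length = sample(1:6, n, replace = TRUE),
    label = rep(c(0L, 0L, 0L, 1L), n / 4))  # prior 0.25
  m <- train_consensus_model(tab, seed = 5)
  new <- tab[1:200, ]
  new$key <- paste0("unseen", 1:200)
  p <- consensus_probability(m, new)
  expect_lt(abs(mean(p) - 0.25), 0.1)
})

test_that("training is deterministic for a fixed seed", {
  train <- separable_table(400, 3)
  test <- separable_table(100, 4)
  p1 <- consensus_probability(train_consensus_model(train, seed = 7), test)
  p2 <- consensus_probability(train_consensus_model(train, seed = 7), test)
  expect_identical(p1, p2)
})

test_that("the probability cutoff retains >= threshold and is monotone", {
  withr::local_seed(8)
  cfg <- tiny_config()
  sr <- make_reference(cfg, 21)
  tr <- simulate_truth(sr, cfg, 22)
  raw <- simulate_callers(tr, sr, cfg, 23)
  un <- merge_union(lapply(raw, normalize_callset, ref_seqs = sr$reference),
                    sr$targets)
  cov <- consensus_covariates(un, sr$reference)
  m <- train_consensus_model(label_training(cov, indel_key(tr$loci)), seed = 24)
  p <- consensus_probability(m, cov)
  cons <- apply_consensus(un, m, sr$reference, threshold = 0.4)
  expect_setequal(cons$records$key, un$records$key[p >= 0.4])
  expect_true(all(cons$records$prob >= 0.4))
  # threshold 0 keeps the whole union; raising the cutoff never adds sites
  cons0 <- apply_consensus(un, m, sr$reference, threshold = 0)
  expect_setequal(cons0$records$key, un$records$key)
  prev <- nrow(cons0$records)
  for (thr in c(0.2, 0.4, 0.6, 0.8)) {
    cur <- nrow(apply_consensus(un, m, sr$reference, thr)$records)
    expect_lte(cur, prev)
    prev <- cur
  }
  expect_error(apply_consensus(un, m, sr$reference, 1.01), "\\[0, 1\\]")
})

test_that("regenotyping maximizes the binomial likelihood and prunes empty loci", {
  loci <- indel_records("chr1", c(10L, 20L), c("A", "C"), c("AT", "CT"))
  dp <- matrix(c(30, 30, 30, 30), 2, 2)
  vr <- matrix(c(0, 15, 0, 0), 2, 2)  # locus 2 has no variant reads anywhere
  gm <- genotype_matrix(loci, c("S1", "S2"), matrix(1L, 2, 2), dp, vr)
  out <- regenotype(gm, error = 0.02)
  # oracle: explicit likelihoods for v=15, d=30
  ll <- dbinom(15, 30, c(0.02, 0.5, 0.98))
  expect_identical(which.max(ll) - 1L, 1L)
  expect_identical(unname(out$gt[1, "S1"]), 1L)
  expect_identical(unname(out$gt[1, "S2"]), 0L)
  expect_identical(nrow(out$loci), 1L)  # all-reference locus removed
  # v=0,d=30 -> hom-ref; depth 0 -> missing
  gm2 <- genotype_matrix(loci[1, ], c("S1", "S2"), matrix(1L, 1, 2),
                         matrix(c(30, 0), 1, 2), matrix(c(30, 0), 1, 2))
  out2 <- regenotype(gm2)
  expect_identical(unname(out2$gt[1, "S1"]), 2L)
  expect_true(is.na(out2$gt[1, "S2"]))
})

test_that("consensus filtering lowers the false fraction at bounded sensitivity cost", {
  # planted-label FDR comparison on one synthetic replicate (the multi-seed
  # version runs in the acceptance suite)
  cfg <- tiny_config()
  sr <- make_reference(cfg, 31)
  tr <- simulate_truth(sr, cfg, 32)
  raw <- simulate_callers(tr, sr, cfg, 33)
  un <- merge_union(lapply(raw, normalize_callset, ref_seqs = sr$reference),
                    sr$targets)
  truth_keys <- indel_key(tr$loci)
  cov <- consensus_covariates(un, sr$reference)
  m <- train_consensus_model(label_training(cov, truth_keys), seed = 34)
  cons <- apply_consensus(un, m, sr$reference, 0.4)
  fdr_union <- mean(!(un$records$key %in% truth_keys))
  fdr_cons <- mean(!(cons$records$key %in% truth_keys))
  expect_lt(fdr_cons, fdr_union)
  tp_union <- sum(un$records$key %in% truth_keys)
  tp_cons <- sum(cons$records$key %in% truth_keys)
  expect_gte(tp_cons / tp_union, 0.7)
})
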