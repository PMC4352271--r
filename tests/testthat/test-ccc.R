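test_that("smallest_motif finds the minimal tiling unit", {
  expect_identical(smallest_motif("AGAG"), "AG")
  expect_identical(smallest_motif("AAA"), "A")
  expect_identical(smallest_motif("AGC"), "AGC")
  expect_identical(smallest_motif(c("ACACAC", "GGGG", "ACGACG")),
                   c("AC", "G", "ACG"))
  expect_error(smallest_motif("AGN"), "A,C,G,T")
  expect_error(smallest_motif(""), "non-empty")
})

test_that("copy-count classification matches the slippage definition", {
  ref <- c(chr1 = "GGATTGCAGCAGTCCAAGGG")
  #                12345678901234567890
  # T inserted next to the T run at 4-5: homopolymer expansion
  ins_t <- indel_records("chr1", 4L, "T", "TT")
  # CAG deleted from the CAGCAG doublet at 7-12: one copy remains
  del_cag <- indel_records("chr1", 6L, "GCAG", "G")
  # GTC inserted at 15: neither neighbor 3-mer is GTC
  ins_gtc <- indel_records("chr1", 15L, "C", "CGTC")
  out <- classify_ccc(dplyr::bind_rows(ins_t, del_cag, ins_gtc), ref)
  expect_identical(out$ccc, c(TRUE, TRUE, FALSE))
  expect_identical(out$motif, c("T", "CAG", "GTC"))
  expect_false(any(out$ccc_ambiguous))
})

test_that("N in the inspected context yields NCCC with the ambiguity flag", {
  ref <- c(chr1 = "GGANTTTTAG")
  rec <- indel_records("chr1", 4L, "N", "NT")  # left context is N
  rec$seq <- "T"
  out <- classify_ccc(rec, ref)
  expect_false(out$ccc)
  expect_true(out$ccc_ambiguous)
})

test_that("classification is invariant under left alignment", {
  withr::local_seed(13)
  chromstr <- random_refstr(5000, runs = 60L)
  ref <- c(chr1 = chromstr)
  for (i in 1:200) {
    ri <- random_indel(chromstr, max_len = 6L)
    rec <- left_align(indel_records("chr1", ri$pos, ri$ref, ri$alt), ref)
    shifted <- indelcons:::right_shift(rec, ref)
    realigned <- left_align(shifted, ref)
    expect_identical(classify_ccc(realigned, ref)$ccc, classify_ccc(rec, ref)$ccc)
  }
})

test_that("classification agrees with the exhaustive tandem-array oracle", {
  withr::local_seed(14)
  cfg <- tiny_config()
  sr <- make_reference(cfg, 41)
  recs <- simulate_random_indels(default_length_distribution(), sr$targets,
                                 sr$reference, n = 800, seed = 42)
  out <- classify_ccc(recs, sr$reference)
  orc <- vapply(seq_len(nrow(out)), function(i) {
    oracle_ccc(sr$reference[[out$chrom[i]]], out$pos[i], out$length[i], out$seq[i])
  }, logical(1))
  expect_identical(out$ccc, orc)
})

test_that("for deletions CCC implies a tandem array spanning the event", {
  withr::local_seed(15)
  cfg <- tiny_config()
  sr <- make_reference(cfg, 43)
  tr <- simulate_truth(sr, cfg, 44)
  dels <- classify_ccc(tr$loci[tr$loci$length < 0, ], sr$reference)
  ccc_dels <- dels[dels$ccc, ]
  for (i in seq_len(nrow(ccc_dels))) {
    chromstr <- sr$reference[[ccc_dels$chrom[i]]]
    expect_true(oracle_ccc(chromstr, ccc_dels$pos[i], ccc_dels$length[i],
                           ccc_dels$seq[i]))
  }
})

test_that("ccc_profile splits loci and individuals into the four classes", {
  ref <- c(chr1 = "GGATTGCAGCAGTCCAAGGGATCGGATCGGTAACCGTA")
  loci <- dplyr::bind_rows(
    indel_records("chr1", 4L, "T", "TT"),      # CCC ins
    indel_records("chr1", 16L, "A", "AA"),     # CCC ins (A run)
    indel_records("chr1", 22L, "TCGG", "T"),   # NCCC deletion
    indel_records("chr1", 30L, "GTAA", "G"))   # NCCC deletion
  cl <- classify_ccc(loci, ref)
  # a clean 2 CCC-ins / 2 NCCC-del configuration for the arithmetic
  stopifnot(identical(cl$ccc, c(TRUE, TRUE, FALSE, FALSE)))
  # S1 carries only the insertions, S2 carries every locus
  gm <- genotype_matrix(cl, c("S1", "S2"),
                        gt = matrix(c(1L, 1L, 0L, 0L, 1L, 1L, 1L, 1L), 4, 2))
  prof <- ccc_profile(gm)
  expect_equal(prof$population,
               c(ccc_ins = 50, nccc_ins = 0, ccc_del = 0, nccc_del = 50))
  # an individual carrying every locus reproduces the population split,
  # so the individual average is the mean of 100/0/0/0 and 50/0/0/50
  expect_equal(prof$individual,
               c(ccc_ins = 75, nccc_ins = 0, ccc_del = 0, nccc_del = 25))
  expect_error(ccc_profile(subset_loci(gm, integer(0))), "empty")
})

test_that("planted CCC fractions are recovered from the truth set", {
  cfg <- tiny_config(ccc_fraction = 0.6)
  sr <- make_reference(cfg, 51)
  tr <- simulate_truth(sr, cfg, 52)
  cl <- classify_ccc(tr$loci, sr$reference)
  expect_identical(cl$ccc, tr$loci$ccc_planted)
  se <- sqrt(0.6 * 0.4 / nrow(cl))
  expect_lt(abs(mean(cl$ccc) - 0.6), 3 * se + 1e-9)
})

test_that("random INDEL sets reproduce the requested length histogram", {
  cfg <- tiny_config()
  sr <- make_reference(cfg, 61)
  ld <- default_length_distribution()
  recs <- simulate_random_indels(ld, sr$targets, sr$reference, n = 10000, seed = 62)
  obs <- table(factor(recs$length, levels = names(ld)))
  gof <- suppressWarnings(chisq.test(as.numeric(obs), p = as.numeric(ld)))
  expect_gt(gof$p.value, 0.01)
  # determinism and the empty draw
  again <- simulate_random_indels(ld, sr$targets, sr$reference, n = 50, seed = 63)
  again2 <- simulate_random_indels(ld, sr$targets, sr$reference, n = 50, seed = 63)
  expect_identical(again, again2)
  none <- simulate_random_indels(ld, sr$targets, sr$reference, n = 0, seed = 1)
  expect_identical(nrow(none), 0L)
})
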