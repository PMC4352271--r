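test_that("signed_length signs insertions and deletions and rejects non-indels", {
  expect_identical(signed_length("A", "AT"), 1L)
  expect_identical(signed_length("ACAG", "A"), -3L)
  expect_error(signed_length("A", "A"), "not an INDEL")
  expect_error(signed_length("A", "G"), "not an INDEL")
  expect_error(signed_length("", "A"), "empty")
  expect_error(signed_length("A", "AX"), "A,C,G,T,N")
  # antisymmetry under swapping ref/alt
  for (i in 1:20) {
    r <- random_refstr(20)
    a <- substr(r, 1, sample(1:19, 1))
    if (nchar(a) == nchar(r)) next
    expect_identical(signed_length(r, a), -signed_length(a, r))
  }
})

test_that("frameshift status follows length mod 3", {
  expect_false(is_frameshift(3L))
  expect_true(is_frameshift(1L))
  expect_false(is_frameshift(-84L))
  expect_identical(is_frameshift(c(-2L, -3L, 4L, 6L)), c(TRUE, FALSE, TRUE, FALSE))
  expect_error(is_frameshift(0L), "non-zero")
})

test_that("indel_records enforces the pure-INDEL contract", {
  r <- indel_records("chr1", 10L, "A", "ATT")
  expect_identical(r$length, 2L)
  expect_identical(r$seq, "TT")
  expect_error(indel_records("chr1", 10L, "AC", "ATT"), "anchor")
  expect_error(indel_records("chr1", 10L, "ACG", "ATT"), "INDEL")
  expect_error(indel_records("chr1", 10L, "A", paste0("A", strrep("T", 100))),
               "below 100")
})

test_that("left alignment shifts a homopolymer deletion to the run start", {
  ref <- c(chr1 = "ACTTTG")
  # deletion of one T anchored at the rightmost T of the TTT run
  rec <- indel_records("chr1", 4L, "TT", "T")
  out <- left_align(rec, ref)
  orc <- oracle_left_align(ref[["chr1"]], 4L, "TT", "T")
  expect_identical(out$pos, as.integer(orc[["pos"]]))
  expect_identical(out$ref, orc[["ref"]])
  expect_identical(out$alt, orc[["alt"]])
  expect_identical(out$pos, 2L)  # anchored at C, immediately left of the run
  # already-leftmost record is unchanged (idempotence)
  again <- left_align(out, ref)
  expect_identical(again, out)
})

test_that("left alignment shifts an inserted repeat unit to the leftmost anchor", {
  ref <- c(chr1 = "CAGAGT")
  # "AG" inserted after the second AG copy
  rec <- indel_records("chr1", 5L, "G", "GAG")
  out <- left_align(rec, ref)
  orc <- oracle_left_align(ref[["chr1"]], 5L, "G", "GAG")
  expect_identical(out$pos, as.integer(orc[["pos"]]))
  expect_identical(apply_variant(ref[["chr1"]], out$pos, out$ref, out$alt),
                   apply_variant(ref[["chr1"]], 5L, "G", "GAG"))
  expect_identical(out$pos, 1L)
})

test_that("left alignment preserves the alternate haplotype on fuzzed records", {
  withr::local_seed(42)
  chromstr <- random_refstr(4000, runs = 30L)
  ref <- c(chr1 = chromstr)
  for (i in 1:300) {
    ri <- random_indel(chromstr)
    rec <- indel_records("chr1", ri$pos, ri$ref, ri$alt)
    out <- left_align(rec, ref)
    expect_identical(
      apply_variant(chromstr, out$pos, out$ref, out$alt),
      apply_variant(chromstr, ri$pos, ri$ref, ri$alt))
    out2 <- left_align(out, ref)
    expect_identical(out2$pos, out$pos)
    orc <- oracle_left_align(chromstr, ri$pos, ri$ref, ri$alt)
    expect_identical(out$pos, as.integer(orc[["pos"]]))
  }
})

test_that("left alignment raises on a reference mismatch", {
  ref <- c(chr1 = "ACGTACGT")
  rec <- indel_records("chr1", 3L, "GA", "G")  # reference has GT at 3-4
  expect_error(left_align(rec, ref), "reference mismatch")
})

test_that("complex events split into SNPs plus at most one pure INDEL", {
  # pure SNP: no INDEL component
  out <- split_complex("chr1", 5L, "ACGT", "ATGT")
  expect_identical(out$type, "SNP")
  # already-simple insertion
  out <- split_complex("chr1", 5L, "A", "ATT")
  expect_identical(out$type, "INS")
  expect_identical(out$pos, 5L)
  expect_identical(out$alt, "ATT")
  # substitution folded into a deletion
  chromstr <- paste0("GGGG", "CTTG", "AAAA")
  out <- split_complex("chr1", 5L, "CTTG", "CAG")
  expect_setequal(out$type, c("SNP", "DEL"))
  expect_identical(sum(out$type != "SNP"), 1L)
  expect_identical(apply_components(chromstr, out),
                   apply_variant(chromstr, 5L, "CTTG", "CAG"))
})

test_that("split_complex reconstructs the haplotype on fuzzed complex variants", {
  withr::local_seed(7)
  for (i in 1:200) {
    chromstr <- random_refstr(60)
    pos <- sample(5:30, 1)
    w <- sample(1:8, 1)
    ref <- substr(chromstr, pos, pos + w - 1L)
    alt <- paste(sample(c("A", "C", "G", "T"), sample(1:8, 1), replace = TRUE),
                 collapse = "")
    if (ref == alt) next
    out <- split_complex("chr1", pos, ref, alt)
    expect_lte(sum(out$type != "SNP"), 1L)
    expect_identical(apply_components(chromstr, out),
                     apply_variant(chromstr, pos, ref, alt))
  }
})

test_that("indel keys identify alleles across caller representations", {
  withr::local_seed(11)
  chromstr <- random_refstr(2000, runs = 20L)
  ref <- c(chr1 = chromstr)
  # two right-shifted encodings of the same allele get one key
  for (i in 1:50) {
    ri <- random_indel(chromstr)
    rec <- left_align(indel_records("chr1", ri$pos, ri$ref, ri$alt), ref)
    shifted <- indelcons:::right_shift(rec, ref)
    back <- left_align(shifted, ref)
    expect_identical(indel_key(back), indel_key(rec))
  }
  a <- indel_records(c("chr1", "chr2"), c(5L, 5L), c("A", "A"), c("AT", "AT"))
  expect_false(indel_key(a)[1] == indel_key(a)[2])
  b <- indel_records("chr1", c(5L, 5L), c("A", "A"), c("AT", "AG"))
  expect_false(indel_key(b)[1] == indel_key(b)[2])
})

test_that("autosome filter accepts chr1-chr22 and rejects the rest", {
  expect_true(all(is_autosome(c("chr1", "22", "chr22", "9"))))
  expect_false(any(is_autosome(c("chrX", "chrY", "chrM", "X", "chr23", "GL0001"))))
})
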