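# Independent brute-force oracles used to freeze expected values.
# These deliberately avoid the package's own shifting/adjacency code:
# everything is decided by haplotype identity or exhaustive scanning.

# Leftmost equivalent anchor by exhaustive enumeration: try every anchor
# q <= pos, derive the candidate allele from the alternate haplotype, and
# keep the smallest q that reproduces the identical haplotype.
oracle_left_align <- function(chromstr, pos, ref, alt, max_shift = 300L) {
  H <- apply_variant(chromstr, pos, ref, alt)
  L <- nchar(alt) - nchar(ref)
  best <- c(pos = pos, ref = ref, alt = alt)
  for (q in seq(max(1L, pos - max_shift), pos)) {
    anchor <- substr(chromstr, q, q)
    if (L > 0L) {
      s <- substr(H, q + 1L, q + L)
      cand_ref <- anchor
      cand_alt <- paste0(anchor, s)
    } else {
      s <- substr(chromstr, q + 1L, q - L)
      if (nchar(s) < -L) next
      cand_ref <- paste0(anchor, s)
      cand_alt <- anchor
    }
    if (identical(apply_variant(chromstr, q, cand_ref, cand_alt), H)) {
      return(c(pos = q, ref = cand_ref, alt = cand_alt))
    }
  }
  best
}

# Exhaustive tandem-array scan: an event is a copy-count change iff at
# least one further copy of the allele's smallest motif tiles the
# reference immediately beyond either end of the event.
oracle_ccc <- function(chromstr, pos, len, seq) {
  m <- smallest_motif(seq)
  lm <- nchar(m)
  copies_left <- 0L
  q <- pos
  while (q - lm + 1L >= 1L && substr(chromstr, q - lm + 1L, q) == m) {
    copies_left <- copies_left + 1L
    q <- q - lm
  }
  copies_right <- 0L
  q <- pos + 1L + (if (len < 0L) -len else 0L)
  while (q + lm - 1L <= nchar(chromstr) && substr(chromstr, q, q + lm - 1L) == m) {
    copies_right <- copies_right + 1L
    q <- q + lm
  }
  copies_left + copies_right >= 1L
}

# Apply split_complex components jointly (INDEL first, then SNPs, whose
# positions always lie at or before the indel anchor).
apply_components <- function(chromstr, components) {
  H <- chromstr
  ind <- components[components$type != "SNP", ]
  if (nrow(ind) == 1L) H <- apply_variant(H, ind$pos, ind$ref, ind$alt)
  snps <- components[components$type == "SNP", ]
  if (nrow(snps)) {
    for (i in order(snps$pos, decreasing = TRUE)) {
      H <- apply_variant(H, snps$pos[i], snps$ref[i], snps$alt[i])
    }
  }
  H
}

# Random reference string (optionally with a few planted repeat runs)
random_refstr <- function(n, runs = 0L) {
  s <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  if (runs > 0L) {
    for (i in seq_len(runs)) {
      w <- sample(4:10, 1L)
      st <- sample.int(n - w - 2L, 1L) + 1L
      s[st:(st + w - 1L)] <- sample(c("A", "C", "G", "T"), 1L)
    }
  }
  paste(s, collapse = "")
}

# Random pure indel consistent with a reference string
random_indel <- function(chromstr, max_len = 8L) {
  n <- nchar(chromstr)
  L <- sample(c(-max_len:-1, 1:max_len), 1L)
  pos <- sample(seq(5L, n - max_len - 5L), 1L)
  anchor <- substr(chromstr, pos, pos)
  if (L < 0L) {
    s <- substr(chromstr, pos + 1L, pos - L)
    list(pos = pos, ref = paste0(anchor, s), alt = anchor)
  } else {
    s <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    list(pos = pos, ref = anchor, alt = paste0(anchor, s))
  }
}

tiny_config <- function(...) {
  sim_config(ref_length = 1e5, n_true_indels = 250, n_samples = 20, ...)
}
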