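#' Simulation configuration for the synthetic pipeline inputs
#'
#' Bundles every tunable of the synthetic-data generator. The defaults
#' describe the study conditions the pipeline is exercised under: an
#' exome-like reference of 1 Mb with planted homopolymer/tandem tracts,
#' 50 diploid samples, 2,000 true short INDELs with a length distribution
#' heavy at 1 bp and enriched at multiples of three (deletions outnumber
#' insertions 1.5:1), a 60% change-in-copy-count fraction, a rare-skewed
#' neutral site-frequency spectrum, and three callers of decreasing
#' sensitivity whose false-positive loads are derived so that the union
#' call set carries a planted FDR of about 0.35.
#'
#' @param ref_length Total reference length in bp across chromosomes.
#' @param n_chrom Number of autosomes to emit (`chr1`, `chr2`, ...).
#' @param repeat_density Planted repeat tracts per kb.
#' @param homopolymer_frac Fraction of tracts that are homopolymers (the
#'   rest are short tandem repeats with 2-4 bp motifs).
#' @param target_fraction Fraction of the reference covered by
#'   exome-like target intervals.
#' @param exon_bp Width of each target interval.
#' @param n_samples Number of diploid samples.
#' @param n_true_indels Number of true INDEL loci.
#' @param length_distribution Named numeric vector: names are signed
#'   lengths, values are weights.
#' @param ccc_fraction Fraction of true INDELs planted as copy-count
#'   changes (slippage-like events).
#' @param sfs_weights Weights over alternate allele counts `1..2N-1`;
#'   `NULL` uses the neutral `1/i` spectrum.
#' @param sensitivities Per-caller probability of reporting a true site.
#' @param target_union_fdr Planted false fraction of the union; per-caller
#'   false-positive counts are derived from it.
#' @param repeat_fp_bias Probability that a caller false positive is
#'   placed adjacent to a repeat tract rather than uniformly.
#' @param qual_tp,qual_fp Lognormal `c(meanlog, sdlog)` parameters of
#'   caller quality scores for true and false calls.
#' @param depth_mean Mean per-sample read depth (Poisson).
#' @param seq_error Per-read sequencing error rate for genotype evidence.
#' @param artifact_ratio Beta `c(shape1, shape2)` of the variant-read
#'   ratio observed at false sites in their claimed carriers.
#' @param right_shift_frac Fraction of caller records emitted in a
#'   right-shifted (non-canonical) representation.
#' @param complex_frac Fraction of caller records emitted as complex
#'   events (an adjacent substitution folded into the allele strings).
#' @param validation_depth Amplicon read depth for validation evidence.
#' @param validation_error Per-read error rate of the validation assay.
#' @param design_fail_rate Fraction of validation assays that fail by
#'   design/PCR.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(ref_length = 1e6,
                       n_chrom = 2L,
                       repeat_density = 3,
                       homopolymer_frac = 0.7,
                       target_fraction = 0.5,
                       exon_bp = 200L,
                       n_samples = 50L,
                       n_true_indels = 2000L,
                       length_distribution = default_length_distribution(),
                       ccc_fraction = 0.6,
                       sfs_weights = NULL,
                       sensitivities = c(atlas = 0.85, freebayes = 0.80, gatk = 0.75),
                       target_union_fdr = 0.35,
                       repeat_fp_bias = 0.5,
                       qual_tp = c(5.0, 0.7),
                       qual_fp = c(3.4, 0.7),
                       depth_mean = 60,
                       seq_error = 0.01,
                       artifact_ratio = c(2, 8),
                       right_shift_frac = 0.25,
                       complex_frac = 0.05,
                       validation_depth = 100L,
                       validation_error = 0.005,
                       design_fail_rate = 0.05) {
  stopifnot(ref_length >= 1e4, n_chrom >= 1L,
            target_fraction > 0, target_fraction <= 1,
            ccc_fraction >= 0, ccc_fraction <= 1,
            all(sensitivities > 0), all(sensitivities <= 1),
            target_union_fdr >= 0, target_union_fdr < 1)
  ld <- length_distribution / sum(length_distribution)
  if (any(as.integer(names(ld)) == 0L)) stop("length distribution may not contain 0")
  structure(list(
    ref_length = ref_length, n_chrom = as.integer(n_chrom),
    repeat_density = repeat_density, homopolymer_frac = homopolymer_frac,
    target_fraction = target_fraction, exon_bp = as.integer(exon_bp),
    n_samples = as.integer(n_samples), n_true_indels = as.integer(n_true_indels),
    length_distribution = ld, ccc_fraction = ccc_fraction,
    sfs_weights = sfs_weights, sensitivities = sensitivities,
    target_union_fdr = target_union_fdr, repeat_fp_bias = repeat_fp_bias,
    qual_tp = qual_tp, qual_fp = qual_fp,
    depth_mean = depth_mean, seq_error = seq_error,
    artifact_ratio = artifact_ratio,
    right_shift_frac = right_shift_frac, complex_frac = complex_frac,
    validation_depth = as.integer(validation_depth),
    validation_error = validation_error,
    design_fail_rate = design_fail_rate
  ), class = "sim_config")
}

#' Default signed-length distribution of true INDELs
#'
#' Power-law decay heavy at 1 bp, a 2x enrichment at multiples of three
#' (in-frame events persist under selection) and a 1.5x excess of
#' deletions over insertions, over lengths -12..12.
#'
#' @return Named numeric vector of normalized weights.
#' @export
default_length_distribution <- function() {
  lens <- c(-12:-1, 1:12)
  w <- abs(lens)^-1.8 * ifelse(abs(lens) %% 3 == 0, 2, 1) *
    ifelse(lens < 0, 1.5, 1)
  stats::setNames(w / sum(w), lens)
}

#' Generate a synthetic reference with planted repeat tracts
#'
#' Draws an i.i.d. uniform background and overwrites it with homopolymer
#' and short-tandem-repeat tracts at the configured density, then lays
#' exome-like target intervals covering the configured fraction of each
#' chromosome. Deterministic given `(config, seed)`.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A list of class `sim_reference`: `reference` (named character
#'   vector), `targets` ([GenomicRanges::GRanges]) and `tracts` (tibble
#'   `chrom`, `start`, `end`, `motif` -- the planted repeat registry).
#' @export
make_reference <- function(config, seed) {
  withr::local_seed(seed)
  chr_len <- as.integer(config$ref_length / config$n_chrom)
  chroms <- paste0("chr", seq_len(config$n_chrom))
  bases <- c("A", "C", "G", "T")
  seqs <- character(config$n_chrom)
  tracts <- list()
  n_tracts_per_chrom <- round(config$repeat_density * chr_len / 1000)
  for (ci in seq_along(chroms)) {
    s <- sample(bases, chr_len, replace = TRUE)
    if (n_tracts_per_chrom > 0) {
      reg <- vector("list", n_tracts_per_chrom)
      taken <- raw(chr_len)  # tracts must not overwrite one another
      for (t in seq_len(n_tracts_per_chrom)) {
        if (stats::runif(1) < config$homopolymer_frac) {
          motif <- sample(bases, 1L)
          span <- sample(6:14, 1L)
          unit <- motif
        } else {
          repeat {
            m <- sample(2:4, 1L)
            unit <- paste(sample(bases, m, replace = TRUE), collapse = "")
            if (smallest_motif(unit) == unit) break  # primitive motifs only
          }
          span <- nchar(unit) * sample(3:6, 1L)
          motif <- unit
        }
        start <- NA_integer_
        for (try in 1:50) {
          cand <- sample.int(chr_len - span - 100L, 1L) + 50L
          win <- cand:(cand + span + 1L)
          if (all(taken[win] == as.raw(0))) {
            taken[max(1L, cand - 1L):(cand + span + 1L)] <- as.raw(1)
            start <- cand
            break
          }
        }
        if (is.na(start)) {
          stop("repeat density too high: unable to place non-overlapping tracts")
        }
        tile <- strsplit(paste(rep(unit, ceiling(span / nchar(unit))), collapse = ""),
                         "", fixed = TRUE)[[1]][seq_len(span)]
        s[start:(start + span - 1L)] <- tile
        reg[[t]] <- tibble::tibble(chrom = chroms[ci], start = start,
                                   end = start + span - 1L, motif = motif)
      }
      tracts[[ci]] <- dplyr::bind_rows(reg)
    }
    seqs[ci] <- paste(s, collapse = "")
  }
  names(seqs) <- chroms
  period <- max(as.integer(round(config$exon_bp / config$target_fraction)),
                config$exon_bp)
  starts <- seq(101L, chr_len - config$exon_bp - 100L, by = period)
  targets <- GenomicRanges::GRanges(
    rep(chroms, each = length(starts)),
    IRanges::IRanges(start = rep(starts, times = length(chroms)),
                     width = config$exon_bp))
  structure(list(reference = seqs, targets = targets,
                 tracts = if (length(tracts)) dplyr::bind_rows(tracts)
                          else tibble::tibble(chrom = character(), start = integer(),
                                              end = integer(), motif = character())),
            class = "sim_reference")
}

#' Simulate the truth call set (sites, CCC status, genotypes)
#'
#' Places `n_true_indels` true events inside the target regions: the
#' configured CCC fraction is planted as expansions or contractions of
#' repeat context (insertions duplicate the adjacent reference bases;
#' deletions contract a planted tract while leaving at least one motif
#' copy), the rest are verified non-CCC by rejection against
#' [classify_ccc()]. Each site receives an alternate allele count from
#' the configured site-frequency spectrum and per-sample diploid
#' genotypes by drawing that many chromosomes without replacement.
#' Output records are left-aligned and key-deduplicated.
#'
#' @param simref A `sim_reference` from [make_reference()].
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A [genotype_matrix()]; `loci` carries a logical `ccc_planted`
#'   column.
#' @export
simulate_truth <- function(simref, config, seed) {
  withr::local_seed(seed)
  ref_seqs <- simref$reference
  n <- config$n_true_indels
  lens <- sample(as.integer(names(config$length_distribution)), n,
                 replace = TRUE, prob = config$length_distribution)
  want_ccc <- stats::runif(n) < config$ccc_fraction
  occ <- occupancy_new(ref_seqs)
  in_t <- anchor_in_targets(
    tibble::tibble(chrom = simref$tracts$chrom, pos = simref$tracts$start),
    simref$targets)
  tract_pool <- simref$tracts[in_t, ]
  tract_used <- rep(FALSE, nrow(tract_pool))
  chrom <- character(n); pos <- integer(n); seq <- character(n)
  tstarts <- GenomicRanges::start(simref$targets)
  tends <- GenomicRanges::end(simref$targets)
  tchroms <- as.character(GenomicRanges::seqnames(simref$targets))
  twidths <- tends - tstarts + 1L
  rand_target_pos <- function() {
    iv <- sample.int(length(twidths), 1L, prob = twidths)
    list(chrom = tchroms[iv], pos = tstarts[iv] + sample.int(twidths[iv], 1L) - 1L)
  }
  for (i in seq_len(n)) {
    L <- lens[i]
    placed <- FALSE
    tries <- 0L
    while (!placed) {
      tries <- tries + 1L
      if (tries > 500L) stop("unable to place event ", i,
                             ": repeat density too low for the requested CCC fraction?")
      if (want_ccc[i] && L < 0L) {
        # contract a planted tract, leaving >= 1 motif copy adjacent
        mlen <- nchar(tract_pool$motif)
        span <- tract_pool$end - tract_pool$start + 1L
        cand <- which(!tract_used & (-L) %% mlen == 0L & span >= (-L) + mlen)
        if (length(cand) == 0L) { lens[i] <- L <- resample_length(config); next }
        tr <- cand[sample.int(length(cand), 1L)]
        p <- tract_pool$start[tr] - 1L
        s <- substr(ref_seqs[[tract_pool$chrom[tr]]], p + 1L, p - L)
        if (!occupancy_claim(occ, tract_pool$chrom[tr], p, -L)) {
          tract_used[tr] <- TRUE  # area taken by another event; retire it
          next
        }
        tract_used[tr] <- TRUE
        chrom[i] <- tract_pool$chrom[tr]; pos[i] <- p; seq[i] <- s
        placed <- TRUE
      } else if (want_ccc[i] && L > 0L) {
        # tandem duplication of the adjacent reference bases
        rp <- rand_target_pos()
        s <- substr(ref_seqs[[rp$chrom]], rp$pos + 1L, rp$pos + L)
        if (nchar(s) < L || grepl("N", s, fixed = TRUE)) next
        if (!occupancy_claim(occ, rp$chrom, rp$pos, L)) next
        chrom[i] <- rp$chrom; pos[i] <- rp$pos; seq[i] <- s
        placed <- TRUE
      } else {
        rp <- rand_target_pos()
        if (L < 0L) {
          s <- substr(ref_seqs[[rp$chrom]], rp$pos + 1L, rp$pos - L)
          if (nchar(s) < -L) next
        } else {
          s <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                     collapse = "")
        }
        cand <- indel_records(rp$chrom, rp$pos,
                              ref = if (L < 0L) paste0(anchor_base(ref_seqs, rp$chrom, rp$pos), s)
                                    else anchor_base(ref_seqs, rp$chrom, rp$pos),
                              alt = if (L < 0L) anchor_base(ref_seqs, rp$chrom, rp$pos)
                                    else paste0(anchor_base(ref_seqs, rp$chrom, rp$pos), s))
        cand$seq <- s
        # classification is defined on the canonical (left-aligned) form
        if (classify_ccc(left_align(cand, ref_seqs), ref_seqs)$ccc) next
        if (!occupancy_claim(occ, rp$chrom, rp$pos, abs(L))) next
        chrom[i] <- rp$chrom; pos[i] <- rp$pos; seq[i] <- s
        placed <- TRUE
      }
    }
  }
  anchor <- mapply(anchor_base, chrom = chrom, pos = pos,
                   MoreArgs = list(ref_seqs = ref_seqs), USE.NAMES = FALSE)
  ins <- lens > 0L
  loci <- indel_records(chrom, pos,
                        ref = ifelse(ins, anchor, paste0(anchor, seq)),
                        alt = ifelse(ins, paste0(anchor, seq), anchor))
  loci$ccc_planted <- want_ccc
  loci <- left_align(loci, ref_seqs)
  keep <- !duplicated(indel_key(loci))
  loci <- loci[keep, ]
  # site-frequency spectrum and genotypes
  n_chr <- 2L * config$n_samples
  w <- config$sfs_weights
  if (is.null(w)) w <- 1 / seq_len(n_chr - 1L)
  counts <- sample(seq_len(n_chr - 1L), nrow(loci), replace = TRUE, prob = w)
  gt <- t(vapply(counts, function(cc) {
    chrs <- sample.int(n_chr, cc)
    tabulate(((chrs - 1L) %/% 2L) + 1L, nbins = config$n_samples)
  }, integer(config$n_samples)))
  ord <- order(loci$chrom, loci$pos)
  samples <- sprintf("S%03d", seq_len(config$n_samples))
  genotype_matrix(loci[ord, ], samples, gt[ord, , drop = FALSE])
}

anchor_base <- function(ref_seqs, chrom, pos) substr(ref_seqs[[chrom]], pos, pos)

resample_length <- function(config) {
  sample(as.integer(names(config$length_distribution)), 1L,
         prob = config$length_distribution)
}

# bitmap of claimed positions, +/- 5 bp guard, so events never collide
occupancy_new <- function(ref_seqs) {
  e <- new.env(parent = emptyenv())
  for (ch in names(ref_seqs)) assign(ch, raw(nchar(ref_seqs[[ch]])), envir = e)
  e
}

occupancy_claim <- function(occ, chrom, pos, span) {
  v <- get(chrom, envir = occ)
  lo <- max(1L, pos - 5L)
  hi <- min(length(v), pos + span + 5L)
  if (any(v[lo:hi] != as.raw(0))) return(FALSE)
  v[lo:hi] <- as.raw(1)
  assign(chrom, v, envir = occ)
  TRUE
}
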