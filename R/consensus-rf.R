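COVARIATE_NAMES <- c("n_callers", "norm_qual_mean", "site_depth",
                     "variant_read_ratio", "homopolymer_run", "abs_length")

#' Longest homopolymer run near an INDEL anchor
#'
#' Maximum run length of any single base in the reference context
#' `pos - flank .. pos + flank` around each record's anchor. Homopolymer
#' tracts are the dominant context of slippage-driven INDEL artifacts and
#' the run length is one of the six consensus covariates.
#'
#' @param records An [indel_records()] tibble.
#' @param ref_seqs Reference sequences.
#' @param flank Context half-width in bp (default 10).
#' @return Integer vector of maximum run lengths.
#' @export
homopolymer_run <- function(records, ref_seqs, flank = 10L) {
  vapply(seq_len(nrow(records)), function(i) {
    w <- ref_window(ref_seqs, records$chrom[i],
                    records$pos[i] - flank, records$pos[i] + flank)
    r <- rle(strsplit(w, "", fixed = TRUE)[[1]])
    max(r$lengths[r$values != "N"], 0L)
  }, integer(1))
}

#' Assemble the 6-covariate table for consensus classification
#'
#' The classifier consumes, per union allele: the number of supporting
#' call sets, the mean rank-normalized caller quality, mean depth and
#' variant-read ratio over carrier samples, the local homopolymer run
#' length, and the absolute allele length.
#'
#' @param union A `union_set` from [merge_union()].
#' @param ref_seqs Reference sequences.
#' @return A tibble with columns `key` plus the six covariates.
#' @export
consensus_covariates <- function(union, ref_seqs) {
  rec <- union$records
  tibble::tibble(
    key = rec$key,
    n_callers = as.numeric(rec$n_callers),
    norm_qual_mean = rec$norm_qual_mean,
    site_depth = rec$site_depth,
    variant_read_ratio = rec$variant_read_ratio,
    homopolymer_run = as.numeric(homopolymer_run(rec, ref_seqs)),
    abs_length = as.numeric(abs(rec$length))
  )
}

#' Label union alleles against a truth call set
#'
#' Union alleles whose [indel_key()] appears in the truth set are labeled
#' true positives (1); all others false positives (0). This mirrors
#' training against an orthogonal genome-sequencing truth overlap.
#'
#' @param covariates Covariate table from [consensus_covariates()].
#' @param truth_keys Character vector of truth-set keys (left-aligned).
#' @return The covariate table with an integer `label` column.
#' @export
label_training <- function(covariates, truth_keys) {
  if (length(truth_keys) == 0L) {
    warning("empty truth set: all labels 0; training will be refused")
  }
  covariates$label <- as.integer(covariates$key %in% truth_keys)
  covariates
}

#' Train the consensus random-forest classifier
#'
#' Fits a random forest over the six covariates; the consensus probability
#' of an allele is the fraction of trees voting "true". Training is
#' deterministic for a fixed seed. Out-of-bag probabilities are stored so
#' that the very table the model was trained on can be scored without
#' resubstitution bias.
#'
#' @param labeled Labeled covariate table from [label_training()].
#' @param seed Integer seed.
#' @param n_trees Number of trees (default 500).
#' @return A `consensus_model`: the fitted forest plus metadata (covariate
#'   names, seed, label counts, out-of-bag probabilities keyed by allele).
#' @export
train_consensus_model <- function(labeled, seed, n_trees = 500L) {
  stopifnot(n_trees >= 1L)
  tab <- table(labeled$label)
  if (length(tab) < 2L) {
    stop("training labels contain a single class; need both true and false examples")
  }
  x <- as.data.frame(labeled[COVARIATE_NAMES])
  y <- factor(labeled$label, levels = c(0L, 1L))
  withr::local_seed(seed)
  fit <- randomForest::randomForest(x = x, y = y, ntree = n_trees)
  oob <- fit$votes[, "1"]
  structure(list(
    forest = fit, covariates = COVARIATE_NAMES, seed = seed,
    n_trees = n_trees, label_counts = as.integer(tab),
    oob_prob = stats::setNames(as.numeric(oob), labeled$key)
  ), class = "consensus_model")
}

#' @export
print.consensus_model <- function(x, ...) {
  cat(sprintf("consensus_model: %d trees over %s\n", x$n_trees,
              paste(x$covariates, collapse = ", ")))
  cat(sprintf("  training: %d false / %d true, seed %d\n",
              x$label_counts[1], x$label_counts[2], x$seed))
  invisible(x)
}

#' Consensus probabilities for a covariate table
#'
#' For alleles that were part of the model's training table (matched by
#' key) the stored out-of-bag probability is used; anything else is scored
#' with the full forest.
#'
#' @param model A `consensus_model`.
#' @param covariates Covariate table from [consensus_covariates()].
#' @return Numeric vector of probabilities in [0, 1].
#' @export
consensus_probability <- function(model, covariates) {
  p <- rep(NA_real_, nrow(covariates))
  hit <- match(covariates$key, names(model$oob_prob))
  p[!is.na(hit)] <- model$oob_prob[hit[!is.na(hit)]]
  todo <- is.na(p)
  if (any(todo)) {
    nd <- as.data.frame(covariates[todo, model$covariates])
    p[todo] <- stats::predict(model$forest, newdata = nd, type = "prob")[, "1"]
  }
  p
}

#' Apply the consensus probability cutoff
#'
#' Retains union alleles whose probability of being a true INDEL is at
#' least `threshold`; alleles with probability below the cutoff are not
#' included in the consensus (the boundary value itself is retained).
#'
#' @param union A `union_set`.
#' @param model A `consensus_model`.
#' @param ref_seqs Reference sequences (for covariates).
#' @param threshold Probability cutoff in [0, 1]; default 0.4.
#' @return The `union_set` restricted to retained alleles, with a `prob`
#'   column appended to `records`.
#' @export
apply_consensus <- function(union, model, ref_seqs, threshold = 0.4) {
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  cov <- consensus_covariates(union, ref_seqs)
  p <- consensus_probability(model, cov)
  keep <- p >= threshold
  out <- union
  out$records <- union$records[keep, ]
  out$records$prob <- p[keep]
  out$genotypes <- subset_loci(union$genotypes, keep)
  out
}

#' Regenotype sites under a binomial read model
#'
#' Assigns each (site, sample) the maximum-likelihood diploid genotype
#' given variant reads `v` of depth `d`: hom-ref emits variant reads at
#' error rate `e`, het at 0.5, hom-alt at `1 - e`, with a flat prior.
#' Samples with zero depth are missing. Sites where no sample is called
#' non-reference after regenotyping are removed.
#'
#' @param gm A [genotype_matrix()] carrying `dp` and `vr` evidence for the
#'   sites to regenotype.
#' @param error Sequencing error rate `e` (default 0.02).
#' @return A `genotype_matrix` with re-called `gt` and empty loci dropped.
#' @export
regenotype <- function(gm, error = 0.02) {
  if (is.null(gm$dp) || is.null(gm$vr)) stop("regenotyping requires dp and vr evidence")
  d <- gm$dp
  v <- gm$vr
  miss <- is.na(d) | is.na(v) | d == 0L
  d[miss] <- 1L
  v[miss] <- 0L
  ll0 <- stats::dbinom(v, d, error, log = TRUE)
  ll1 <- stats::dbinom(v, d, 0.5, log = TRUE)
  ll2 <- stats::dbinom(v, d, 1 - error, log = TRUE)
  gt <- max.col(cbind(as.vector(ll0), as.vector(ll1), as.vector(ll2)),
                ties.method = "first") - 1L
  gt <- matrix(gt, nrow(d), ncol(d))
  gt[miss] <- NA_integer_
  called <- rowSums(gt > 0L, na.rm = TRUE) > 0L
  genotype_matrix(gm$loci, gm$samples, gt, gm$dp, gm$vr) |> subset_loci(called)
}
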