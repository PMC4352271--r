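#' Rank-normalize caller quality scores to [0, 1]
#'
#' Caller quality scales are incomparable and heavy-tailed, so the union
#' annotates each record with its empirical-CDF value within its own call
#' set: qualities are rank-transformed to `rank/n` in (0, 1], ties sharing
#' the mean rank. Records with missing quality are flagged and assigned
#' 0.5 (a median prior).
#'
#' @param qual Numeric vector of one caller's reported qualities.
#' @return Numeric vector of normalized qualities in (0, 1] (0.5 for
#'   missing input values).
#' @examples
#' normalize_qualities(c(10, 20, 30))  # 1/3 2/3 1
#' @export
normalize_qualities <- function(qual) {
  out <- rep(0.5, length(qual))
  ok <- !is.na(qual)
  if (any(ok)) out[ok] <- rank(qual[ok], ties.method = "average") / sum(ok)
  out
}

#' Merge normalized caller call sets into an annotated union
#'
#' Takes K caller call sets (each a [genotype_matrix()] whose loci are
#' already decomposed, complex-split and left-aligned) and produces one
#' record per distinct [indel_key()], restricted to autosomes and to loci
#' whose anchor base lies in the target regions. Each union record carries
#' the evidence covariates consumed by the consensus classifier:
#'
#' \describe{
#'   \item{n_callers}{number of call sets reporting the allele}
#'   \item{norm_qual_mean}{mean rank-normalized quality over supporting
#'     callers only}
#'   \item{site_depth}{mean total depth over carrier samples (pooled
#'     across supporting callers)}
#'   \item{variant_read_ratio}{pooled variant reads / pooled depth over
#'     carrier samples}
#' }
#'
#' Genotypes for the union come from the first supporting call set per
#' allele, so alleles unique to one caller keep that caller's genotypes.
#'
#' @param callsets Named list of [genotype_matrix()] objects, one per
#'   caller, loci carrying `qual`.
#' @param targets A [GenomicRanges::GRanges] of target intervals (or
#'   `NULL` for no target restriction).
#' @return A list of class `union_set`: `records` (loci tibble plus
#'   `key`, `callers`, `n_callers`, `norm_qual_mean`, `site_depth`,
#'   `variant_read_ratio`) and `genotypes` (a `genotype_matrix` over the
#'   union loci).
#' @export
merge_union <- function(callsets, targets = NULL) {
  if (length(callsets) == 0L) stop("no input call sets")
  if (is.null(names(callsets)) || any(!nzchar(names(callsets)))) {
    names(callsets) <- paste0("caller", seq_along(callsets))
  }
  samples <- callsets[[1]]$samples
  for (cs in callsets) {
    if (!identical(cs$samples, samples)) {
      stop("call sets must share an identical sample list")
    }
  }
  per <- lapply(names(callsets), function(nm) {
    cs <- callsets[[nm]]
    keep <- is_autosome(cs$loci$chrom)
    if (!is.null(targets)) keep <- keep & anchor_in_targets(cs$loci, targets)
    cs <- subset_loci(cs, keep)
    cw <- carrier_matrix(cs)
    dp <- if (is.null(cs$dp)) matrix(NA_real_, nrow(cw), ncol(cw)) else cs$dp
    vr <- if (is.null(cs$vr)) matrix(NA_real_, nrow(cw), ncol(cw)) else cs$vr
    dp[!cw | is.na(dp)] <- NA_real_
    vr[!cw | is.na(vr)] <- NA_real_
    tibble::tibble(
      key = indel_key(cs$loci),
      caller = nm,
      nqual = normalize_qualities(cs$loci$qual),
      dp_sum = rowSums(dp, na.rm = TRUE),
      dp_n = rowSums(!is.na(dp)),
      vr_sum = rowSums(vr, na.rm = TRUE),
      idx = seq_len(nrow(cs$loci))
    )
  })
  names(per) <- names(callsets)
  ann <- dplyr::bind_rows(per)
  if (nrow(ann) == 0L) {
    stop("no autosomal in-target records in any call set")
  }
  agg <- ann |>
    dplyr::group_by(.data$key) |>
    dplyr::summarise(
      callers = paste(.data$caller, collapse = ","),
      n_callers = dplyr::n(),
      norm_qual_mean = mean(.data$nqual),
      site_depth = ifelse(sum(.data$dp_n) > 0,
                          sum(.data$dp_sum) / sum(.data$dp_n), 0),
      variant_read_ratio = ifelse(sum(.data$dp_sum) > 0,
                                  sum(.data$vr_sum) / sum(.data$dp_sum), 0),
      first_caller = .data$caller[1L],
      first_idx = .data$idx[1L],
      .groups = "drop"
    )
  # reconstruct the loci tibble and genotypes from each allele's first caller
  norm_sets <- lapply(names(callsets), function(nm) {
    cs <- callsets[[nm]]
    keep <- is_autosome(cs$loci$chrom)
    if (!is.null(targets)) keep <- keep & anchor_in_targets(cs$loci, targets)
    subset_loci(cs, keep)
  })
  names(norm_sets) <- names(callsets)
  take <- function(field) {
    mats <- mapply(function(nm, i) {
      m <- norm_sets[[nm]][[field]]
      if (is.null(m)) rep(NA_real_, length(samples)) else m[i, ]
    }, agg$first_caller, agg$first_idx, SIMPLIFY = FALSE)
    do.call(rbind, mats)
  }
  loci_rows <- mapply(function(nm, i) norm_sets[[nm]]$loci[i, ],
                      agg$first_caller, agg$first_idx, SIMPLIFY = FALSE)
  loci <- dplyr::bind_rows(loci_rows)
  ord <- order(loci$chrom, loci$pos, loci$ref, loci$alt)
  loci <- loci[ord, ]
  agg <- agg[ord, ]
  gm <- genotype_matrix(loci, samples,
                        gt = take("gt")[ord, , drop = FALSE],
                        dp = take("dp")[ord, , drop = FALSE],
                        vr = take("vr")[ord, , drop = FALSE])
  records <- dplyr::bind_cols(
    loci[c("chrom", "pos", "ref", "alt", "length", "seq")],
    agg[c("key", "callers", "n_callers", "norm_qual_mean",
          "site_depth", "variant_read_ratio")]
  )
  structure(list(records = records, genotypes = gm), class = "union_set")
}

#' @export
print.union_set <- function(x, ...) {
  cat(sprintf("union_set: %d alleles, %d samples\n",
              nrow(x$records), length(x$genotypes$samples)))
  print(table(n_callers = x$records$n_callers))
  invisible(x)
}

# target membership is decided by the anchor base position (a single point)
anchor_in_targets <- function(loci, targets) {
  if (nrow(loci) == 0L) return(logical(0))
  pts <- GenomicRanges::GRanges(
    loci$chrom, IRanges::IRanges(start = loci$pos, width = 1L))
  IRanges::overlapsAny(pts, targets, ignore.strand = TRUE)
}
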