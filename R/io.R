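#' Write a call set to VCF
#'
#' Serializes a [genotype_matrix()] as a sorted multi-sample VCF 4.2 with
#' `GT:DP:AD` genotype fields and optional per-record INFO annotations
#' (e.g. `CALLERS`, `NQUAL`, `PROB`, `CCC`, `MOTIF`). Output is
#' bgzip-style gzipped when the path ends in `.gz`.
#'
#' @param gm A [genotype_matrix()].
#' @param path Output path (`.vcf.gz` recommended).
#' @param info Optional named list of per-record vectors written as INFO
#'   fields.
#' @param ref_seqs Optional reference for `##contig` header lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path, info = NULL, ref_seqs = NULL) {
  loci <- gm$loci
  ord <- order(loci$chrom, loci$pos, loci$ref, loci$alt)
  gm <- subset_loci(gm, ord)
  loci <- gm$loci
  n <- nrow(loci)
  meta <- c("##fileformat=VCFv4.2",
            paste0("##source=indelcons_", utils::packageVersion("indelcons")))
  if (!is.null(ref_seqs)) {
    meta <- c(meta, sprintf("##contig=<ID=%s,length=%d>",
                            names(ref_seqs), nchar(ref_seqs)))
  }
  info_str <- rep(".", n)
  if (!is.null(info) && length(info)) {
    for (nm in names(info)) {
      meta <- c(meta, sprintf(
        "##INFO=<ID=%s,Number=1,Type=%s,Description=\"%s\">",
        nm, if (is.numeric(info[[nm]])) "Float" else "String", nm))
    }
    parts <- mapply(function(nm, v) paste0(nm, "=", format(v, trim = TRUE)),
                    names(info), info, SIMPLIFY = FALSE)
    info_str <- do.call(paste, c(lapply(parts, function(p) p[ord]), sep = ";"))
  }
  meta <- c(meta,
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
            "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
            "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths (ref,alt)\">")
  fix <- cbind(CHROM = loci$chrom, POS = as.character(loci$pos), ID = ".",
               REF = loci$ref, ALT = loci$alt,
               QUAL = ifelse(is.na(loci$qual), ".", format(loci$qual, trim = TRUE)),
               FILTER = ".", INFO = info_str)
  gt_code <- c("0/0", "0/1", "1/1")
  fmt_cell <- function(g, d, v) {
    gs <- ifelse(is.na(g), "./.", gt_code[g + 1L])
    ds <- if (is.null(d)) "." else ifelse(is.na(d), ".", as.character(d))
    vs <- if (is.null(v)) "." else {
      ifelse(is.na(v) | is.na(d), ".", paste0(d - v, ",", v))
    }
    paste(gs, ds, vs, sep = ":")
  }
  body <- vapply(seq_along(gm$samples), function(j) {
    fmt_cell(gm$gt[, j], gm$dp[, j], gm$vr[, j])
  }, character(n))
  if (n == 1L) body <- matrix(body, nrow = 1L)
  gt <- cbind(FORMAT = rep("GT:DP:AD", n), body)
  colnames(gt) <- c("FORMAT", gm$samples)
  v <- methods::new(methods::getClassDef("vcfR", package = "vcfR"),
                    meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(v, file = path)
  invisible(path)
}

#' Read and normalize a caller call set from VCF
#'
#' Parses a multi-sample VCF with [vcfR::read.vcfR()], decomposes
#' multi-allelic lines into one record per alternate allele, splits
#' complex events (keeping the INDEL component), left-aligns, and drops
#' non-INDELs and alleles of 100 bp or longer. Genotypes are converted
#' to alternate-allele counts per sample; `DP` and the matching `AD`
#' component populate the evidence matrices when present.
#'
#' @param path VCF path (plain or gzipped).
#' @param ref_seqs Reference from [load_reference()].
#' @param caller Caller name recorded on each record.
#' @return A normalized [genotype_matrix()].
#' @export
read_callset <- function(path, ref_seqs, caller = NA_character_) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L,
                                       dimnames = list(NULL, names(fix)))
  if (is.null(fix) || nrow(fix) == 0L) stop("VCF contains no records: ", path)
  missing_chr <- setdiff(unique(fix[, "CHROM"]), names(ref_seqs))
  if (length(missing_chr)) {
    stop("contig(s) absent from reference: ", paste(missing_chr, collapse = ", "))
  }
  has_gt <- ncol(v@gt) > 1L
  samples <- if (has_gt) colnames(v@gt)[-1] else character(0)
  none <- matrix(NA_character_, nrow(fix), length(samples))
  gt_str <- if (has_gt) vcfR::extract.gt(v, "GT") else none
  dp <- if (has_gt) vcfR::extract.gt(v, "DP", as.numeric = TRUE) else none
  ad <- if (has_gt) vcfR::extract.gt(v, "AD") else NULL
  if (is.null(dim(gt_str))) gt_str <- matrix(gt_str, nrow = nrow(fix))
  if (is.null(dim(dp))) dp <- matrix(as.numeric(dp), nrow = nrow(fix))
  if (!is.null(ad) && is.null(dim(ad))) ad <- matrix(ad, nrow = nrow(fix))
  rows <- list()
  gts <- list()
  dps <- list()
  vrs <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    gsplit <- strsplit(gt_str[i, ], "[/|]")
    ad_i <- if (is.null(ad)) NULL else strsplit(ad[i, ], ",", fixed = TRUE)
    for (j in seq_along(alts)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
        ref = fix[i, "REF"], alt = alts[j],
        qual = suppressWarnings(as.numeric(fix[i, "QUAL"])))
      gts[[length(gts) + 1L]] <- vapply(gsplit, function(g) {
        if (length(g) == 0L || any(g == ".") || all(is.na(g))) NA_integer_
        else sum(g == as.character(j))
      }, integer(1))
      dps[[length(dps) + 1L]] <- as.numeric(dp[i, ])
      vrs[[length(vrs) + 1L]] <- if (is.null(ad_i)) rep(NA_real_, length(samples))
        else vapply(ad_i, function(a) {
          if (length(a) <= j || any(is.na(a))) NA_real_ else as.numeric(a[j + 1L])
        }, numeric(1))
    }
  }
  loci <- dplyr::bind_rows(rows)
  loci$caller <- caller
  raw <- genotype_matrix(loci, samples,
                         gt = do.call(rbind, gts),
                         dp = do.call(rbind, dps),
                         vr = do.call(rbind, vrs))
  normalize_callset(raw, ref_seqs)
}

#' Read target regions from BED
#'
#' BED intervals are 0-based half-open on disk; the returned
#' [GenomicRanges::GRanges] uses 1-based closed coordinates (the
#' conversion happens at this I/O boundary).
#'
#' @param path BED path.
#' @return A `GRanges` of target intervals.
#' @export
read_targets <- function(path) {
  rtracklayer::import(path, format = "BED")
}

#' Write target regions to BED
#'
#' @param targets A [GenomicRanges::GRanges].
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_targets <- function(targets, path) {
  rtracklayer::export(targets, path, format = "BED")
  invisible(path)
}

#' Write reference sequences to FASTA
#'
#' @param ref_seqs Named character vector of chromosome sequences.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(ref_seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(ref_seqs), path)
  invisible(path)
}
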