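#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test of Hardy-Weinberg genotype proportions given the
#' allele counts: the p-value is the sum of the probabilities of all
#' heterozygote counts (same parity as the minor-allele count) whose
#' conditional probability does not exceed that of the observed
#' configuration. This is the standard sum-of-less-probable definition, not
#' the mid-p variant.
#'
#' @param n_AA,n_Aa,n_aa non-negative integer genotype counts (major
#'   homozygote, heterozygote, minor homozygote); at least one must be > 0.
#' @return the exact p-value, in (0, 1].
#' @export
hwe_exact_p <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("genotype counts must be non-negative integers")
  n <- sum(counts)
  if (n == 0) stop("all genotype counts are zero")
  n1 <- min(2 * n_AA + n_Aa, 2 * n_aa + n_Aa)  # rarer allele count
  n2 <- 2 * n - n1
  h <- seq(n1 %% 2, n1, by = 2)                # feasible heterozygote counts
  logp <- lfactorial(n) + lfactorial(n1) + lfactorial(n2) - lfactorial(2 * n) +
    h * log(2) - lfactorial((n1 - h) / 2) - lfactorial(h) -
    lfactorial((n2 - h) / 2)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_Aa, h)]
  min(1, sum(p[p <= obs * (1 + 1e-9)]))
}

# Per-variant minor-allele frequency (of the allele counted by the dosage)
# and missing rate over a dosage matrix.
variant_stats <- function(dos) {
  n_ok <- colSums(!is.na(dos))
  list(af = colSums(dos, na.rm = TRUE) / (2 * pmax(n_ok, 1)),
       miss = 1 - n_ok / nrow(dos),
       n_ok = n_ok)
}

#' Filter variants on MAF, missingness and Hardy-Weinberg equilibrium
#'
#' Applies the standard marker quality filters of a GWAS: minimum
#' minor-allele frequency, maximum per-variant missing rate, and an exact
#' Hardy-Weinberg test. HWE is assessed in the non-metastatic reference
#' group (stage I/II) by default, since strong case-only association at a
#' true risk locus distorts genotype proportions in the metastatic group.
#' Each removed variant records the first filter it failed, in the order
#' MAF, missingness, HWE.
#'
#' @param dataset a [genotype_dataset()].
#' @param maf_min minimum minor-allele frequency (default 0.01).
#' @param miss_max maximum fraction of missing genotypes (default 0.02).
#' @param hwe_alpha minimum exact HWE p-value (default 1e-6).
#' @param hwe_group stage labels of the samples used for the HWE test;
#'   falls back to all samples if no sample matches.
#' @return a list with the filtered `dataset` and a `report` (class
#'   `qc_report`): per-variant `maf`, `miss_rate`, `hwe_p`, and a
#'   `removed` data.frame of `variant_id` + `reason`.
#' @export
filter_variants <- function(dataset, maf_min = 0.01, miss_max = 0.02,
                            hwe_alpha = 1e-6, hwe_group = c("I", "II")) {
  if (ncol(dataset$dosages) == 0 || nrow(dataset$dosages) == 0)
    stop("empty dataset")
  stopifnot(maf_min >= 0, maf_min <= 1, miss_max >= 0, miss_max <= 1,
            hwe_alpha >= 0, hwe_alpha <= 1)
  st <- variant_stats(dataset$dosages)
  maf <- pmin(st$af, 1 - st$af)
  hrows <- stage_samples(dataset, hwe_group)
  if (!length(hrows)) hrows <- seq_len(nrow(dataset$dosages))
  hdos <- dataset$dosages[hrows, , drop = FALSE]
  hwe_p <- vapply(seq_len(ncol(hdos)), function(j) {
    d <- hdos[, j]
    n0 <- sum(d == 0, na.rm = TRUE); n1 <- sum(d == 1, na.rm = TRUE)
    n2 <- sum(d == 2, na.rm = TRUE)
    if (n0 + n1 + n2 == 0) return(NA_real_)
    hwe_exact_p(n0, n1, n2)
  }, numeric(1))
  reason <- rep(NA_character_, ncol(dataset$dosages))
  reason[is.na(reason) & maf < maf_min] <- "maf"
  reason[is.na(reason) & st$miss > miss_max] <- "missingness"
  reason[is.na(reason) & !is.na(hwe_p) & hwe_p < hwe_alpha] <- "hwe"
  keep <- is.na(reason)
  report <- structure(list(
    side = "variant",
    stats = data.frame(variant_id = dataset$variants$variant_id,
                       maf = maf, miss_rate = st$miss, hwe_p = hwe_p,
                       removed = !keep, reason = reason,
                       stringsAsFactors = FALSE),
    removed = data.frame(variant_id = dataset$variants$variant_id[!keep],
                         reason = reason[!keep], stringsAsFactors = FALSE),
    thresholds = c(maf_min = maf_min, miss_max = miss_max,
                   hwe_alpha = hwe_alpha)),
    class = "qc_report")
  list(dataset = subset_variants(dataset, keep), report = report)
}

#' Filter samples on genotyping call rate
#'
#' @param dataset a [genotype_dataset()].
#' @param call_rate_min minimum fraction of non-missing genotypes per
#'   sample (default 0.98).
#' @return a list with the filtered `dataset` and a `report` (class
#'   `qc_report`) holding per-sample call rates and the removed samples.
#' @export
filter_samples <- function(dataset, call_rate_min = 0.98) {
  stopifnot(call_rate_min >= 0, call_rate_min <= 1)
  if (nrow(dataset$dosages) == 0) stop("empty dataset")
  cr <- rowMeans(!is.na(dataset$dosages))
  keep <- cr >= call_rate_min
  if (!any(keep)) stop("all samples removed by call-rate filter")
  report <- structure(list(
    side = "sample",
    stats = data.frame(sample_id = dataset$samples$sample_id,
                       call_rate = cr, removed = !keep,
                       reason = ifelse(keep, NA_character_, "call_rate"),
                       stringsAsFactors = FALSE),
    removed = data.frame(sample_id = dataset$samples$sample_id[!keep],
                         reason = rep("call_rate", sum(!keep)),
                         stringsAsFactors = FALSE),
    thresholds = c(call_rate_min = call_rate_min)),
    class = "qc_report")
  list(dataset = subset_samples(dataset, keep), report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report (%s side): %d of %d removed\n", x$side,
              nrow(x$removed), nrow(x$stats)))
  if (nrow(x$removed)) print(table(x$removed$reason))
  invisible(x)
}

#' Population stratification axes by classical multidimensional scaling
#'
#' Computes a pairwise allele-sharing (identity-by-state) distance — one
#' minus the proportion of shared alleles over pairwise non-missing loci —
#' and extracts the leading axes with classical metric scaling
#' (`stats::cmdscale`). Axes are ordered by decreasing eigenvalue and each
#' axis is oriented so its largest-magnitude coordinate is positive, making
#' the sign convention reproducible.
#'
#' @param dataset a [genotype_dataset()].
#' @param k number of axes to return (>= 1, at most samples - 1).
#' @return an object of class `stratification_result`: `points` (samples x
#'   k coordinate matrix, zero-mean per axis), `eig` (all eigenvalues), and
#'   `k`.
#' @export
mds_components <- function(dataset, k = 2) {
  n <- nrow(dataset$dosages)
  if (n < 2) stop("need at least 2 samples")
  if (k < 1 || k > n - 1) stop("k must be in [1, samples - 1]")
  m <- ncol(dataset$dosages)
  # |d_i - d_j| sums 0..2m; dist() rescales for pairwise-missing entries
  d <- stats::dist(dataset$dosages, method = "manhattan") / (2 * m)
  fit <- stats::cmdscale(d, k = k, eig = TRUE)
  pts <- fit$points
  for (j in seq_len(ncol(pts)))
    if (pts[which.max(abs(pts[, j])), j] < 0) pts[, j] <- -pts[, j]
  rownames(pts) <- dataset$samples$sample_id
  colnames(pts) <- paste0("PC", seq_len(ncol(pts)))
  structure(list(points = pts, eig = fit$eig, k = k,
                 distance = "allele-sharing (IBS)"),
            class = "stratification_result")
}

#' @export
print.stratification_result <- function(x, ...) {
  cat(sprintf("stratification_result: %d samples, %d axes (%s distance)\n",
              nrow(x$points), x$k, x$distance))
  ev <- x$eig[seq_len(min(x$k, length(x$eig)))]
  cat("  leading eigenvalues:", paste(signif(ev, 4), collapse = ", "), "\n")
  invisible(x)
}
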