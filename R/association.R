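#' Minor-allele frequency from genotype counts
#'
#' @param n_AA,n_Aa,n_aa non-negative integer genotype counts: major
#'   homozygotes, heterozygotes, minor homozygotes.
#' @return `(n_Aa + 2 * n_aa) / (2 * (n_AA + n_Aa + n_aa))`.
#' @export
maf_from_counts <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("genotype counts must be non-negative integers")
  total <- n_AA + n_Aa + n_aa
  if (total == 0) stop("total genotype count is zero")
  (n_Aa + 2 * n_aa) / (2 * total)
}

#' Genotype counts and MAF of a dosage vector
#'
#' @param dosages dosage vector (0/1/2/NA).
#' @param group optional group label stored with the summary.
#' @return a one-row data.frame: `group`, `n_AA`, `n_Aa`, `n_aa`, `n`,
#'   `maf`.
#' @export
genotype_summary <- function(dosages, group = NA_character_) {
  n0 <- sum(dosages == 0, na.rm = TRUE)
  n1 <- sum(dosages == 1, na.rm = TRUE)
  n2 <- sum(dosages == 2, na.rm = TRUE)
  data.frame(group = group, n_AA = n0, n_Aa = n1, n_aa = n2,
             n = n0 + n1 + n2,
             maf = if (n0 + n1 + n2 > 0) maf_from_counts(n0, n1, n2)
                   else NA_real_,
             stringsAsFactors = FALSE)
}

#' Covariate-adjusted log-additive logistic association for one SNP
#'
#' Fits the trend (log-additive) model: logistic regression of case status
#' on the 0/1/2 minor-allele dosage plus covariates, by maximum likelihood
#' (iteratively reweighted least squares via `stats::glm`, relative
#' convergence 1e-10, at most 100 iterations). Samples with a missing
#' dosage, covariate or phenotype are excluded listwise. The p-value is
#' the two-sided Wald test of the dosage coefficient; the 95% CI uses
#' z = 1.96 exactly. Non-convergence or separation is reported as
#' `converged = FALSE` with a note — no silent estimate and no penalised
#' fallback.
#'
#' @param dosages dosage vector (0/1/2/NA), counting copies of A1.
#' @param phenotype binary vector (1/TRUE = metastatic case, 0/FALSE =
#'   reference); must contain both classes.
#' @param covariates optional numeric matrix or data.frame, rows aligned
#'   with `dosages`.
#' @param variant_id label carried into the result row.
#' @return a one-row data.frame: `variant_id`, `beta`, `se`, `or_`,
#'   `ci_lo`, `ci_hi`, `p`, `n_used`, `converged`, `note`.
#' @export
fit_logistic_trend <- function(dosages, phenotype, covariates = NULL,
                               variant_id = NA_character_) {
  y <- as.numeric(phenotype)
  if (!all(y %in% c(0, 1) | is.na(y)))
    stop("phenotype must be binary (0/1)")
  X <- cbind(dosage = as.numeric(dosages))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != length(dosages))
      stop("covariates must have one row per sample")
    X <- cbind(X, covariates)
  }
  keep <- stats::complete.cases(X) & !is.na(y)
  X <- X[keep, , drop = FALSE]
  y <- y[keep]
  if (length(unique(y)) < 2) stop("phenotype has a single class after listwise deletion")
  if (length(unique(X[, "dosage"])) < 2)
    stop("monomorphic in analysis set")
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(cbind(`(Intercept)` = 1, X), y,
                   family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  # Wald statistics from the IRLS weights at the optimum
  w <- fit$weights
  XX <- cbind(1, X)
  info <- crossprod(XX * sqrt(w))
  cov_ok <- TRUE
  covb <- tryCatch(solve(info), error = function(e) { cov_ok <<- FALSE; NULL })
  beta <- unname(fit$coefficients["dosage"])
  se <- if (cov_ok) sqrt(covb["dosage", "dosage"]) else NA_real_
  converged <- isTRUE(fit$converged) && !sep && cov_ok &&
    is.finite(beta) && is.finite(se) && se < 100
  note <- if (converged) NA_character_
          else if (sep) "separation: fitted probabilities 0 or 1"
          else if (!isTRUE(fit$converged)) "IRLS did not converge"
          else "singular information matrix"
  z <- beta / se
  data.frame(variant_id = variant_id, beta = beta, se = se,
             or_ = exp(beta),
             ci_lo = exp(beta - 1.96 * se), ci_hi = exp(beta + 1.96 * se),
             p = 2 * stats::pnorm(-abs(z)),
             n_used = length(y), converged = converged, note = note,
             stringsAsFactors = FALSE)
}

#' Build a numeric covariate matrix from sample metadata
#'
#' @param dataset a [genotype_dataset()].
#' @param use character vector among `"age"` and `"sex"` (`sex` coded
#'   male = 1).
#' @param strat optional `stratification_result` from [mds_components()];
#'   its axes are appended as PC columns.
#' @return numeric matrix with one row per sample.
#' @export
covariate_matrix <- function(dataset, use = c("age", "sex"), strat = NULL) {
  cols <- list()
  if ("age" %in% use) cols$age <- dataset$samples$age
  if ("sex" %in% use) cols$sex <- as.numeric(dataset$samples$sex == "male")
  X <- do.call(cbind, cols)
  if (!is.null(strat)) {
    pts <- strat$points[match(dataset$samples$sample_id, rownames(strat$points)),
                        , drop = FALSE]
    X <- cbind(X, pts)
  }
  rownames(X) <- dataset$samples$sample_id
  X
}

#' Per-SNP association scan of metastatic vs non-metastatic cases
#'
#' Runs [fit_logistic_trend()] for every variant, contrasting the
#' metastatic case group against the non-metastatic reference group.
#' Controls (and any stage outside the two groups) never enter the fits;
#' per-variant fit errors (e.g. monomorphic markers) become flagged rows
#' rather than aborting the scan. Per-group genotype summaries (including
#' a control MAF reference when controls are present) are returned
#' alongside.
#'
#' @param dataset a [genotype_dataset()] (QC already applied).
#' @param covariates optional numeric covariate matrix with one row per
#'   dataset sample (see [covariate_matrix()]).
#' @param group_case,group_ref stage labels of cases (coded 1) and the
#'   reference (coded 0).
#' @return an object of class `genome_scan`: `results` (one row per
#'   variant, sortable by `p`) and `group_summaries` (genotype counts and
#'   MAF per variant for case, reference, combined case and control
#'   groups).
#' @export
genome_scan <- function(dataset, covariates = NULL,
                        group_case = "IV", group_ref = c("I", "II")) {
  rows_case <- stage_samples(dataset, group_case)
  rows_ref <- stage_samples(dataset, group_ref)
  if (!length(rows_case) || !length(rows_ref))
    stop("case and reference groups must both be non-empty")
  rows <- c(rows_case, rows_ref)
  y <- rep(c(1, 0), c(length(rows_case), length(rows_ref)))
  covs <- if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == nrow(dataset$dosages))
    covariates[rows, , drop = FALSE]
  }
  rows_ctl <- stage_samples(dataset, "control")
  res <- vector("list", ncol(dataset$dosages))
  sums <- vector("list", ncol(dataset$dosages))
  for (j in seq_len(ncol(dataset$dosages))) {
    vid <- dataset$variants$variant_id[j]
    d <- dataset$dosages[rows, j]
    res[[j]] <- tryCatch(
      fit_logistic_trend(d, y, covs, variant_id = vid),
      error = function(e)
        data.frame(variant_id = vid, beta = NA_real_, se = NA_real_,
                   or_ = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                   p = NA_real_, n_used = sum(!is.na(d)), converged = FALSE,
                   note = conditionMessage(e), stringsAsFactors = FALSE))
    gs <- rbind(
      genotype_summary(dataset$dosages[rows_case, j], "case"),
      genotype_summary(dataset$dosages[rows_ref, j], "reference"),
      genotype_summary(dataset$dosages[c(rows_case, rows_ref), j], "combined"),
      if (length(rows_ctl))
        genotype_summary(dataset$dosages[rows_ctl, j], "control"))
    gs$variant_id <- vid
    sums[[j]] <- gs
  }
  structure(list(results = do.call(rbind, res),
                 group_summaries = do.call(rbind, sums),
                 group_case = group_case, group_ref = group_ref),
            class = "genome_scan")
}

#' @export
print.genome_scan <- function(x, ...) {
  r <- x$results
  cat(sprintf("genome_scan: %d variants (%s vs %s), %d converged\n",
              nrow(r), paste(x$group_case, collapse = "/"),
              paste(x$group_ref, collapse = "/"), sum(r$converged)))
  top <- r[order(r$p), ][seq_len(min(5, nrow(r))), c("variant_id", "or_", "p")]
  print(top, row.names = FALSE)
  invisible(x)
}

#' Quantile-quantile data for a set of p-values
#'
#' @param p_values p-values in (0, 1].
#' @return a data.frame of `expected` and `observed` -log10 p, with
#'   expected quantiles `i / (n + 1)`.
#' @export
qq_data <- function(p_values) {
  p <- p_values[!is.na(p_values)]
  if (!length(p)) stop("no p-values supplied")
  if (any(p <= 0 | p > 1)) stop("p-values must be in (0, 1]")
  n <- length(p)
  data.frame(expected = -log10(seq_len(n) / (n + 1)),
             observed = -log10(sort(p)))
}
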