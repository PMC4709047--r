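#' Standard error of a log odds ratio from its 95% CI
#'
#' Published study results usually report only the OR and its 95% CI; the
#' log-scale standard error is recovered as
#' `(ln ci_hi - ln ci_lo) / (2 * 1.96)` (1.96 exactly, matching
#' two-decimal printed CIs).
#'
#' @param or_ odds ratio (must lie within the interval).
#' @param ci_lo,ci_hi 95% confidence bounds.
#' @return the standard error of `ln(or_)`.
#' @export
se_from_ci <- function(or_, ci_lo, ci_hi) {
  if (ci_lo > ci_hi) stop("ci_lo must be <= ci_hi")
  if (ci_lo <= 0) stop("bounds must be positive")
  if (!(ci_lo <= or_ && or_ <= ci_hi))
    stop("or_ must lie within its confidence interval")
  (log(ci_hi) - log(ci_lo)) / (2 * 1.96)
}

#' Assemble per-study estimates for meta-analysis
#'
#' @param study_id character labels.
#' @param or_,ci_lo,ci_hi per-study odds ratios and 95% bounds.
#' @param n per-study total sample sizes (needed only for
#'   [sample_size_weighted_z()]).
#' @param p optional per-study two-sided p-values (ditto).
#' @return a data.frame of class `study_estimates` with `ln_or`, `se` and
#'   `direction` columns added.
#' @export
study_estimates <- function(study_id, or_, ci_lo, ci_hi, n = NA_real_,
                            p = NA_real_) {
  se <- mapply(se_from_ci, or_, ci_lo, ci_hi)
  out <- data.frame(study_id = study_id, or_ = or_, ci_lo = ci_lo,
                    ci_hi = ci_hi, ln_or = log(or_), se = se, n = n, p = p,
                    direction = sign(log(or_)), stringsAsFactors = FALSE)
  class(out) <- c("study_estimates", "data.frame")
  out
}

pooled_summary <- function(ln_or, se, model) {
  z <- ln_or / se
  list(model = model, pooled_ln_or = ln_or, pooled_se = se,
       pooled_or = exp(ln_or),
       ci_lo = exp(ln_or - 1.96 * se), ci_hi = exp(ln_or + 1.96 * se),
       z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Inverse-variance fixed-effects pooling of odds ratios
#'
#' Weights `w_i = 1/se_i^2`; pooled `lnOR = sum(w * lnOR) / sum(w)` with
#' standard error `1/sqrt(sum(w))`, 95% CI at z = 1.96 and a two-sided
#' normal p-value.
#'
#' @param estimates a [study_estimates()] data.frame (or any data.frame
#'   with `ln_or` and `se`).
#' @return a list: `model = "fixed"`, `pooled_ln_or`, `pooled_se`,
#'   `pooled_or`, `ci_lo`, `ci_hi`, `z`, `p`, and normalized `weights`.
#' @export
fixed_effects <- function(estimates) {
  se <- estimates$se
  if (length(se) < 1) stop("need at least one estimate")
  if (any(se == 0) && length(se) > 1)
    stop("a zero standard error gives infinite weight")
  w <- 1 / se^2
  out <- pooled_summary(sum(w * estimates$ln_or) / sum(w), 1 / sqrt(sum(w)),
                        "fixed")
  out$weights <- w / sum(w)
  out
}

#' Cochran's Q test of between-study homogeneity
#'
#' `Q = sum(w_i * (lnOR_i - pooled)^2)` around the fixed-effects pooled
#' estimate, referred to a chi-square with `k - 1` degrees of freedom.
#'
#' @param estimates a [study_estimates()] data.frame (>= 2 studies).
#' @return a list `q`, `df`, `q_p`.
#' @export
cochran_q <- function(estimates) {
  if (nrow(estimates) < 2) stop("need at least two estimates")
  fe <- fixed_effects(estimates)
  w <- 1 / estimates$se^2
  q <- sum(w * (estimates$ln_or - fe$pooled_ln_or)^2)
  df <- nrow(estimates) - 1
  list(q = q, df = df, q_p = stats::pchisq(q, df, lower.tail = FALSE))
}

#' DerSimonian-Laird random-effects pooling
#'
#' Method-of-moments between-study variance
#' `tau2 = max(0, (Q - df) / (sum(w) - sum(w^2)/sum(w)))` with fixed-effects
#' weights `w`; random-effects weights are `1/(se_i^2 + tau2)` and pooling
#' proceeds as in [fixed_effects()]. When `Q <= df`, `tau2 = 0` and the
#' random-effects result equals the fixed-effects one.
#'
#' @param estimates a [study_estimates()] data.frame (>= 2 studies).
#' @return a list as in [fixed_effects()] plus `tau2`, `q`, `df`, `q_p`.
#' @export
dersimonian_laird <- function(estimates) {
  qq <- cochran_q(estimates)
  w <- 1 / estimates$se^2
  denom <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (qq$q - qq$df) / denom)
  wr <- 1 / (estimates$se^2 + tau2)
  out <- pooled_summary(sum(wr * estimates$ln_or) / sum(wr),
                        1 / sqrt(sum(wr)), "random")
  out$weights <- wr / sum(wr)
  out$tau2 <- tau2
  c(out, qq)
}

#' Sample-size-weighted z-score meta-analysis
#'
#' The signed-z combination used by METAL's sample-size scheme: per-study
#' `z_i = qnorm(1 - p_i/2) * direction_i`, weights `sqrt(n_i)`, pooled
#' `Z = sum(w * z) / sqrt(sum(w^2))` with a two-sided p-value.
#'
#' @param estimates a [study_estimates()] data.frame with `n`, `p` and
#'   `direction` available.
#' @return a list `z_by_study`, `z`, `p`.
#' @export
sample_size_weighted_z <- function(estimates) {
  p <- estimates$p; n <- estimates$n; dir <- estimates$direction
  if (any(is.na(p)) || any(is.na(n))) stop("per-study p and n are required")
  if (any(p <= 0)) stop("p = 0: z quantile undefined")
  zi <- stats::qnorm(p / 2, lower.tail = FALSE) * dir
  w <- sqrt(n)
  z <- sum(w * zi) / sqrt(sum(w^2))
  list(z_by_study = zi, z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Full odds-ratio meta-analysis of per-study estimates
#'
#' Pools the studies under both the inverse-variance fixed-effects and the
#' DerSimonian-Laird random-effects model, reports Cochran's Q, and — when
#' per-study p-values and sample sizes are available — the sample-size-
#' weighted z combination, so that discrepancies between the weighting
#' schemes are visible rather than conflated.
#'
#' @param estimates a [study_estimates()] data.frame.
#' @return an object of class `meta_result`: `fixed`, `random` (each as in
#'   [fixed_effects()] / [dersimonian_laird()]), `q`, `df`, `q_p`, `tau2`,
#'   optional `sswz`, and the input `estimates`.
#' @export
meta_analysis <- function(estimates) {
  fe <- fixed_effects(estimates)
  re <- dersimonian_laird(estimates)
  sswz <- if (!any(is.na(estimates$p)) && !any(is.na(estimates$n)))
    sample_size_weighted_z(estimates)
  structure(list(fixed = fe, random = re, q = re$q, df = re$df,
                 q_p = re$q_p, tau2 = re$tau2, sswz = sswz,
                 estimates = estimates),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  f <- x$fixed; r <- x$random
  cat(sprintf("meta_result (%d studies)\n", nrow(x$estimates)))
  cat(sprintf("  fixed:  OR %.2f (95%% CI %.2f-%.2f), p = %.3g\n",
              f$pooled_or, f$ci_lo, f$ci_hi, f$p))
  cat(sprintf("  random: OR %.2f (95%% CI %.2f-%.2f), p = %.3g (tau2 = %.3g)\n",
              r$pooled_or, r$ci_lo, r$ci_hi, r$p, x$tau2))
  cat(sprintf("  Cochran Q = %.2f, df = %d, p = %.3g\n", x$q, x$df, x$q_p))
  if (!is.null(x$sswz))
    cat(sprintf("  sample-size-weighted Z = %.2f, p = %.3g\n",
                x$sswz$z, x$sswz$p))
  invisible(x)
}

#' Forest-plot data for a meta-analysis
#'
#' @param meta a `meta_result` from [meta_analysis()].
#' @return a data.frame with one row per study plus one row per pooled
#'   model: `label`, `or_`, `ci_lo`, `ci_hi`, `weight_fixed`,
#'   `weight_random`.
#' @export
forest_data <- function(meta) {
  stopifnot(inherits(meta, "meta_result"))
  est <- meta$estimates
  rbind(
    data.frame(label = est$study_id, or_ = est$or_, ci_lo = est$ci_lo,
               ci_hi = est$ci_hi, weight_fixed = meta$fixed$weights,
               weight_random = meta$random$weights,
               stringsAsFactors = FALSE),
    data.frame(label = c("pooled (fixed)", "pooled (random)"),
               or_ = c(meta$fixed$pooled_or, meta$random$pooled_or),
               ci_lo = c(meta$fixed$ci_lo, meta$random$ci_lo),
               ci_hi = c(meta$fixed$ci_hi, meta$random$ci_hi),
               weight_fixed = NA_real_, weight_random = NA_real_,
               stringsAsFactors = FALSE))
}
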