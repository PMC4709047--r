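#' Winner's-curse shrinkage to the 50% lower confidence limit
#'
#' Discovery-stage odds ratios are optimistically biased ("winner's
#' curse"). For replication power planning the effect is shrunk to the
#' lower bound of a 50% confidence interval: with the log-scale standard
#' error reconstructed from the 95% CI, returns
#' `exp(ln or_hat - 0.6745 * SE)`, 0.6745 being the 75th-percentile
#' standard-normal quantile.
#'
#' @param or_hat discovery odds ratio.
#' @param ci_lo,ci_hi its 95% confidence bounds.
#' @return the shrunken odds ratio (always <= `or_hat`; equal iff the CI
#'   is degenerate).
#' @export
shrunken_or <- function(or_hat, ci_lo, ci_hi) {
  if (ci_lo > ci_hi) stop("ci_lo must be <= ci_hi")
  if (!(ci_lo <= or_hat && or_hat <= ci_hi))
    stop("or_hat must lie within its confidence interval")
  if (ci_lo <= 0) stop("bounds must be positive")
  se <- (log(ci_hi) - log(ci_lo)) / (2 * 1.96)
  exp(log(or_hat) - stats::qnorm(0.75) * se)
}

#' Power of the allelic test in a replication cohort
#'
#' Normal-approximation power for the two-sided per-allele (allelic 2x2)
#' test at level `alpha`: the reference-group allele frequency and the
#' (shrunken) odds ratio imply the expected case allele frequency; the
#' variance of the log odds ratio is the usual sum of reciprocal expected
#' allele-table cell counts; power is
#' `pnorm(|lnOR|/SE - z) + pnorm(-|lnOR|/SE - z)` with
#' `z = qnorm(1 - alpha/2)`.
#'
#' @param or_ odds ratio under the alternative (use [shrunken_or()] output
#'   for replication planning).
#' @param maf reference-group minor-allele frequency, in (0, 0.5].
#' @param n_cases,n_controls replication group sizes (individuals; each
#'   contributes two alleles).
#' @param alpha per-test two-sided significance level.
#' @return power in [0, 1]. If any expected cell count is below 1 the
#'   result carries attribute `unreliable = TRUE` (the normal
#'   approximation is poor there).
#' @export
replication_power <- function(or_, maf, n_cases, n_controls, alpha) {
  stopifnot(or_ > 0, maf > 0, maf <= 0.5, n_cases > 0, n_controls > 0,
            alpha > 0, alpha < 1)
  p0 <- maf
  p1 <- odds_transform(p0, or_)
  cells <- c(2 * n_cases * p1, 2 * n_cases * (1 - p1),
             2 * n_controls * p0, 2 * n_controls * (1 - p0))
  se <- sqrt(sum(1 / cells))
  za <- stats::qnorm(1 - alpha / 2)
  ncp <- abs(log(or_)) / se
  pow <- stats::pnorm(ncp - za) + stats::pnorm(-ncp - za)
  if (any(cells < 1)) attr(pow, "unreliable") <- TRUE
  pow
}

#' Build a two-tier replication plan with a split Bonferroni budget
#'
#' Selects SNPs for the validation stage the way a power-guided two-stage
#' GWAS pre-registers them: the most significant discovery SNPs whose
#' replication power — computed at the winner's-curse-shrunken odds ratio —
#' meets `power_floor` fill tier 1 (per-test alpha `budget1[2]/|tier1|`),
#' the next qualifying SNPs fill tier 2 (`budget2[2]/|tier2|`), so the
#' family-wise type-I error is capped at `budget1[2] + budget2[2]`.
#' Companion SNPs in complete LD (D' = 1) with a tier-1 member are appended
#' with no alpha of their own ("no statistical adjustment").
#'
#' @param scan_results data.frame from [genome_scan()]`$results` (or of the
#'   same shape), sorted or sortable by `p`; needs columns `variant_id`,
#'   `or_`, `ci_lo`, `ci_hi`, `p`.
#' @param mafs named vector of reference-group MAFs per variant id.
#' @param n_cases,n_controls planned validation group sizes.
#' @param ld_pairs optional data.frame with columns `companion_id`,
#'   `partner_id` listing D' = 1 companions of candidate SNPs.
#' @param budget1,budget2 `c(max SNPs, alpha share)` per tier; defaults
#'   `c(9, 0.04)` and `c(8, 0.01)`.
#' @param power_floor minimum shrunken-OR replication power (default 0.80).
#' @param alpha_power per-test level at which the power screen is run;
#'   defaults to `budget1[2] / budget1[1]`.
#' @return an object of class `replication_plan`: `tier1`, `tier2`
#'   (variant ids), `alpha1`, `alpha2`, `companions` (data.frame),
#'   `overall_alpha`, and the per-SNP screening table `screen`.
#' @export
build_plan <- function(scan_results, mafs, n_cases, n_controls,
                       ld_pairs = NULL, budget1 = c(9, 0.04),
                       budget2 = c(8, 0.01), power_floor = 0.80,
                       alpha_power = budget1[2] / budget1[1]) {
  if (is.null(scan_results) || nrow(scan_results) == 0) stop("empty scan")
  need <- c("variant_id", "or_", "ci_lo", "ci_hi", "p")
  miss <- setdiff(need, names(scan_results))
  if (length(miss)) stop("scan_results missing column(s): ",
                         paste(miss, collapse = ", "))
  sc <- scan_results[!is.na(scan_results$p), need]
  sc$maf <- as.numeric(mafs[sc$variant_id])
  sc$shrunk_or <- mapply(shrunken_or, sc$or_, sc$ci_lo, sc$ci_hi)
  sc$power <- mapply(function(or_, maf) {
    if (is.na(maf)) return(NA_real_)
    # reference-group frequency of a globally-minor allele can exceed 0.5;
    # the allelic test is label-invariant, so fold frequency and effect
    if (maf > 0.5) { maf <- 1 - maf; or_ <- 1 / or_ }
    as.numeric(replication_power(or_, maf, n_cases, n_controls, alpha_power))
  }, sc$shrunk_or, sc$maf)
  # deterministic order: p, then larger shrunken-OR power, then id
  sc <- sc[order(sc$p, -sc$power, sc$variant_id), ]
  qual <- sc[!is.na(sc$power) & sc$power >= power_floor, ]
  tier1 <- utils::head(qual$variant_id, budget1[1])
  tier2 <- utils::head(setdiff(qual$variant_id, tier1), budget2[1])
  companions <- data.frame(companion_id = character(0),
                           partner_id = character(0),
                           stringsAsFactors = FALSE)
  if (!is.null(ld_pairs) && nrow(ld_pairs)) {
    sel <- ld_pairs$partner_id %in% tier1 &
      !ld_pairs$companion_id %in% c(tier1, tier2)
    companions <- unique(ld_pairs[sel, c("companion_id", "partner_id")])
  }
  a1 <- if (length(tier1)) budget1[2] / length(tier1) else NA_real_
  a2 <- if (length(tier2)) budget2[2] / length(tier2) else NA_real_
  structure(list(tier1 = tier1, alpha1 = a1,
                 tier2 = tier2, alpha2 = a2,
                 companions = companions,
                 overall_alpha = budget1[2] + budget2[2],
                 power_floor = power_floor,
                 n_cases = n_cases, n_controls = n_controls,
                 screen = sc),
            class = "replication_plan")
}

#' @export
print.replication_plan <- function(x, ...) {
  cat(sprintf("replication_plan: %d tier-1 SNPs at alpha %.4g, %d tier-2 at %.4g\n",
              length(x$tier1), x$alpha1, length(x$tier2), x$alpha2))
  cat(sprintf("  %d unadjusted D'=1 companions; overall alpha %.3g\n",
              nrow(x$companions), x$overall_alpha))
  invisible(x)
}

#' Judge replication of a pre-registered plan
#'
#' A planned SNP replicates iff its validation p-value is strictly below
#' its tier's per-test alpha AND the validation effect points in the same
#' direction as discovery (a significant sign flip is not replication).
#' Companion SNPs inherit their partner's tier alpha for reporting only.
#' SNPs absent from the validation results (genotyping failures) are
#' reported as `NA` verdicts.
#'
#' @param plan a `replication_plan` from [build_plan()].
#' @param validation_results data.frame with columns `variant_id`, `or_`,
#'   `p` from the validation cohort.
#' @param discovery_results data.frame with columns `variant_id`, `or_`
#'   giving the discovery effect directions; defaults to `plan$screen`.
#' @return a data.frame with one row per planned SNP: `variant_id`,
#'   `tier`, `alpha`, `discovery_or`, `validation_or`, `validation_p`,
#'   `same_direction`, `replicated`.
#' @export
evaluate_replication <- function(plan, validation_results,
                                 discovery_results = plan$screen) {
  stopifnot(inherits(plan, "replication_plan"))
  ids <- c(plan$tier1, plan$tier2, plan$companions$companion_id)
  tier <- c(rep("tier1", length(plan$tier1)),
            rep("tier2", length(plan$tier2)),
            rep("companion", nrow(plan$companions)))
  alpha <- c(rep(plan$alpha1, length(plan$tier1)),
             rep(plan$alpha2, length(plan$tier2)),
             rep(plan$alpha1, nrow(plan$companions)))
  vr <- validation_results[match(ids, validation_results$variant_id), ]
  dr <- discovery_results[match(ids, discovery_results$variant_id), ]
  same_dir <- sign(log(vr$or_)) == sign(log(dr$or_))
  replicated <- !is.na(vr$p) & vr$p < alpha & same_dir
  replicated[is.na(vr$p) | is.na(same_dir)] <- NA
  data.frame(variant_id = ids, tier = tier, alpha = alpha,
             discovery_or = dr$or_, validation_or = vr$or_,
             validation_p = vr$p, same_direction = same_dir,
             replicated = replicated, stringsAsFactors = FALSE)
}
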