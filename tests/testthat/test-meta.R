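# Odds-ratio meta-analysis: CI reconstruction, fixed/random pooling,
# Cochran's Q, sample-size-weighted z. metafor::rma is the independent
# cross-check for the pooling routes.

test_that("se_from_ci reconstructs log-scale standard errors", {
  expect_equal(se_from_ci(2, 2, 2), 0)
  # validation-cohort style input: 1.89 (1.27, 2.80)
  expect_equal(se_from_ci(1.89, 1.27, 2.80),
               (log(2.80) - log(1.27)) / 3.92)
  expect_equal(se_from_ci(1.89, 1.27, 2.80), 0.20168, tolerance = 1e-4)
  expect_error(se_from_ci(2, 3, 1), "ci_lo")
  expect_error(se_from_ci(5, 1, 2), "within")
  # the three printed studies are log-symmetric to within 2%
  est <- printed_studies()
  expect_true(all(abs(sqrt(est$ci_lo * est$ci_hi) / est$or_ - 1) < 0.02))
})

test_that("fixed effects: identity, precision pooling, and printed studies", {
  one <- study_estimates("a", 2.0, 1.5, 8 / 3)
  f1 <- fixed_effects(one)
  expect_equal(f1$pooled_or, 2.0, tolerance = 1e-12)
  expect_equal(f1$pooled_se, one$se, tolerance = 1e-12)

  two <- study_estimates(c("a", "b"), c(2, 2), c(1.5, 1.5), c(8 / 3, 8 / 3))
  f2 <- fixed_effects(two)
  expect_equal(f2$pooled_or, 2.0, tolerance = 1e-12)
  expect_equal(f2$pooled_se, one$se / sqrt(2), tolerance = 1e-12)

  est <- printed_studies()
  fe <- fixed_effects(est)
  expect_equal(fe$pooled_or, 1.93, tolerance = 0.02 / 1.93)
  expect_equal(fe$ci_lo, 1.50, tolerance = 0.02 / 1.50)
  expect_equal(fe$ci_hi, 2.49, tolerance = 0.02 / 2.49)
  expect_lt(fe$p, 1e-6)
  # cross-check against metafor's FE fit
  rma_fe <- metafor::rma(yi = est$ln_or, sei = est$se, method = "FE")
  expect_equal(fe$pooled_ln_or, as.numeric(rma_fe$beta), tolerance = 1e-10)
  expect_equal(fe$pooled_se, rma_fe$se, tolerance = 1e-10)
  # pooled precision dominates every study
  expect_true(all(fe$pooled_se <= est$se))
  expect_equal(sum(fe$weights), 1)
})

test_that("Cochran's Q matches hand arithmetic and metafor", {
  same <- study_estimates(c("a", "b"), c(2, 2), c(1.5, 1.5), c(8 / 3, 8 / 3))
  q0 <- cochran_q(same)
  expect_equal(q0$q, 0, tolerance = 1e-12)
  expect_equal(q0$q_p, 1)

  # hand example: lnORs 0 and 1 with weights 4 and 1
  two <- study_estimates(c("a", "b"), exp(c(0, 1)),
                         exp(c(0, 1) - 1.96 * c(0.5, 1)),
                         exp(c(0, 1) + 1.96 * c(0.5, 1)))
  qh <- cochran_q(two)
  # pooled = (4*0 + 1*1)/5 = 0.2; Q = 4*0.04 + 1*0.64 = 0.8
  expect_equal(qh$q, 0.8, tolerance = 1e-9)
  expect_equal(qh$df, 1)

  est <- printed_studies()
  qp <- cochran_q(est)
  expect_equal(qp$df, 2)
  rma_dl <- metafor::rma(yi = est$ln_or, sei = est$se, method = "DL")
  expect_equal(qp$q, rma_dl$QE, tolerance = 1e-10)
  expect_error(cochran_q(est[1, ]), "two")
})

test_that("DerSimonian-Laird reduces to fixed effects when Q <= df", {
  two <- study_estimates(c("a", "b"), c(2.0, 2.05), c(1.5, 1.53),
                         c(8 / 3, 2.747))
  dl <- dersimonian_laird(two)
  fe <- fixed_effects(two)
  expect_equal(dl$tau2, 0)
  expect_equal(dl$pooled_or, fe$pooled_or, tolerance = 1e-12)
  expect_equal(dl$pooled_se, fe$pooled_se, tolerance = 1e-12)
})

test_that("DerSimonian-Laird matches step-by-step arithmetic and metafor", {
  # heterogeneous two-study example worked by hand: lnOR 0 / 1,
  # se 0.5 / 1 -> w = (4, 1), pooled 0.2, Q = 0.8, df = 1,
  # C = 5 - 17/5 = 1.6, tau2 = max(0, -0.2/1.6) = 0 here, so make Q > df:
  thr <- study_estimates(c("a", "b", "c"), exp(c(0, 1, -0.5)),
                         exp(c(0, 1, -0.5) - 1.96 * c(0.3, 0.3, 0.3)),
                         exp(c(0, 1, -0.5) + 1.96 * c(0.3, 0.3, 0.3)))
  w <- rep(1 / 0.09, 3)
  pooled <- mean(c(0, 1, -0.5))
  Q <- sum(w * (c(0, 1, -0.5) - pooled)^2)
  C <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (Q - 2) / C)
  wr <- 1 / (0.09 + tau2)
  hand_lnor <- sum(wr * c(0, 1, -0.5)) / (3 * wr)
  hand_se <- 1 / sqrt(3 * wr)
  dl <- dersimonian_laird(thr)
  expect_equal(dl$tau2, tau2, tolerance = 1e-9)
  expect_equal(dl$pooled_ln_or, hand_lnor, tolerance = 1e-9)
  expect_equal(dl$pooled_se, hand_se, tolerance = 1e-9)

  est <- printed_studies()
  dlp <- dersimonian_laird(est)
  rma_dl <- metafor::rma(yi = est$ln_or, sei = est$se, method = "DL")
  expect_equal(dlp$tau2, rma_dl$tau2, tolerance = 1e-9)
  expect_equal(dlp$pooled_ln_or, as.numeric(rma_dl$beta), tolerance = 1e-9)
  expect_equal(dlp$pooled_se, rma_dl$se, tolerance = 1e-9)
  expect_equal(dlp$pooled_or, 1.92, tolerance = 0.03 / 1.92)
})

test_that("sample-size-weighted z follows its closed forms", {
  one <- study_estimates("a", 1.8, 1.2, 2.7, n = 300, p = 0.004)
  s1 <- sample_size_weighted_z(one)
  expect_equal(s1$z, qnorm(0.002, lower.tail = FALSE), tolerance = 1e-12)

  two <- study_estimates(c("a", "b"), c(1.8, 1.8), c(1.2, 1.2), c(2.7, 2.7),
                         n = c(300, 300), p = c(0.004, 0.004))
  s2 <- sample_size_weighted_z(two)
  expect_equal(s2$z, s1$z * sqrt(2), tolerance = 1e-12)

  est <- printed_studies()
  s3 <- sample_size_weighted_z(est)
  zi <- qnorm(est$p / 2, lower.tail = FALSE) * sign(est$ln_or)
  expect_equal(s3$z, sum(sqrt(est$n) * zi) / sqrt(sum(est$n)),
               tolerance = 1e-12)
  bad <- est; bad$p[1] <- 0
  expect_error(sample_size_weighted_z(bad), "undefined")
})

test_that("meta_analysis integrates models and exports forest rows", {
  est <- printed_studies()
  m <- meta_analysis(est)
  expect_equal(m$df, 2)
  # random CI contains the fixed point estimate; wider when tau2 > 0
  expect_gt(m$tau2, 0)
  expect_true(m$random$ci_lo < m$fixed$pooled_or &&
              m$fixed$pooled_or < m$random$ci_hi)
  expect_gt(log(m$random$ci_hi / m$random$ci_lo),
            log(m$fixed$ci_hi / m$fixed$ci_lo))
  fd <- forest_data(m)
  expect_equal(nrow(fd), 5)
  expect_equal(fd$label[4:5], c("pooled (fixed)", "pooled (random)"))
  expect_equal(sum(fd$weight_fixed, na.rm = TRUE), 1)
  # adding a study never increases the pooled fixed se
  m2 <- fixed_effects(est[1:2, ])
  expect_lte(meta_analysis(est)$fixed$pooled_se, m2$pooled_se)
})
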