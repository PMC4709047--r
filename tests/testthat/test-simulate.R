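# The synthetic cohort generator: determinism, frequency calibration,
# and the planted founder-haplotype structure.

test_that("identical seeds give byte-identical datasets", {
  sp <- cohort_spec(seed = 11, n_snps = 30, region_snps = 15,
                    founder_span = 6)
  d1 <- simulate_cohort(sp)
  d2 <- simulate_cohort(sp)
  expect_identical(d1, d2)
  d3 <- simulate_cohort(cohort_spec(seed = 12, n_snps = 30,
                                    region_snps = 15, founder_span = 6))
  expect_false(identical(d1$dosages, d3$dosages))
})

test_that("invalid specifications are rejected", {
  expect_error(cohort_spec(index_maf = 0.7), "index_maf")
  expect_error(cohort_spec(index_maf = 0), "index_maf")
  expect_error(cohort_spec(allelic_or = -1), "allelic_or")
  expect_error(cohort_spec(founder_span = 30, region_snps = 20), "founder_span")
  expect_error(cohort_spec(missing_rate = 0.5), "missing_rate")
  expect_error(cohort_spec(n_snps = 10, region_snps = 20), "region_snps")
})

test_that("stage IV frequency follows the odds transform of the planted OR", {
  # index_maf 0.14 at allelic OR 2.63 implies stage IV MAF
  # (0.14/0.86*2.63)/(1 + 0.14/0.86*2.63) = 0.2998
  sp <- cohort_spec(seed = 21, index_maf = 0.14, allelic_or = 2.63,
                    n_snps = 5, region_snps = 3, founder_span = 2,
                    old_span = 0, missing_rate = 0)
  expected_f4 <- (0.14 / 0.86 * 2.63) / (1 + 0.14 / 0.86 * 2.63)
  expect_equal(expected_f4, 0.2997883, tolerance = 1e-6)
  tt <- truth_table(sp)
  expect_equal(tt$group_frequencies$f_total[1], expected_f4, tolerance = 1e-12)
  ds <- simulate_cohort(sp)
  d4 <- ds$dosages[stage_samples(ds, "IV"), tt$index_id]
  f4_hat <- mean(d4) / 2
  se <- sqrt(expected_f4 * (1 - expected_f4) / (2 * length(d4)))
  expect_lt(abs(f4_hat - expected_f4), 3 * se)
})

test_that("a null spec (OR = 1) gives no group frequency difference", {
  sp <- cohort_spec(seed = 31, allelic_or = 1, n_snps = 5, region_snps = 3,
                    founder_span = 0, missing_rate = 0)
  ds <- simulate_cohort(sp)
  tt <- truth_table(sp)
  d4 <- ds$dosages[stage_samples(ds, "IV"), tt$index_id]
  d12 <- ds$dosages[stage_samples(ds, c("I", "II")), tt$index_id]
  f4 <- mean(d4) / 2; f12 <- mean(d12) / 2
  f <- mean(c(d4, d12)) / 2
  se <- sqrt(f * (1 - f) * (1 / (2 * length(d4)) + 1 / (2 * length(d12))))
  expect_lt(abs(f4 - f12), 3 * se)
})

test_that("frequency calibration holds in expectation over replicates", {
  n_rep <- 200
  f0s <- ors <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    sp <- cohort_spec(seed = 1000 + i, n_snps = 5, region_snps = 3,
                      founder_span = 2, old_span = 0, n_controls = 0,
                      missing_rate = 0)
    ds <- simulate_cohort(sp)
    d <- ds$dosages[, truth_table(sp)$index_id]
    g4 <- ds$samples$stage == "IV"
    a4 <- sum(d[g4]); b4 <- 2 * sum(g4) - a4
    a0 <- sum(d[!g4]); b0 <- 2 * sum(!g4) - a0
    f0s[i] <- a0 / (a0 + b0)
    ors[i] <- (a4 / b4) / (a0 / b0)
  }
  expect_lt(abs(mean(f0s) - 0.14), 2 * sd(f0s) / sqrt(n_rep))
  expect_lt(abs(mean(ors) - 2.63), 2 * sd(ors) / sqrt(n_rep))
})

test_that("truth_table echoes the planted parameters", {
  sp <- cohort_spec(seed = 41, n_snps = 40, region_snps = 21,
                    founder_span = 8, index_maf = 0.2, allelic_or = 1.8)
  tt <- truth_table(sp)
  expect_equal(tt$allelic_or, 1.8)
  expect_equal(tt$founder_span, 8)
  expect_length(tt$span_ids, 8)
  expect_equal(tt$group_frequencies$f_total[2], 0.2)
  ds <- simulate_cohort(sp)
  expect_true(ds$variants$is_index[ds$variants$variant_id == tt$index_id])
  expect_true(all(tt$span_ids %in% tt$region_ids))

  # no founder structure: expected span difference collapses to zero
  sp0 <- cohort_spec(seed = 41, n_snps = 40, region_snps = 21,
                     founder_span = 0)
  expect_equal(truth_table(sp0)$expected_span_difference, 0)
})

test_that("noiseless haplotype pool carries complete LD across the span", {
  # direct haplotype counting on the phased pool (no EM): every span SNP
  # must be at |D'| = 1 with the index among stage IV chromosomes
  sp <- cohort_spec(seed = 51, n_snps = 60, region_snps = 60,
                    founder_span = 20, missing_rate = 0, n_controls = 0)
  ds <- simulate_cohort(sp, keep_haplotypes = TRUE)
  tt <- truth_table(sp)
  hp <- attr(ds, "haplotypes")
  g4 <- ds$samples$stage == "IV"
  haps <- rbind(hp$h1[g4, ], hp$h2[g4, ])
  colnames(haps) <- ds$variants$variant_id
  idx <- haps[, tt$index_id]
  n_complete <- 0
  for (sid in tt$span_ids) {
    f <- c(AB = mean(idx == 1 & haps[, sid] == 1),
           Ab = mean(idx == 1 & haps[, sid] == 0),
           aB = mean(idx == 0 & haps[, sid] == 1),
           ab = mean(idx == 0 & haps[, sid] == 0))
    if (min(f) < 1e-12) n_complete <- n_complete + 1  # one class absent
  }
  expect_gte(n_complete, 20)
})

test_that("founder structure lengthens the stage IV span; null is exchangeable", {
  wins <- 0
  for (i in 1:15) {
    sp <- cohort_spec(seed = 600 + i, n_snps = 21, region_snps = 21,
                      founder_span = 10, allelic_or = 2.6, n_controls = 0)
    ds <- simulate_cohort(sp)
    tt <- truth_table(sp)
    c4 <- span_count(ds, tt$index_id, group = "IV")$count
    c12 <- span_count(ds, tt$index_id, group = c("I", "II"))$count
    wins <- wins + (c4 > c12)
  }
  expect_gte(wins, 12)  # majority, strongly

  diffs <- numeric(15)
  for (i in 1:15) {
    sp <- cohort_spec(seed = 700 + i, n_snps = 21, region_snps = 21,
                      founder_span = 0, allelic_or = 1, n_controls = 0)
    ds <- simulate_cohort(sp)
    tt <- truth_table(sp)
    diffs[i] <- span_count(ds, tt$index_id, group = "IV")$count -
      span_count(ds, tt$index_id, group = c("I", "II"))$count
  }
  # small-group advantage aside, no systematic founder signal:
  # both directions occur and the mean difference stays small
  expect_lt(abs(mean(diffs)), 4)
})

test_that("an OR incompatible with the MAF is rejected", {
  # odds transform keeps f4 < 1 for any finite OR, so the guard only
  # trips on degenerate input
  expect_silent(validate <- simulate_cohort(
    cohort_spec(seed = 1, index_maf = 0.5, allelic_or = 50, n_snps = 3,
                region_snps = 2, founder_span = 1, old_span = 0,
                n_stage4 = 20, n_stage12 = 20, n_controls = 0)))
})

test_that("covariate-effect knob shifts carrier frequency with sex", {
  sp <- cohort_spec(seed = 81, n_snps = 3, region_snps = 2, founder_span = 1,
                    old_span = 0, sex_beta = 1.5, missing_rate = 0,
                    n_stage4 = 500, n_stage12 = 500, n_controls = 0)
  ds <- simulate_cohort(sp)
  tt <- truth_table(sp)
  d <- ds$dosages[, tt$index_id]
  fm <- mean(d[ds$samples$sex == "male"]) / 2
  ff <- mean(d[ds$samples$sex == "female"]) / 2
  expect_gt(fm, ff)
})
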