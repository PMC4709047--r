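# Two-locus EM, D', and the index-SNP span count.

test_that("EM equals direct haplotype counting when phase is unambiguous", {
  # no double heterozygotes: every genotype pair resolves uniquely
  d1 <- c(0, 0, 1, 2, 2, 1, 0, 2)
  d2 <- c(0, 2, 2, 2, 0, 0, 1, 1)
  stopifnot(sum(d1 == 1 & d2 == 1) == 0)
  fit <- em_haplotype_freqs(d1, d2)
  # hand counting of the 16 haplotypes: outside double heterozygotes the
  # alleles of at least one locus coincide, so any chromosome pairing is
  # phase-correct
  count_haps <- function(d1, d2) {
    h <- c(0, 0, 0, 0)  # AB, Ab, aB, ab
    for (i in seq_along(d1)) {
      if (d1[i] == 1 && d2[i] == 1) stop("ambiguous")
      av <- rep(c(1, 0), c(d1[i], 2 - d1[i]))
      bv <- rep(c(1, 0), c(d2[i], 2 - d2[i]))
      for (k in 1:2) {
        cls <- 2 * (1 - av[k]) + (1 - bv[k]) + 1
        h[cls] <- h[cls] + 1
      }
    }
    h / (2 * length(d1))
  }
  expect_equal(c(fit$p_AB, fit$p_Ab, fit$p_aB, fit$p_ab),
               count_haps(d1, d2), tolerance = 1e-9)
})

test_that("EM log-likelihood matches grid-search maximisation", {
  set.seed(18)
  for (rep in 1:8) {
    # genotypes with genuine double-het ambiguity, from correlated loci
    n <- 60
    h <- matrix(rbinom(4 * n, 1, 0.35), 2 * n, 2)
    flip <- runif(2 * n) < 0.7
    h[flip, 2] <- h[flip, 1]
    d1 <- h[1:n, 1] + h[(n + 1):(2 * n), 1]
    d2 <- h[1:n, 2] + h[(n + 1):(2 * n), 2]
    if (all(d1 == 0) || all(d1 == 2) || all(d2 == 0) || all(d2 == 2)) next
    fit <- em_haplotype_freqs(d1, d2)
    tab9 <- founderscan:::pair_tables(d1, matrix(d2, ncol = 1))[1, ]
    oracle <- grid_ll_max_fast(tab9)
    expect_lt(abs(fit$loglik - oracle$ll), 1e-6)
    expect_gte(fit$loglik, oracle$ll - 1e-9)   # EM at least as good
  }
  # the fast grid oracle agrees with its pairwise-composed sibling
  tab_chk <- c(5, 3, 1, 4, 6, 2, 1, 3, 5)
  expect_equal(grid_ll_max_fast(tab_chk, step0 = 0.05, zooms = 1)$ll,
               grid_ll_max(tab_chk, step0 = 0.05, zooms = 1)$ll,
               tolerance = 1e-9)
})

test_that("EM recovers generating pool frequencies from paired haplotypes", {
  sp <- cohort_spec(seed = 19, n_snps = 30, region_snps = 30,
                    founder_span = 10, missing_rate = 0, n_controls = 0,
                    n_stage4 = 300, n_stage12 = 300)
  ds <- simulate_cohort(sp, keep_haplotypes = TRUE)
  tt <- truth_table(sp)
  hp <- attr(ds, "haplotypes")
  j_idx <- match(tt$index_id, ds$variants$variant_id)
  for (sid in tt$span_ids[c(1, 5, 10)]) {
    j <- match(sid, ds$variants$variant_id)
    fit <- em_haplotype_freqs(ds$dosages[, j_idx], ds$dosages[, j])
    truth_AB <- mean(c(hp$h1[, j_idx] & hp$h1[, j],
                       hp$h2[, j_idx] & hp$h2[, j]))
    se <- sqrt(truth_AB * (1 - truth_AB) / (2 * nrow(ds$dosages)))
    expect_lt(abs(fit$p_AB - truth_AB), 3 * max(se, 1e-3))
  }
})

test_that("EM log-likelihood never decreases across iterations", {
  set.seed(20)
  for (rep in 1:20) {
    tab <- matrix(rpois(9, 8), 1, 9)
    fit <- founderscan:::em_tables(tab, trace = TRUE)
    expect_true(all(diff(fit$history) >= -1e-10))
  }
})

test_that("monomorphic loci are rejected", {
  expect_error(em_haplotype_freqs(rep(0, 20), rbinom(20, 2, 0.3)),
               "LD undefined")
  expect_error(em_haplotype_freqs(rbinom(20, 2, 0.3), rep(2, 20)),
               "LD undefined")
})

test_that("d_prime follows its closed form", {
  # equilibrium: D = 0
  expect_equal(d_prime(c(0.35 * 0.4, 0.35 * 0.6, 0.65 * 0.4, 0.65 * 0.6)), 0)
  # an empty haplotype class pins |D'| at 1
  expect_equal(abs(d_prime(c(0.3, 0, 0.2, 0.5))), 1)
  expect_equal(abs(d_prime(c(0, 0.3, 0.2, 0.5))), 1)
  # random tables match the hand formula
  set.seed(21)
  for (rep in 1:25) {
    fr <- as.vector(stats::rmultinom(1, 200, runif(4, 0.05, 1))) / 200
    pA_ <- fr[1] + fr[2]; pB_ <- fr[1] + fr[3]
    if (pA_ <= 0 || pA_ >= 1 || pB_ <= 0 || pB_ >= 1) next
    pA <- fr[1] + fr[2]; pB <- fr[1] + fr[3]
    D <- fr[1] - pA * pB
    dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
            else min(pA * pB, (1 - pA) * (1 - pB))
    expect_equal(d_prime(fr), if (D == 0) 0 else D / dmax, tolerance = 1e-12)
    # allele-label swap at locus 1 negates D' (|D'| invariant)
    expect_equal(d_prime(fr[c(3, 4, 1, 2)]), -d_prime(fr), tolerance = 1e-12)
  }
  expect_error(d_prime(c(0.5, 0.5, 0, 0)), "monomorphic")
})

test_that("span counts match exhaustive hand computation on a tiny fixture", {
  # 8 samples, 5 SNPs; SNP 3 is the index. SNPs 2 and 4 copy the index
  # exactly (|D'| = 1); SNP 1 is a shuffled copy breaking one haplotype
  # class; SNP 5 is independent.
  idx <- c(0, 1, 2, 1, 0, 0, 1, 2)
  dos <- cbind(c(1, 0, 2, 1, 0, 0, 1, 2),   # recombinant vs index
               idx, idx, idx,
               c(2, 0, 1, 0, 1, 2, 0, 1))
  ds <- make_dataset(dos, stage = rep("IV", 8), index = 3)
  sc <- span_count(ds, "v003", group = "IV")
  expect_equal(sort(names(sc$d_prime)),
               sort(c("v001", "v002", "v004", "v005")))
  expect_equal(abs(unname(sc$d_prime["v002"])), 1, tolerance = 1e-9)
  expect_equal(abs(unname(sc$d_prime["v004"])), 1, tolerance = 1e-9)
  # hand EM check for v001 via the grid oracle: not complete LD
  expect_lt(abs(sc$d_prime["v001"]), 1 - 1e-6)
  expect_gte(sc$count, 2)
  # a region holding only the index SNP counts nothing
  ds1 <- subset_variants(ds, 3)
  expect_equal(span_count(ds1, "v003", group = "IV")$count, 0)
})

test_that("span_count is monotone non-increasing in strictness", {
  sp <- cohort_spec(seed = 22, n_snps = 31, region_snps = 31,
                    founder_span = 10, n_controls = 0)
  ds <- simulate_cohort(sp)
  tt <- truth_table(sp)
  c_tight <- span_count(ds, tt$index_id, group = "IV", tolerance = 1e-9)$count
  c_mid <- span_count(ds, tt$index_id, group = "IV", tolerance = 1e-3)$count
  c_loose <- span_count(ds, tt$index_id, group = "IV", tolerance = 0.2)$count
  expect_lte(c_tight, c_mid)
  expect_lte(c_mid, c_loose)
})

test_that("span_count validates the index and region", {
  dos <- cbind(rep(0L, 6), rbinom(6, 2, 0.5))
  ds <- make_dataset(dos, stage = rep("IV", 6), index = 1)
  expect_error(span_count(ds, "v001", group = "IV"), "monomorphic")
  expect_error(span_count(ds, "nope", group = "IV"), "not found")
  ds2 <- make_dataset(cbind(rbinom(6, 2, 0.5), rbinom(6, 2, 0.5)),
                      stage = rep("IV", 6), index = 1)
  expect_error(span_count(ds2, "v001", region = c(5000, 6000)),
               "outside the region")
})
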