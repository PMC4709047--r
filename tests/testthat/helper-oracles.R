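# Independent oracles and fixture builders used across the test suite.
# Each oracle recomputes a quantity by a different route than the package
# (recurrence, brute-force grid, Monte Carlo) so agreement is evidence,
# not tautology.

# --- Hardy-Weinberg exact test by upward recurrence -------------------------
# Builds the conditional distribution of the heterozygote count from the
# parity-minimal value using the ratio P(h+2)/P(h) = 4*homr*homc/((h+1)(h+2)),
# then sums probabilities <= the observed one.
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n1 <- min(2 * n_AA + n_Aa, 2 * n_aa + n_Aa)
  n2 <- 2 * n - n1
  hs <- seq(n1 %% 2, n1, by = 2)
  pr <- numeric(length(hs))
  pr[1] <- 1
  if (length(hs) > 1) {
    for (i in seq_len(length(hs) - 1)) {
      h <- hs[i]
      homr <- (n1 - h) / 2
      homc <- (n2 - h) / 2
      pr[i + 1] <- pr[i] * 4 * homr * homc / ((h + 1) * (h + 2))
    }
  }
  pr <- pr / sum(pr)
  obs <- pr[match(n_Aa, hs)]
  min(1, sum(pr[pr <= obs * (1 + 1e-9)]))
}

# --- two-locus likelihood, written from genotype probabilities --------------
# Observed-data log-likelihood of a 3x3 genotype-pair count table under
# haplotype frequencies (pAB, pAb, paB, pab), composed pair by pair.
oracle_pair_ll <- function(fr, tab9) {
  pAB <- fr[1]; pAb <- fr[2]; paB <- fr[3]; pab <- fr[4]
  gp <- function(g1, g2) {
    # sum over ordered haplotype pairs consistent with the genotype pair
    haps <- rbind(c(1, 1), c(1, 0), c(0, 1), c(0, 0))  # (A?, B?)
    pr <- c(pAB, pAb, paB, pab)
    tot <- 0
    for (i in 1:4) for (j in 1:4)
      if (haps[i, 1] + haps[j, 1] == g1 && haps[i, 2] + haps[j, 2] == g2)
        tot <- tot + pr[i] * pr[j]
    tot
  }
  ll <- 0
  for (g1 in 0:2) for (g2 in 0:2) {
    nc <- tab9[3 * g1 + g2 + 1]
    if (nc > 0) ll <- ll + nc * log(gp(g1, g2))
  }
  ll
}

# Exhaustive maximisation of oracle_pair_ll over the haplotype-frequency
# simplex: coarse grid then three zoom refinements around the best point.
grid_ll_max <- function(tab9, step0 = 0.02, zooms = 3) {
  eval_grid <- function(pAB, pAb, paB) {
    pab <- 1 - pAB - pAb - paB
    keep <- pab >= -1e-12
    pAB <- pAB[keep]; pAb <- pAb[keep]; paB <- paB[keep]
    pab <- pmax(pab[keep], 0)
    ll <- vapply(seq_along(pAB), function(i)
      oracle_pair_ll(c(pAB[i], pAb[i], paB[i], pab[i]), tab9), numeric(1))
    i <- which.max(ll)
    list(fr = c(pAB[i], pAb[i], paB[i], pab[i]), ll = ll[i])
  }
  g <- seq(0, 1, by = step0)
  gr <- expand.grid(pAB = g, pAb = g, paB = g)
  best <- eval_grid(gr$pAB, gr$pAb, gr$paB)
  step <- step0
  for (z in seq_len(zooms)) {
    newstep <- step / 10
    rng <- function(c0) {
      v <- seq(max(0, c0 - step), min(1, c0 + step), by = newstep)
      v
    }
    gr <- expand.grid(pAB = rng(best$fr[1]), pAb = rng(best$fr[2]),
                      paB = rng(best$fr[3]))
    cand <- eval_grid(gr$pAB, gr$pAb, gr$paB)
    if (cand$ll > best$ll) best <- cand
    step <- newstep
  }
  best
}

# vectorised version of the oracle likelihood for grid use (much faster,
# still composed independently from genotype-pair probabilities)
grid_ll_max_fast <- function(tab9, step0 = 0.02, zooms = 3) {
  eval_grid <- function(pAB, pAb, paB) {
    pab <- 1 - pAB - pAb - paB
    keep <- pab >= -1e-12
    pAB <- pAB[keep]; pAb <- pAb[keep]; paB <- paB[keep]
    pab <- pmax(pab[keep], 0)
    P <- cbind(pab^2, 2 * paB * pab, paB^2,
               2 * pAb * pab, 2 * (pAB * pab + pAb * paB), 2 * pAB * paB,
               pAb^2, 2 * pAB * pAb, pAB^2)
    ll <- as.vector(log(pmax(P, 1e-300)) %*% tab9)
    ll[rowSums(P == 0 & rep(tab9 > 0, each = nrow(P))) > 0] <- -Inf
    i <- which.max(ll)
    list(fr = c(pAB[i], pAb[i], paB[i], pab[i]), ll = ll[i])
  }
  g <- seq(0, 1, by = step0)
  gr <- expand.grid(pAB = g, pAb = g, paB = g)
  best <- eval_grid(gr$pAB, gr$pAb, gr$paB)
  step <- step0
  for (z in seq_len(zooms)) {
    newstep <- step / 10
    rng <- function(c0) seq(max(0, c0 - step), min(1, c0 + step), by = newstep)
    gr <- expand.grid(pAB = rng(best$fr[1]), pAb = rng(best$fr[2]),
                      paB = rng(best$fr[3]))
    cand <- eval_grid(gr$pAB, gr$pAb, gr$paB)
    if (cand$ll > best$ll) best <- cand
    step <- newstep
  }
  best
}

# --- small dataset builders -------------------------------------------------
make_dataset <- function(dos, stage = NULL, pos = NULL, chrom = "chr1",
                         index = NULL) {
  n <- nrow(dos); m <- ncol(dos)
  if (is.null(stage)) stage <- rep(c("IV", "I"), length.out = n)
  if (is.null(pos)) pos <- 1000L * seq_len(m)
  samples <- data.frame(sample_id = sprintf("s%03d", seq_len(n)),
                        stage = stage, age = 60 + seq_len(n) %% 20,
                        sex = rep(c("male", "female"), length.out = n),
                        cohort_id = "test", stringsAsFactors = FALSE)
  variants <- data.frame(variant_id = sprintf("v%03d", seq_len(m)),
                         chrom = chrom, pos = pos, a1 = "A", a2 = "G",
                         is_index = seq_len(m) == (index %||% 0),
                         stringsAsFactors = FALSE)
  genotype_dataset(dos, samples, variants)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# dosage vectors from genotype counts, in a fixed deterministic order
dosage_from_counts <- function(n0, n1, n2) rep(0:2, c(n0, n1, n2))

# per-study printed estimates used throughout the meta-analysis tests:
# discovery 2.83 (1.81-4.44), validation #1 1.89 (1.27-2.80),
# validation #2 1.31 (0.81-2.12)
printed_studies <- function() {
  study_estimates(c("discovery", "validation1", "validation2"),
                  or_ = c(2.83, 1.89, 1.31),
                  ci_lo = c(1.81, 1.27, 0.81),
                  ci_hi = c(4.44, 2.80, 2.12),
                  n = c(323, 462, 343),
                  p = c(2.73e-6, 8.05e-4, 0.32))
}
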