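# Two-locus linkage disequilibrium from unphased genotypes.
#
# All estimation runs on 3x3 genotype-pair count tables; the EM engine is
# vectorised across many SNP pairs at once because the span permutation
# test recomputes index-vs-SNP LD for every permutation.

# 3x3 genotype cross-tabulations of one index dosage vector against every
# column of a dosage matrix, pairwise-complete. Returns a K x 9 count
# matrix, column order (g1, g2) = (0,0),(0,1),(0,2),(1,0),...,(2,2).
pair_tables <- function(d1, dmat) {
  K <- ncol(dmat)
  tab <- matrix(0L, K, 9L)
  for (g in 0:2) {
    rows <- which(d1 == g)
    if (!length(rows)) next
    sub <- dmat[rows, , drop = FALSE]
    for (h in 0:2)
      tab[, 3L * g + h + 1L] <- as.integer(colSums(sub == h, na.rm = TRUE))
  }
  tab
}

# Observed-data log-likelihood of genotype-pair tables given haplotype
# frequencies (each argument a vector across tables).
ll_tables <- function(pAB, pAb, paB, pab, tab) {
  P <- list(pab * pab, 2 * paB * pab, paB * paB,
            2 * pAb * pab, 2 * (pAB * pab + pAb * paB), 2 * pAB * paB,
            pAb * pAb, 2 * pAB * pAb, pAB * pAB)
  ll <- 0
  for (cc in 1:9) {
    tc <- tab[, cc]
    # adding (tc == 0) makes 0 * log(0) contribute exactly 0
    ll <- ll + tc * log(pmax(P[[cc]], 1e-300) + (tc == 0))
  }
  ll
}

# EM over the double-heterozygote phase ambiguity, vectorised across the
# rows of `tab` (one genotype-pair count table per row). Initialised at
# linkage equilibrium; iterates until the log-likelihood change is < tol
# or max_iter. Converged rows are compacted out of the working set, which
# keeps the span permutation test affordable. With trace = TRUE (single
# table only) the per-iteration log-likelihood path is returned.
em_tables <- function(tab, tol = 1e-12, max_iter = 1000L, trace = FALSE) {
  tab <- matrix(as.numeric(tab), nrow = NROW(tab))
  M <- nrow(tab)
  N <- rowSums(tab)
  twoN <- 2 * N
  # haplotype counts fixed by unambiguous genotypes
  cAB <- 2 * tab[, 9] + tab[, 8] + tab[, 6]
  cAb <- 2 * tab[, 7] + tab[, 8] + tab[, 4]
  caB <- 2 * tab[, 3] + tab[, 2] + tab[, 6]
  cab <- 2 * tab[, 1] + tab[, 2] + tab[, 4]
  ndh <- tab[, 5]
  pA <- (cAB + cAb + ndh) / twoN
  pB <- (caB + cAB + ndh) / twoN
  pAB <- pA * pB; pAb <- pA * (1 - pB); paB <- (1 - pA) * pB
  pab <- (1 - pA) * (1 - pB)
  ll <- ll_tables(pAB, pAb, paB, pab, tab)
  hist <- if (trace) ll
  iters <- integer(M)
  act <- seq_len(M)
  for (it in seq_len(max_iter)) {
    if (!length(act)) break
    den <- pAB[act] * pab[act] + pAb[act] * paB[act]
    rho <- ifelse(den > 0, pAB[act] * pab[act] / pmax(den, 1e-300), 0.5)
    nd <- ndh[act]
    pAB2 <- (cAB[act] + nd * rho) / twoN[act]
    pab2 <- (cab[act] + nd * rho) / twoN[act]
    pAb2 <- (cAb[act] + nd * (1 - rho)) / twoN[act]
    paB2 <- (caB[act] + nd * (1 - rho)) / twoN[act]
    ll2 <- ll_tables(pAB2, pAb2, paB2, pab2, tab[act, , drop = FALSE])
    pAB[act] <- pAB2; pAb[act] <- pAb2; paB[act] <- paB2; pab[act] <- pab2
    iters[act] <- it
    conv <- ll2 - ll[act] < tol
    ll[act] <- ll2
    if (trace) hist <- c(hist, ll)
    act <- act[!conv]
  }
  list(freqs = cbind(p_AB = pAB, p_Ab = pAb, p_aB = paB, p_ab = pab),
       loglik = ll, iters = iters, n_used = N,
       history = if (trace) hist)
}

# 0/1 indicator columns for dosage levels 0/1/2 (missing rows all zero).
onehot3 <- function(d) {
  cbind(!is.na(d) & d == 0, !is.na(d) & d == 1, !is.na(d) & d == 2) + 0
}

# Genotype-pair count tables of one index dosage vector against every
# column of `dmat`, for every sample subset given as a 0/1 membership
# column of `S` — one BLAS crossproduct per (g, h) genotype cell. Returns
# a (G*K) x 9 matrix; row r corresponds to subset (r-1) %% G + 1 and SNP
# (r-1) %/% G + 1.
batch_pair_tables <- function(d_index, dmat, S) {
  A <- onehot3(d_index)
  G <- ncol(S); K <- ncol(dmat)
  tab <- matrix(0, G * K, 9L)
  for (h in 0:2) {
    Bh <- (!is.na(dmat) & dmat == h) + 0
    for (g in 0:2)
      tab[, 3L * g + h + 1L] <- as.vector(crossprod(S, A[, g + 1] * Bh))
  }
  tab
}

# D, D' and r^2 from haplotype frequency matrix (columns pAB,pAb,paB,pab).
dprime_from_freqs <- function(fr) {
  fr <- matrix(fr, ncol = 4)
  pA <- fr[, 1] + fr[, 2]; pB <- fr[, 1] + fr[, 3]
  D <- fr[, 1] - pA * pB
  dmax <- ifelse(D >= 0,
                 pmin(pA * (1 - pB), (1 - pA) * pB),
                 pmin(pA * pB, (1 - pA) * (1 - pB)))
  dp <- ifelse(D == 0, 0, D / dmax)
  r2 <- ifelse(D == 0, 0,
               D^2 / (pA * (1 - pA) * pB * (1 - pB)))
  list(D = D, d_prime = dp, r2 = r2, dmax = dmax)
}

#' Two-locus haplotype frequencies by EM
#'
#' Maximum-likelihood haplotype frequencies for a pair of biallelic loci
#' from unphased dosages, resolving the double-heterozygote phase ambiguity
#' by expectation-maximisation. Samples missing at either locus are
#' excluded pairwise. The EM starts at linkage equilibrium and never
#' decreases the observed-data log-likelihood.
#'
#' @param dos1,dos2 dosage vectors (0/1/2/NA) of the two loci, A = allele
#'   counted by `dos1`, B = allele counted by `dos2`.
#' @param tol convergence tolerance on the log-likelihood change.
#' @param max_iter iteration cap.
#' @return an object of class `pair_ld`: haplotype frequencies `p_AB`,
#'   `p_Ab`, `p_aB`, `p_ab`, the disequilibrium coefficient `D`, signed
#'   `d_prime`, `r2`, `n_used`, `em_iterations` and the final `loglik`.
#' @export
em_haplotype_freqs <- function(dos1, dos2, tol = 1e-12, max_iter = 1000L) {
  keep <- !is.na(dos1) & !is.na(dos2)
  d1 <- dos1[keep]; d2 <- dos2[keep]
  if (!length(d1)) stop("no samples with complete genotypes at both loci")
  if (length(unique(d1)) == 1L || all(d1 == 0) || all(d1 == 2))
    stop("LD undefined: locus 1 monomorphic in analysis set")
  if (length(unique(d2)) == 1L || all(d2 == 0) || all(d2 == 2))
    stop("LD undefined: locus 2 monomorphic in analysis set")
  tab <- pair_tables(d1, matrix(d2, ncol = 1))
  fit <- em_tables(tab, tol = tol, max_iter = max_iter)
  fr <- fit$freqs[1, ]
  ld <- dprime_from_freqs(fit$freqs)
  structure(list(p_AB = fr[["p_AB"]], p_Ab = fr[["p_Ab"]],
                 p_aB = fr[["p_aB"]], p_ab = fr[["p_ab"]],
                 D = ld$D[1], d_prime = ld$d_prime[1], r2 = ld$r2[1],
                 n_used = fit$n_used[1], em_iterations = fit$iters[1],
                 loglik = fit$loglik[1]),
            class = "pair_ld")
}

#' @export
print.pair_ld <- function(x, ...) {
  cat(sprintf("pair_ld: D = %.4f  D' = %.4f  r2 = %.4f  (n = %d, %d EM iterations)\n",
              x$D, x$d_prime, x$r2, x$n_used, x$em_iterations))
  cat(sprintf("  haplotype frequencies: AB %.4f  Ab %.4f  aB %.4f  ab %.4f\n",
              x$p_AB, x$p_Ab, x$p_aB, x$p_ab))
  invisible(x)
}

#' Normalised linkage disequilibrium D'
#'
#' `D / Dmax` with the sign of `D`, where `Dmax` is the frequency-
#' constrained maximum `min(pA*(1-pB), (1-pA)*pB)` for positive `D` and
#' `min(pA*pB, (1-pA)*(1-pB))` for negative `D`. `|D'| = 1` means at least
#' one of the four two-locus haplotype classes is absent.
#'
#' @param pair a `pair_ld` object from [em_haplotype_freqs()], or a numeric
#'   vector of the four haplotype frequencies `(p_AB, p_Ab, p_aB, p_ab)`.
#' @return signed D' in [-1, 1]; exactly 0 when D = 0.
#' @export
d_prime <- function(pair) {
  fr <- if (inherits(pair, "pair_ld"))
    c(pair$p_AB, pair$p_Ab, pair$p_aB, pair$p_ab)
  else as.numeric(pair)
  if (length(fr) != 4) stop("need four haplotype frequencies")
  if (any(fr < -1e-9) || abs(sum(fr) - 1) > 1e-6)
    stop("invalid haplotype frequencies")
  ld <- dprime_from_freqs(rbind(fr))
  if (ld$dmax[1] <= 0 && ld$D[1] != 0)
    stop("D' undefined: a locus is monomorphic")
  pA <- fr[1] + fr[2]; pB <- fr[1] + fr[3]
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1)
    stop("D' undefined: a locus is monomorphic")
  ld$d_prime[1]
}

# Count engine shared by span_count() and the permutation test: index
# dosages vs a dosage matrix, for every sample subset given as a 0/1
# membership column of S. SNP/subset combinations where either locus is
# monomorphic are skipped (their D' is undefined).
span_counts_groups <- function(d_index, dmat, S, tolerance) {
  G <- ncol(S); K <- ncol(dmat)
  tab <- batch_pair_tables(d_index, dmat, S)
  N <- rowSums(tab)
  pA <- (tab[, 4] + tab[, 5] + tab[, 6] +
           2 * (tab[, 7] + tab[, 8] + tab[, 9])) / (2 * pmax(N, 1))
  pB <- (tab[, 2] + tab[, 5] + tab[, 8] +
           2 * (tab[, 3] + tab[, 6] + tab[, 9])) / (2 * pmax(N, 1))
  ok <- N > 0 & pA > 0 & pA < 1 & pB > 0 & pB < 1
  dp <- rep(NA_real_, G * K)
  if (any(ok)) {
    fit <- em_tables(tab[ok, , drop = FALSE])
    dp[ok] <- dprime_from_freqs(fit$freqs)$d_prime
  }
  hit <- !is.na(dp) & abs(dp) >= 1 - tolerance
  list(counts = rowSums(matrix(hit, G, K)),
       d_prime = matrix(dp, G, K), ok = matrix(ok, G, K))
}

span_count_engine <- function(d_index, dmat, tolerance) {
  r <- span_counts_groups(d_index, dmat,
                          matrix(1, length(d_index), 1), tolerance)
  list(d_prime = r$d_prime[1, ], count = r$counts[1],
       skipped = which(!r$ok[1, ]))
}

#' Count SNPs in complete LD with an index SNP within a sample group
#'
#' For each region SNP, estimates index-vs-SNP haplotype frequencies by EM
#' within the group's samples and counts SNPs with `|D'| >= 1 - tolerance`.
#' The index SNP itself is excluded from its own count. SNPs monomorphic
#' within the group are skipped (recorded in the result). Note that the raw
#' count is descriptive: |D'| = 1 is easier to attain in smaller groups, so
#' group comparisons should use [permutation_span_test()].
#'
#' @param dataset a [genotype_dataset()].
#' @param index_id variant id of the index SNP.
#' @param region optional `c(start, end)` base-pair bounds (1-based,
#'   inclusive) on the index SNP's chromosome; default spans all SNPs on
#'   that chromosome.
#' @param group character vector of stage labels defining the sample group
#'   (e.g. `"IV"` or `c("I", "II")`).
#' @param shared_snps optional variant ids to restrict the count to (e.g.
#'   markers present on both of two genotyping arrays).
#' @param tolerance slack on `|D'| = 1`; EM reaches the frequency-simplex
#'   boundary only in the limit.
#' @return an object of class `span_count`: `group`, `region`, `snp_ids`,
#'   `count`, per-SNP `d_prime`, and `skipped` ids.
#' @export
span_count <- function(dataset, index_id, region = NULL,
                       group = "IV", shared_snps = NULL,
                       tolerance = 1e-6) {
  v <- dataset$variants
  ii <- match(index_id, v$variant_id)
  if (is.na(ii)) stop("index SNP '", index_id, "' not found")
  chrom <- v$chrom[ii]
  if (is.null(region)) region <- range(v$pos[v$chrom == chrom])
  if (v$pos[ii] < region[1] || v$pos[ii] > region[2])
    stop("index SNP is outside the region")
  sel <- v$chrom == chrom & v$pos >= region[1] & v$pos <= region[2] &
    v$variant_id != index_id
  if (!is.null(shared_snps)) sel <- sel & v$variant_id %in% shared_snps
  rows <- stage_samples(dataset, group)
  if (!length(rows)) stop("group has no samples")
  d_index <- dataset$dosages[rows, ii]
  pA <- mean(d_index, na.rm = TRUE) / 2
  if (is.nan(pA) || pA <= 0 || pA >= 1)
    stop("index SNP monomorphic in group")
  dmat <- dataset$dosages[rows, sel, drop = FALSE]
  eng <- span_count_engine(d_index, dmat, tolerance)
  ids <- v$variant_id[sel]
  dp <- stats::setNames(eng$d_prime, ids)
  structure(list(group = paste(group, collapse = "/"),
                 region = c(chrom = chrom, start = region[1], end = region[2]),
                 snp_ids = ids[!seq_along(ids) %in% eng$skipped],
                 count = eng$count, d_prime = dp,
                 skipped = ids[eng$skipped], tolerance = tolerance),
            class = "span_count")
}

#' @export
print.span_count <- function(x, ...) {
  cat(sprintf("span_count: %d of %d SNPs with |D'| = 1 to the index (group %s)\n",
              x$count, length(x$snp_ids), x$group))
  if (length(x$skipped))
    cat("  skipped (monomorphic in group):", length(x$skipped), "\n")
  invisible(x)
}
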