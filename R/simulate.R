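#' Specify a synthetic case-case cohort
#'
#' Parameters of the haplotype-pool simulator. Defaults mirror the design of
#' a discovery cohort of Ashkenazi-like colon cancer cases: 89 stage IV
#' (metastatic) versus 234 stage I/II (organ-confined) cases plus 139
#' cancer-free controls used only as a minor-allele-frequency reference, a
#' biallelic index SNP with stage I/II minor-allele frequency 0.14 and a
#' per-allele odds ratio of 2.63 for stage IV, sitting inside an LD block in
#' which stage IV carriers share a long conserved flanking haplotype.
#'
#' The risk allele segregates on two lineages: a "young" founder haplotype
#' conserved across `founder_span` flanking SNPs, and an "old" lineage
#' conserved only across `old_span` SNPs. Stage IV risk-allele copies are
#' all of founder origin; among stage I/II copies a fraction `old_frac`
#' rides the old lineage. This nesting is what makes the D'=1 span around
#' the index SNP longer in the metastatic group while the total per-allele
#' odds ratio between the groups stays exactly `allelic_or`.
#'
#' @param n_stage4,n_stage12,n_controls group sample counts (> 0;
#'   `n_controls` may be 0).
#' @param n_snps total number of variants simulated.
#' @param region_snps number of variants in the founder LD block
#'   (`founder_span <= region_snps <= n_snps`).
#' @param index_maf minor-allele frequency of the index SNP among stage
#'   I/II cases, in (0, 0.5].
#' @param allelic_or per-allele odds ratio for stage IV vs stage I/II (> 0).
#' @param founder_span number of flanking SNPs conserved on the founder
#'   haplotype.
#' @param old_frac fraction of stage I/II risk-allele copies on the old
#'   (short) lineage, in [0, 1).
#' @param old_span flanking SNPs conserved on the old lineage; default
#'   `floor(founder_span / 3)`.
#' @param background_maf_range length-2 range of allele-1 frequencies for
#'   null background SNPs.
#' @param missing_rate fraction of dosages masked missing, in [0, 0.1].
#' @param age_mean,age_sd,male_frac covariate distribution (years; fraction
#'   male).
#' @param age_beta,sex_beta optional per-sample shifts (log-odds per s.d.
#'   of age / for males) of the risk-allele frequency, used to exercise
#'   confounding adjustment; both default to 0 (covariates carry no effect).
#' @param cohort_id label stored with every sample.
#' @param seed integer seed; the simulation is fully reproducible from it.
#'
#' @return an object of class `cohort_spec` (a validated list).
#' @seealso [simulate_cohort()], [truth_table()]
#' @export
cohort_spec <- function(n_stage4 = 89, n_stage12 = 234, n_controls = 139,
                        n_snps = 200, region_snps = 61,
                        index_maf = 0.14, allelic_or = 2.63,
                        founder_span = 20, old_frac = 0.3, old_span = NULL,
                        background_maf_range = c(0.05, 0.5),
                        missing_rate = 0.005,
                        age_mean = 71.16, age_sd = 10.33, male_frac = 0.52,
                        age_beta = 0, sex_beta = 0,
                        cohort_id = "cohort1", seed = 1) {
  if (is.null(old_span)) old_span <- floor(founder_span / 3)
  spec <- list(n_stage4 = n_stage4, n_stage12 = n_stage12,
               n_controls = n_controls, n_snps = n_snps,
               region_snps = region_snps, index_maf = index_maf,
               allelic_or = allelic_or, founder_span = founder_span,
               old_frac = old_frac, old_span = old_span,
               background_maf_range = background_maf_range,
               missing_rate = missing_rate, age_mean = age_mean,
               age_sd = age_sd, male_frac = male_frac,
               age_beta = age_beta, sex_beta = sex_beta,
               cohort_id = cohort_id, seed = as.integer(seed))
  validate_cohort_spec(spec)
  structure(spec, class = "cohort_spec")
}

validate_cohort_spec <- function(s) {
  stopifnot(s$n_stage4 > 0, s$n_stage12 > 0, s$n_controls >= 0,
            s$n_snps >= 1, s$region_snps >= 1)
  if (!(s$index_maf > 0 && s$index_maf <= 0.5))
    stop("index_maf must be in (0, 0.5]")
  if (s$allelic_or <= 0) stop("allelic_or must be > 0")
  if (!(s$founder_span <= s$region_snps && s$region_snps <= s$n_snps))
    stop("need founder_span <= region_snps <= n_snps")
  if (s$founder_span > 0 && s$founder_span > s$region_snps - 1)
    stop("founder_span must leave room for the index SNP in the region")
  if (s$old_span > s$founder_span) stop("old_span must be <= founder_span")
  if (!(s$old_frac >= 0 && s$old_frac < 1)) stop("old_frac must be in [0, 1)")
  if (!(s$missing_rate >= 0 && s$missing_rate <= 0.1))
    stop("missing_rate must be in [0, 0.1]")
  r <- s$background_maf_range
  if (length(r) != 2 || r[1] <= 0 || r[2] > 0.95 || r[1] > r[2])
    stop("background_maf_range must be an increasing pair in (0, 0.95]")
  invisible(s)
}

# Deterministic variant layout shared by simulate_cohort() and truth_table():
# region block centered on the chromosome grid, index SNP at the region
# middle, founder/old span = nearest flanking region SNPs by distance.
region_layout <- function(spec) {
  n <- spec$n_snps
  rstart <- (n - spec$region_snps) %/% 2 + 1
  region <- seq(rstart, length.out = spec$region_snps)
  index <- rstart + (spec$region_snps - 1) %/% 2
  flank <- setdiff(region, index)
  ord <- flank[order(abs(flank - index), flank)]
  list(region = region, index = index,
       span = if (spec$founder_span > 0) ord[seq_len(spec$founder_span)] else integer(0),
       old_span = if (spec$old_span > 0) ord[seq_len(spec$old_span)] else integer(0),
       variant_ids = sprintf("snp%04d", seq_len(n)),
       pos = 5000L * seq_len(n))
}

# Total risk-allele frequency implied by shifting the odds of `maf` by `or`.
odds_transform <- function(maf, or) {
  odds <- maf / (1 - maf) * or
  odds / (1 + odds)
}

#' Simulate a case-case genotype cohort with a planted founder haplotype
#'
#' Draws two haplotypes per sample from a three-lineage pool (young founder
#' / old risk lineage / background) over the LD-block SNPs, with founder
#' frequencies calibrated so the per-allele odds ratio between stage IV and
#' stage I/II equals `spec$allelic_or` exactly in expectation. Background
#' SNPs are independent with frequencies drawn uniformly from
#' `background_maf_range`. Stage assignment is retrospective: group sizes
#' are fixed and allele frequencies differ by group. Ages are drawn around
#' `age_mean` and sexes at `male_frac`; by default they carry no effect.
#'
#' @param spec a [cohort_spec()].
#' @param keep_haplotypes if `TRUE`, attach the phased haplotype matrices
#'   (attribute `"haplotypes"`, a list `h1`/`h2` of 0/1 matrices) for use
#'   as ground truth in LD tests.
#' @return a [genotype_dataset()]; controls are included as samples with
#'   stage `"control"` and must never enter case-case fits.
#' @export
simulate_cohort <- function(spec, keep_haplotypes = FALSE) {
  validate_cohort_spec(spec)
  f0 <- spec$index_maf
  f4 <- odds_transform(f0, spec$allelic_or)
  if (f4 >= 1) stop("allelic_or incompatible with index_maf: stage IV frequency >= 1")
  lay <- region_layout(spec)
  n <- spec$n_stage4 + spec$n_stage12 + spec$n_controls
  stage <- c(rep("IV", spec$n_stage4),
             rep(c("I", "II"), length.out = spec$n_stage12),
             rep("control", spec$n_controls))
  set.seed(spec$seed)
  age <- round(stats::rnorm(n, spec$age_mean, spec$age_sd), 1)
  age[age < 18] <- 18
  sex <- ifelse(stats::runif(n) < spec$male_frac, "male", "female")

  # group-level total risk-allele frequency, then per-sample covariate shift
  f_tot <- ifelse(stage == "IV", f4, f0)
  if (spec$age_beta != 0 || spec$sex_beta != 0) {
    shift <- spec$age_beta * (age - spec$age_mean) / spec$age_sd +
      spec$sex_beta * (sex == "male")
    f_tot <- stats::plogis(stats::qlogis(f_tot) + shift)
  }
  # lineage split: stage IV copies are all founder-origin
  f_old <- ifelse(stage == "IV", 0, spec$old_frac * f_tot)
  f_young <- f_tot - f_old

  q <- stats::runif(spec$n_snps, spec$background_maf_range[1],
                    spec$background_maf_range[2])
  q[lay$index] <- NA_real_  # index allele assigned by lineage, not background

  draw_haps <- function() {
    u <- stats::runif(n)
    lineage <- ifelse(u < f_young, "young",
                      ifelse(u < f_young + f_old, "old", "bg"))
    h <- matrix(stats::runif(n * spec$n_snps), n, spec$n_snps)
    h <- sweep(h, 2, ifelse(is.na(q), 0, q), "<") + 0L
    h[, lay$index] <- 0L
    risk <- lineage != "bg"
    h[risk, lay$index] <- 1L
    if (length(lay$span)) h[lineage == "young", lay$span] <- 1L
    if (length(lay$old_span)) h[lineage == "old", lay$old_span] <- 1L
    storage.mode(h) <- "integer"
    h
  }
  h1 <- draw_haps()
  h2 <- draw_haps()
  dos <- h1 + h2
  if (spec$missing_rate > 0) {
    mask <- stats::runif(length(dos)) < spec$missing_rate
    dos[mask] <- NA_integer_
  }

  samples <- data.frame(
    sample_id = sprintf("%s_s%04d", spec$cohort_id, seq_len(n)),
    stage = stage, age = age, sex = sex, cohort_id = spec$cohort_id,
    stringsAsFactors = FALSE)
  variants <- data.frame(
    variant_id = lay$variant_ids, chrom = "chr1", pos = lay$pos,
    a1 = "A", a2 = "G", is_index = seq_len(spec$n_snps) == lay$index,
    stringsAsFactors = FALSE)
  ds <- genotype_dataset(dos, samples, variants)
  if (keep_haplotypes) attr(ds, "haplotypes") <- list(h1 = h1, h2 = h2)
  ds
}

#' Planted-parameter record for a simulated cohort
#'
#' Echoes the ground truth of [simulate_cohort()] for use in recovery
#' tests: the planted index SNP id, the per-allele odds ratio, the span
#' structure, and the expected per-group frequencies of the index allele
#' and of each haplotype lineage.
#'
#' @param spec a [cohort_spec()].
#' @return a list with elements `index_id`, `allelic_or`, `founder_span`,
#'   `old_span`, `region_ids`, `span_ids`, and a data.frame
#'   `group_frequencies` with the expected total / young-founder / old
#'   lineage frequencies per stage group.
#' @export
truth_table <- function(spec) {
  validate_cohort_spec(spec)
  lay <- region_layout(spec)
  f0 <- spec$index_maf
  f4 <- odds_transform(f0, spec$allelic_or)
  gf <- data.frame(
    group = c("stage_IV", "stage_I_II", "control"),
    f_total = c(f4, f0, f0),
    f_young = c(f4, (1 - spec$old_frac) * f0, (1 - spec$old_frac) * f0),
    f_old = c(0, spec$old_frac * f0, spec$old_frac * f0),
    stringsAsFactors = FALSE)
  list(index_id = lay$variant_ids[lay$index],
       allelic_or = spec$allelic_or,
       founder_span = spec$founder_span,
       old_span = spec$old_span,
       region_ids = lay$variant_ids[lay$region],
       span_ids = lay$variant_ids[lay$span],
       expected_span_difference = spec$founder_span - spec$old_span,
       group_frequencies = gf)
}
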