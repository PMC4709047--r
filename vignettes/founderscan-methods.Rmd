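---
title: "Methods: case-case GWAS for founder risk haplotypes"
author: "founderscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: case-case GWAS for founder risk haplotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The design

`founderscan` implements a two-stage *case-case* genome-wide association
analysis: all subjects are cancer cases, and the contrast is metastatic
progression (stage IV with distant-organ spread) versus organ-confined
disease (stage I/II). In a founder population, a recent risk allele is
expected to show two coupled signatures: an allele-frequency difference
between the groups, and a longer conserved haplotype around the allele
among carriers of the risk phenotype, because the allele is younger than
the population and recombination has had less time to erode its flanking
segment. The pipeline quantifies both signatures and pre-registers a
power-guided replication set in between.

Seven modules cover the path from genotypes to pooled evidence:
simulation (`simulate_cohort`), file formats (`read_vcf`,
`read_plink_text`, covariate and results tables), quality control
(`filter_variants`, `filter_samples`, `hwe_exact_p`, `mds_components`),
association (`fit_logistic_trend`, `genome_scan`), replication design
(`shrunken_or`, `replication_power`, `build_plan`,
`evaluate_replication`), pairwise LD and the haplotype span
(`em_haplotype_freqs`, `d_prime`, `span_count`,
`permutation_span_test`), and meta-analysis (`fixed_effects`,
`dersimonian_laird`, `cochran_q`, `sample_size_weighted_z`).

## The synthetic cohort generator

No subject-level genotypes ship with the package; every stage is
validated against simulated cohorts with known truth. The generator is
haplotype-pool based and deliberately coalescent-free: it reproduces the
*signatures* the pipeline must detect with directly controllable
parameters, not the population history behind them.

Each sample draws two haplotypes over a block of `region_snps` markers
(plus independent background SNPs). A haplotype belongs to one of three
lineages:

* **young founder**: carries the risk allele at the index SNP and a
  conserved allele at the `founder_span` flanking SNPs nearest the index;
* **old risk lineage**: carries the risk allele but conserves only
  `old_span` flanking SNPs (default `floor(founder_span/3)`) — the
  remnant of an older, eroded copy of the same allele;
* **background**: no risk allele; every marker drawn independently at
  its background frequency (uniform on `background_maf_range`).

The total risk-allele frequency is `index_maf` in stage I/II (default
0.14) and is shifted for stage IV through the odds transform
`f4 = (f0/(1-f0)·OR) / (1 + f0/(1-f0)·OR)`, so the per-allele odds ratio
between the groups equals `allelic_or` exactly in expectation — this
calibration is a tested invariant. Within the risk-allele copies, stage
I/II carries a fraction `old_frac` (default 0.3) on the old lineage,
while stage IV copies are all of founder origin. This asymmetry is the
design choice that creates the founder signature: the group-level
|D′| = 1 span is an extreme statistic (a single recombinant haplotype in
a group destroys complete LD at that marker), so the metastatic group
shows the full `founder_span` only if essentially all of its risk-allele
copies are conserved, while the old copies among the non-metastatic cases
cap their span near `old_span`. It is an idealisation of "the risk is
carried by the young lineage"; `old_frac` is the knob that softens it,
and `founder_span = 0` with `allelic_or = 1` yields fully exchangeable
groups for null calibration.

Stage assignment is retrospective — group sizes are fixed (defaults
89/234/139 for stage IV / stage I–II / controls, mirroring a discovery
cohort of that design) and frequencies differ by group — matching
case-case sampling rather than a prospective disease model. Ages are
drawn around 71 (s.d. 10.3), sexes ≈52% male; by default the covariates
carry no effect, and `age_beta`/`sex_beta` shift the carrier frequency
on the logit scale to exercise confounding adjustment. Positions sit on
a uniform 5 kb grid of one synthetic chromosome; only marker order
matters to any statistic. Dosages are masked missing at `missing_rate`
(default 0.005).

What the generator does **not** emulate: genotyping error and batch
effects, recombination-rate variation (no genetic map), admixture or
relatedness, X-chromosome markers, and LD among background SNPs. Tests
passing on these cohorts therefore demonstrate the statistics'
operating characteristics under a clean founder model, not robustness
to real-data artefacts.

## Quality control

Markers are filtered on minor-allele frequency (< 0.01), missingness
(> 2%), and the exact Hardy–Weinberg test; samples on call rate
(< 98%). Each removal records the first rule it failed, in that order.
The HWE p-value is the standard conditional exact test — the sum of the
probabilities of all heterozygote counts no more probable than the
observed one, given the allele counts — not the mid-p variant, so it can
be checked against independent enumeration. HWE is assessed in the stage
I/II group by default (α = 1e-6, configurable): a true risk locus
distorts genotype proportions among metastatic cases, and no external
control genotypes are assumed. Gender-mismatch, duplicate and
relatedness checks are out of scope (they need X-chromosome and IBD
machinery this artifact does not model).

Stratification axes come from classical metric MDS (`stats::cmdscale`)
of the allele-sharing (IBS) distance, `1 −` proportion of shared alleles
over pairwise non-missing loci. Axes are eigenvalue-ordered and
sign-fixed (largest-magnitude coordinate positive) for reproducibility.
One caution that matters at synthetic scale: axes computed from markers
inside the tested LD block will correlate with the founder haplotype
itself and adjust away the association. The acceptance pipeline computes
axes from background SNPs only — the single-region analogue of the
genome-wide practice of LD-pruning and excluding long-range LD regions
before PCA.

## Association

Per SNP, a log-additive (allele-dosage trend) logistic regression of
case status on 0/1/2 dosage plus covariates, fitted by IRLS
(`stats::glm.fit`, relative convergence 1e-10, 100 iterations), with
Wald two-sided p-values and 95% CIs using z = 1.96 exactly. Missing
dosages are dropped listwise per SNP; no imputation. Separation or
non-convergence is reported (`converged = FALSE`, with a note) rather
than silently estimated or replaced by a penalised fit — small case-case
studies legitimately produce large ORs with wide CIs, and the downstream
replication thresholds assume plain ML. Controls never enter fits; they
appear only in the per-group genotype summaries as a frequency
reference. `genome_scan` turns per-variant failures into flagged rows
instead of aborting.

## Replication design

Discovery winners overstate their effects (winner's curse).
`shrunken_or` deflates the discovery OR to the lower bound of a 50% CI:
with `SE = (ln CI_hi − ln CI_lo)/(2·1.96)`, the planning effect is
`exp(ln OR − qnorm(0.75)·SE)`. `replication_power` then applies the
normal approximation for the two-sided allelic (per-allele 2×2) test:
the reference-group MAF and the shrunken OR imply expected allele
frequencies, the log-OR variance is the sum of reciprocal expected cell
counts, and power is `Φ(|lnOR|/SE − z_{α/2}) + Φ(−|lnOR|/SE − z_{α/2})`.
The approximation is cross-checked against Monte-Carlo rejection rates
to ±0.02. When expected cells fall below 1 the result is flagged
unreliable rather than silently trusted. The reference-group MAF is used
as the "prevalence" input; with a rarer control-frequency convention the
power differs only in the second decimal at these designs.

`build_plan` fills tier 1 (default 9 SNPs at α = 0.04/9 ≈ 0.0044) and
tier 2 (8 SNPs at 0.01/8 = 0.00125) with the most significant SNPs whose
shrunken-OR power clears `power_floor` (default 0.80), so the family-wise
error is 0.04 + 0.01 = 0.05 regardless of how full the tiers are. Ties
in p break by larger power, then variant id — plans are deterministic.
Companion SNPs in complete LD (D′ = 1) with a tier-1 member are appended
with no alpha of their own; they are reported against their partner's
threshold. A replication verdict requires the validation p to fall
strictly below the tier alpha *and* the effect direction to match
discovery — a significant sign flip is not replication even though the
budget is stated on p alone.

## Pairwise LD and the haplotype span

Two-locus haplotype frequencies come from the standard EM over the
double-heterozygote phase ambiguity: initialise at linkage equilibrium,
iterate expected haplotype counts until the observed-data log-likelihood
changes by < 1e-12 (≤ 1000 iterations). The log-likelihood is
non-decreasing by construction and is verified against brute-force
grid maximisation over the frequency simplex. D′ is `D/D_max` with
`D_max = min(p_A p_b, p_a p_B)` for positive `D` and
`min(p_A p_B, p_a p_b)` otherwise; `|D′| = 1` means one haplotype class
is absent. Because EM only reaches the simplex boundary in the limit,
"D′ = 1" is counted as `|D′| ≥ 1 − tolerance` with tolerance 1e-6
(configurable). Counts use |D′|, the convention of LD-decay plots; the
index SNP is excluded from its own span, and SNPs monomorphic within a
group are skipped and logged.

The raw span count is descriptive only: complete LD is easier to attain
in a smaller group (fewer chromosomes, fewer chances of a recombinant),
so comparing 89 vs 234 cases directly would be biased. The calibrated
comparison is `permutation_span_test`: all case samples are repeatedly
re-partitioned into pseudo-groups of the original sizes, both counts are
recomputed each time (same region, same optional shared-SNP list), and
the group-size-specific count variances V₁, V₂ estimated from those
permutations combine into `SD = √(V₁+V₂)`, a one-sided
`z = (c_IV − c_I/II)/SD`, and its normal p — the conventional report for
this statistic. That convention is kept for comparability but it is not
calibrated: the null mean of the count *difference* is positive (the
smaller group attains |D′| = 1 more easily) and `z` measures the
difference from zero, so its p runs sharply anti-conservative at these
group sizes. Two companion p-values address this. The empirical
permutation p, `(1 + #{perm diff ≥ observed})/(n_perm + 1)`, is exactly
valid under exchangeability but conservative because an integer count
difference carries heavy ties. The recommended decision rule is the
*centered* permutation p: the one-sided normal probability of
`(diff − mean(perm diff))/sd(perm diff)`, which centres on the
permutation mean and studentises by the full permutation SD of the
difference (covariance included); the shipped calibration test checks
that its null rejection rate at α = 0.05 stays within [0.03, 0.07],
which the tied empirical p does not achieve. Defaults: `n_perm` 10,000
in the run configuration
(199–2,000 in the test suite, which trades resolution for runtime), seed
mandatory. The batched implementation computes all pseudo-group count
tables as matrix crossproducts and runs one vectorised EM, which is what
makes permutation at these scales affordable.

## Meta-analysis

Per-study log-OR standard errors are reconstructed from published 95%
CIs as `(ln hi − ln lo)/(2·1.96)`; 1.96 is used exactly (not 1.959964)
to mirror two-decimal printed intervals, a difference below reporting
precision. Fixed effects pool with inverse-variance weights; Cochran's
Q is the weighted squared deviation around the fixed pooled estimate on
χ²(k−1); DerSimonian–Laird adds the moment estimator
`τ² = max(0, (Q − df)/(Σw − Σw²/Σw))` (floored at zero) and re-pools.
Both inverse-variance pooling and the sample-size-weighted z combination
(`z_i = Φ⁻¹(1 − p_i/2)·sign_i`, weights `√n_i`) are implemented because
published pipelines often name one scheme while printing numbers
consistent with the other; `meta_analysis` reports both so any
discrepancy is visible. `metafor::rma` serves as an independent
cross-check in the tests, never as the implementation. Note that pooling
CI-rounded inputs cannot reproduce an original analysis to full
precision: reconstructed z statistics carry the rounding of two-decimal
bounds, which is why tolerance bands rather than exact matches are the
appropriate check for pooled quantities. Hartung–Knapp adjustment,
meta-regression and influence analysis are out of scope.

## Numerical choices and degenerate inputs

* EM: loglik tolerance 1e-12, cap 1000 iterations; monomorphic locus →
  error ("LD undefined"), never a silent D′.
* IRLS: epsilon 1e-10, 100 iterations; separation detected via the
  fitted-probability warning and the information matrix; `se < 100` as a
  sanity bound on a converged fit.
* D′ = 1 tolerance 1e-6; span counts are monotone in it (tested).
* HWE exact test: direct log-factorial evaluation, compared to an
  independent upward-recurrence oracle over all tables with n ≤ 50.
* Replication plans: deterministic tie-breaks (p, then power, then id).
* Zero permutation variance (degenerate region) is a hard error with a
  diagnostic, not a z of infinity.
* File formats: A1 is re-designated to the minor allele across loaded
  samples on read (flips recorded, idempotent); VCF positions 1-based
  throughout; results tables split the 95% CI into two numeric columns
  (the L95/U95 convention) so round trips are lossless.

## Problem sizes in the shipped tests

The acceptance suite runs the statistics at the sizes the package is
designed for while staying desk-scale: HWE vs enumeration for all
genotype tables with n ≤ 50; 50 EM-vs-grid fixtures; 4,000 null logistic
fits at the 89/234 design (type-I error in [0.04, 0.06]); 500 simulated
cohorts for CI coverage of a planted lnOR 2.63 (coverage in
[0.93, 0.97]); 300 founder-free cohorts for span-test calibration at
n_perm = 199 (empirical rejection in [0.03, 0.07]) and 100 founder
cohorts (span 20, OR 2.6) for power ≥ 0.8. A full acceptance rerun,
including the synthetic end-to-end pipeline, is
`Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json`.

## Known limitations

* The generator's two-lineage founder model is an idealisation; real
  haplotype erosion is continuous in genetic distance and the span
  statistic's power depends on how sharply conservation differs between
  groups.
* The span permutation scheme estimates group-size-specific count
  variances under full exchangeability; alternatives (within-region
  bootstrap, rotation of the index) would answer slightly different
  questions and are not implemented.
* Haplotype phasing beyond two loci, haplotype-block detection,
  genotype imputation, X-chromosome handling, and relatedness/IBD
  filtering are out of scope.
* With markers only from a single LD block, stratification axes and the
  tested haplotype are confounded; compute axes from background markers
  (done in the shipped pipeline) or genome-wide data.
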