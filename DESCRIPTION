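Package: founderscan
Title: Two-Stage Case-Case GWAS for Founder Risk Haplotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for case-case genome-wide association
    studies that search for founder risk alleles in isolated populations.
    Provides marker and sample quality control, covariate-adjusted
    log-additive logistic association, power-guided replication SNP
    selection with winner's-curse shrinkage and a split Bonferroni
    budget, two-locus EM haplotype frequency estimation with D-prime,
    a permutation test for extended haplotype span around an index SNP,
    and fixed/random-effects odds-ratio meta-analysis with Cochran's Q.
    Includes a synthetic genotype cohort simulator that plants a founder
    risk haplotype so every stage can be exercised against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
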