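Package: mrgrs
Title: Mendelian Randomization with Weighted Genetic Risk Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for Mendelian randomization studies of binary disease
    outcomes that instrument a binary exposure with a weighted genetic risk
    score built from published GWAS effect sizes. Provides instrument
    selection with linkage-disequilibrium pruning and proxy substitution,
    variant- and sample-level genotype quality control, effect-allele
    harmonization, weighted genetic risk score construction on dosage data,
    covariate-adjusted logistic association with stratified analyses,
    fixed-effect meta-analysis with Cochran's Q heterogeneity tests, and
    summary-statistic causal estimators (inverse-variance weighted, MR-Egger
    with its pleiotropy intercept test, and simple/weighted median). A
    case-control cohort simulator with configurable causal effect,
    confounding, and directional pleiotropy supports calibration and power
    studies without access to individual-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    metafor,
    vcfR,
    optparse
Config/testthat/edition: 3
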