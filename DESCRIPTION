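Package: pubmr
Title: Mendelian Randomization of Pubertal Development and Prostate Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Implements a Mendelian-randomization analysis linking genetically
    proxied pubertal development (a 13-SNP weighted Tanner-stage genetic risk
    score) to prostate cancer risk, grade, stage and mortality. Provides the
    SNP instrument catalog with allele harmonization and exact Hardy-Weinberg
    tests, weighted risk-score construction with tertile coding,
    covariate-adjusted logistic and cluster-robust Cox association models,
    summarized-data causal estimation with correlated variants, MR-Egger
    pleiotropy analysis, cross-variant heterogeneity, fixed- and random-effects
    meta-analysis, and a fully seeded synthetic-cohort generator with
    configurable causal effects, confounding and pleiotropy so that every
    analysis stage is testable without access to individual-level study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    metafor,
    jsonlite
Config/testthat/edition: 3
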