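Package: PhysiAge
Title: Physiological Aging Clock with Phenotypic-Age Target and Plasma
    Metabolomics Screens
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds and validates a physiological aging clock (PhysiAge): a
    linear model predicting phenotypic age from sex, fasting blood glucose,
    average daily step count and systolic blood pressure, re-anchored to the
    age axis by a median-per-age normalization factor. Includes the Levine
    phenotypic-age mapping from nine blood biomarkers, QC and sex-stratified
    train/test splitting, mortality contrasts and leave-one-parameter-out
    ablation, split-robustness checks, and rank-correlation screens of plasma
    metabolite abundances against age acceleration (deltaAge) and ordered
    health groups. A seeded synthetic-cohort generator (NHANES-like marginal
    age trends, Gompertz-linked mortality, four-group validation cohort, and
    copula-planted metabolite signal) makes the whole pipeline testable
    without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
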