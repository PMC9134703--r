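Package: PolygenicHazard
Title: Polygenic Hazard Scores and Amyloid Age-of-Onset Analysis for
    Pre-Clinical Alzheimer's Disease
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for deriving a polygenic hazard score (PHS) for
    Alzheimer's disease from GWAS summary statistics and genotype dosages
    via forward stepwise Cox proportional-hazards selection with forced
    APOE covariates; for imputing the age of onset of abnormal amyloid
    deposition from longitudinal Centiloid measurements using a
    disease-progression curve; and for the downstream association
    analyses: cross-sectional amyloid regressions with false discovery
    rate control, longitudinal linear mixed models of cognitive decline
    and regional brain atrophy, likelihood-ratio model comparison, AIC
    backward selection, simple-effect slopes at high and low PHS, and
    Cox and Kaplan-Meier comparisons of onset age between PHS strata.
    Includes a synthetic cohort generator with known ground truth that
    emulates the data structure of a longitudinal ageing and amyloid
    imaging study, so every stage can be validated by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    survival,
    lme4,
    lmerTest,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
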