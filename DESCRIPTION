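Package: DCISevo
Title: Genetic and Phenotypic Divergence Analysis for Multi-Region DCIS Cohorts
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies intratumor heterogeneity of ductal carcinoma in situ
    (DCIS) from two geographically distinct samples per patient and relates it
    to clinical outcome. Implements paired-sample SNV burden and divergence,
    bin-level copy-number alteration burden and divergence from corrected log2
    ratios, ordinal immunohistochemistry statistics (mean intensity score,
    Earth Mover's Distance between samples, Cumulative Density Index within
    samples), nonparametric and mixed-model cohort comparisons with Dunn /
    Holm-Sidak and Tukey post-hoc procedures, random-forest feature ranking
    with logistic discrimination, and endpoint-specific survival modeling:
    repeated cross-validated Cox-LASSO stability selection, standardized-hazard
    Cox fits, Youden-threshold risk stratification, Kaplan-Meier/log-rank
    comparison and reverse Kaplan-Meier follow-up. A synthetic cohort generator
    emulating the assumed data structure makes every stage testable without
    controlled-access patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    survival,
    glmnet,
    randomForest,
    lme4,
    lmerTest,
    emmeans,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    boot,
    vcfR,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
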