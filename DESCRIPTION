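Package: grsroc
Title: Genetic Risk Scores and ROC-Based Predictor Comparison for
    Case-Control Genotype Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for multi-marker genetic risk score analysis in
    case-control studies of complex disease: reading and validating
    risk-allele dosage tables, complete-case filtering, per-marker allelic
    association (crude odds ratios with Wald intervals, covariate-adjusted
    logistic regression, exact Hardy-Weinberg testing), count and
    log-odds-weighted genetic risk scores with nonparametric group
    comparison, and nonparametric ROC/AUC estimation with DeLong
    variance and paired tests for comparing correlated predictors on the
    same cohort. Includes a synthetic case-control cohort generator with a
    logistic disease model so every pipeline stage can be exercised and
    validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
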