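Package: grnfuse
Title: Gene Regulatory Network Inference by MIC Screening and
    Tree-Ensemble Importance Fusion
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Infers directed gene regulatory networks from time-series and
    steady-state expression data. Candidate regulators of each target gene
    are screened with the Maximal Information Coefficient, a non-linear
    ordinary-differential-equation model turns the expression data into a
    per-target regression problem, and the feature importances of a gradient
    boosted tree model and a random forest are fused multiplicatively into a
    ranked directed edge list. Includes DREAM4-dialect readers and writers,
    ranking evaluation (AUROC, AUPR, overall score, early precision ratio),
    a two-fold gene-wise cross-validation grid search, and a ground-truthed
    synthetic Hill-kinetics data generator for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xgboost,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
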