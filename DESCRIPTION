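Package: nnfca
Title: Coronary Heart Disease Risk Prediction with Neural-Network Feature
    Correlation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Perturbation-sensitivity analysis of tabular clinical risk
    predictors built on single-hidden-layer neural networks. Ranks features by
    the mean absolute change in a trained network's output under a small input
    perturbation, eliminates low-ranked features stepwise with retraining,
    detects correlated feature pairs from mutual sensitivity changes under
    single-feature amplification, and trains a structured network in which
    correlated features share their hidden units (coupled connections).
    Includes a synthetic health-survey cohort generator with planted effects
    and planted feature correlations, confusion-matrix and ROC evaluation with
    bootstrap confidence intervals, and logistic-regression and dense-network
    baselines.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    withr,
    igraph
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'cohort.R'
    'network.R'
    'sensitivity.R'
    'selection.R'
    'correlation.R'
    'evaluation.R'
    'simulate.R'
    'pipeline.R'
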