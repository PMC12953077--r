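Package: admira
Title: Multimodal MRI Feature-Set Ablation for Alzheimer's Staging and
    Cognitive Decline Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for evaluating the individual and
    combined predictive utility of morphometric (MO), microstructural (MS)
    and graph-theoretical (GT) MRI-derived feature sets in Alzheimer's
    disease stage classification and longitudinal cognitive decline
    prediction. Provides a synthetic cohort generator with planted group
    effects and age/sex confounds, weighted structural-connectome graph
    metrics (591-element feature vectors), leakage-safe fold-wise covariate
    adjustment (eTIV normalization, age/sex residualization,
    standardization), nested cross-validation with grid search over a
    heterogeneous learner registry, diversity-aware stacking ensembles with
    correlation-based pruning and propagated feature importance, and paired
    fold-wise Wilcoxon statistics with bootstrap confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    igraph,
    jsonlite,
    kernlab,
    MASS,
    purrr,
    ranger,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    e1071,
    xgboost
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
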