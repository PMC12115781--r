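Package: stresswear
Title: Stress Classification from Wrist-Worn Physiological Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An end-to-end pipeline for classifying physiological stress from
    wrist-worn sensor recordings (electrodermal activity, heart rate, skin
    temperature). Reads Empatica-E4-style channel exports, aligns channels on
    a common 4 Hz grid with median imputation, extracts sliding-window
    statistical and skin-conductance-response peak features plus lagged means,
    derives three stress classes from a continuous observer-annotated stress
    trace, and fits tree ensembles (random forest, gradient boosting, and a
    stacking combination) under nested stratified cross-validation with
    randomized hyperparameter search. Post-hoc tools compute
    mean-decrease-in-impurity feature importance, feature correlations,
    per-stress-level group statistics with Welch t-tests, time-in-level
    summaries, and emergency-segment validation. A synthetic cohort generator
    with the same statistical structure supports testing without access to
    study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    glmnet,
    nnet,
    ranger,
    rpart,
    xgboost,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
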