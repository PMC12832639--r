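Package: psciEEG
Title: EEG Spectral and Microstate Biomarkers for Post-Stroke Cognitive
    Impairment Risk Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for resting-state EEG biomarker modelling of
    post-stroke cognitive impairment (PSCI): synthetic 19-channel cohort
    simulation, EDF input/output, Butterworth band-pass filtering, common
    average referencing, spherical-spline channel interpolation and
    quality-control screening, Welch band-power ratios (DAR/DTR/DTABR over
    four scalp regions), polarity-invariant modified K-means microstate
    analysis with deterministic template-combination search and temporal
    statistics (MMD/MFO/MC), consensus feature selection (LASSO, random-forest
    importance, Boruta), five-classifier training with repeated
    cross-validated grid search, discrimination, calibration and
    decision-curve evaluation with bootstrap confidence intervals, and exact
    per-subject Shapley attributions for the fitted risk model.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    pracma,
    glmnet,
    ranger,
    xgboost,
    e1071,
    rpart,
    pROC,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
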