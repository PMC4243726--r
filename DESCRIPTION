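Package: chu9dmap
Title: Mapping KIDSCREEN-10 Responses to Child Health Utility 9D Utilities
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for predicting Child Health Utility 9D (CHU9D) utility
    scores from KIDSCREEN-10 responses. Ships the published mapping
    algorithms (index-quadratic and stepwise item-score equations for the
    Australian adolescent and UK adult CHU9D value sets, estimated by
    ordinary least squares, censored least absolute deviations, MM robust
    regression and fractional logit) and re-implements the full estimation
    pipeline so new mapping algorithms can be fitted on any paired dataset:
    the four estimators with heteroskedasticity-robust inference, forward
    stepwise and bootstrap-stepwise selection, variance inflation factors,
    MAE/RMSE goodness of fit with the truncate-at-one adjustment, 5-fold
    cross-validation and random-subsample validation, plus a calibrated
    synthetic-data generator for testing without respondent-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    MASS,
    sandwich,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
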