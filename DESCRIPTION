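Package: glucast
Title: Blood Glucose Forecasting for Type 1 Diabetes from CGM and Event Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Toolkit for multi-step blood glucose forecasting in type 1
    diabetes. Reads continuous glucose monitoring (CGM), meal and bolus
    insulin records in the Ohio T1DM XML dialect, regularizes and imputes
    the CGM stream onto a 5-minute grid, transforms event-based meal and
    bolus records into continuous physiological features (operative
    carbohydrates and active insulin via an exponential insulin-on-board
    model), assembles windowed sequence-to-sequence datasets with
    rolling-origin cross-validation splits, trains a stacked LSTM
    forecaster, and evaluates predictions with walk-forward, imputation-
    masked RMSE. Includes a seeded synthetic patient simulator so the full
    pipeline is testable without access to restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
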