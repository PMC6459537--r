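Package: codaf
Title: Forecasting Compositional Time Series of Population Age Structures
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Forecasts time series of compositional data (vectors of
    proportions summing to one), such as the young/middle-aged/old shares of
    a national population. Implements three constraint-removal transforms
    (linear combined component, isometric log-ratio, hyperspherical), four
    forecasting backends (ARIMA, exponential smoothing, vector
    autoregression, and a single-hidden-layer autoregressive neural
    network), Aitchison-geometry forecast accuracy metrics (CoDa-RMSE,
    CoDa-MAPE), out-of-sample model selection over the transform-by-model
    grid, portmanteau residual diagnostics, and a synthetic-data generator
    with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    nnet,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
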