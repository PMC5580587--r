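Package: tmcgm
Title: Grey GM(1,1) Forecasting with Markov Residual Correction and
    Optimized Whitening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Small-sample forecasting of positive annual time series such as
    disease-specific hospitalization rates. Fits the classical GM(1,1) grey
    model, partitions its signed residuals into equal-width error states,
    estimates a Markov chain over those states, and adds back a whitened
    interval correction whose whitening coefficients are optimized by a
    finite-difference Gauss-Newton (Taylor approximation) iteration -- the
    T-MCGM(1,1) composite model. Includes a synthetic series generator for
    exact parameter- and state-recovery testing, MAPE/RMSE evaluation,
    JSON run reports and a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
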