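Package: littermoist
Title: Dead Fuel Litter Moisture Content Modelling for Daily Fire Danger Rating
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for modelling the daily moisture content of surface leaf
    litter (LMC) from sub-daily weather records, for use in forest fire
    danger forecasting. Implements three model families: multiple linear
    regression on 14:00-anchored lagged meteorological predictors selected
    by partial-F stepwise entry/removal; conversions between the Canadian
    Fire Weather Index fine fuel moisture code (FFMC) and litter moisture
    via FF/FX scale models with a log-log moisture-code regression; and a
    semiphysical direct estimation method combining the Nelson equilibrium
    moisture content model with a discretized exponential time-lag water
    diffusion recursion, fitted by nonlinear least squares. Includes a
    seeded synthetic dry-season weather and moisture generator, Spearman
    lag-correlation profiling, MAE/MRE/RMSE error metrics, N-fold
    cross-validation, and cross-plot extrapolation matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
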