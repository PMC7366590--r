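Package: bipanel
Title: Budget-Impact Forecasting for New Medicines from Monthly Sales Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts the monthly budget impact (list price times volume) of
    newly launched drug products from national sales panels. Fits a linear
    mixed-effects model by maximum likelihood on log expenditure with a random
    intercept and time slope per product and AR(1) within-product residual
    correlation; builds the fixed-effects structure by forward stepwise AIC
    selection with time-transform interactions; validates predictions with a
    rolling-forecasting-origin scheme under continuous retraining and
    prediction capping; and reports symmetric error-ratio metrics, band
    fractions and cap scenario analyses. Includes a synthetic cohort
    generator with the model's exact statistical structure for testing and
    demonstration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    nlme,
    optparse,
    yaml
Config/testthat/edition: 3
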