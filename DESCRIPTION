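Package: hazecast
Title: Regional PM2.5 Forecasting and Pollution Event Classification for
    City Agglomerations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Multi-city hourly air-quality panels as SummarizedExperiment
    objects, with imputation, min-max normalization, sliding-window
    supervision and chronological splitting; a seeded synthetic generator
    of multi-city PM2.5 panels with diurnal and seasonal cycles, lagged
    inter-city transport along an adjacency graph, covariate coupling and
    right-skewed noise; a three-stream multi-output neural forecaster
    (recurrent temporal stream, feed-forward exogenous stream, multi-scale
    convolutional pyramid over the regional PM2.5 field) trained by Adam
    on a multi-output squared-error loss, with analytic gradients;
    evaluation (R2, MAE, RMSE), grid tuning and ten-fold cross-validation;
    and a contiguity-based classifier of mild, moderate and severe
    regional pollution days with annual and seasonal tallies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    Rcpp,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml,
    nortest
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'hazecast-package.R'
    'AllGenerics.R'
    'RcppExports.R'
    'hourly-panel.R'
    'adjacency.R'
    'normalize.R'
    'windows.R'
    'model.R'
    'backprop.R'
    'events.R'
    'impute.R'
    'panel-io.R'
    'report.R'
    'simulate.R'
    'train.R'
    'run.R'
LinkingTo:
    Rcpp,
    RcppArmadillo
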