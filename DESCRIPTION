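Package: yieldnet
Title: Hybrid LSTM-TCN Forecasting of Greenhouse Crop Yield
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: One-week-ahead forecasting of accumulated greenhouse crop
    yield (g/m2) from daily climate records (CO2, temperature, humidity
    deficit, relative humidity, radiation) and the yield history itself.
    Implements a hybrid sequence regressor: a peephole LSTM layer feeds
    a temporal convolutional network (dilated causal convolutions in
    residual blocks with weight normalisation and weight dropout),
    followed by a single-output ReLU head. Forward passes, analytic
    gradients and Adam training are implemented from the defining
    equations in base R. Includes min-max normalisation with
    leakage-free fitting, sliding-window supervision, a seasonal AR(1)
    greenhouse simulator for fully reproducible experiments, repeated
    train/test RMSE benchmarking, architecture grid search, depth
    study, factor-exclusion ablation and a classical-vs-deep
    comparison harness with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    e1071,
    nnet,
    optparse,
    ranger,
    rpart,
    testthat (>= 3.0.0),
    withr,
    xgboost
Config/testthat/edition: 3
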