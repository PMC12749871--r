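Package: evocgm
Title: Neuro-Evolution of Feed-Forward Networks for Short-Horizon CGM
    Glucose Forecasting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for one-step-ahead (5-minute) blood glucose forecasting
    from continuous glucose monitoring (CGM) time series. Implements a
    from-scratch feed-forward neural network whose weights and biases are
    optimised by a genetic algorithm (roulette-wheel selection, averaging
    crossover, bounded uniform mutation and family elitism), with
    validation-based early stopping, a sliding-window supervised dataset
    builder, a window-size sweep with validation-based model selection, and
    a back-propagation trained baseline for comparison. Includes CGM CSV
    input/output with gap interpolation and interval-jitter handling, a
    synthetic CGM trace generator for fully reproducible experiments, and
    reporting of MSE/RMSE comparison metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
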