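#' Window-size sweep with validation-based model selection
#'
#' Runs the chosen training method once (or `replicates` times, keeping the
#' best) at every window size in `cfg$window_range`. For each window the
#' series is re-windowed and re-split chronologically, the model is trained
#' on the training block and its validation MSE recorded. The window with
#' the smallest validation MSE is selected, and only that one model is then
#' evaluated once on the test block — the test data never influences
#' selection.
#'
#' A back-propagation run that diverges (non-finite loss) is recorded as
#' validation MSE `Inf` for its window rather than aborting the sweep, so
#' the report always contains one row per window size; erratic
#' gradient-descent behaviour at some windows is itself a result.
#'
#' @param series A [cgm_series()].
#' @param cfg An [evolution_config()]; also supplies the seed and topology
#'   for the baseline.
#' @param split A [split_spec()].
#' @param method `"evolve"` (genetic algorithm) or `"backprop"` (gradient
#'   baseline).
#' @param backprop Options for the baseline: list with `lr`, `max_epochs`
#'   (defaults 0.01, 500); `patience` follows `cfg$patience`.
#' @param replicates Independent runs per window (derived seeds); the best
#'   validation MSE is kept. Default 1.
#' @param datasets Optional pre-built list of per-window splits (as built
#'   internally); used by [run_experiment()] to guarantee both methods see
#'   byte-identical data.
#' @return An object of class `sweep_report`: `rows` (data frame
#'   `window_size`, `validation_mse`), `selected_window`, `model`,
#'   `test_mse`, `method`, `split`, `datasets`.
#' @export
sweep_window_sizes <- function(series, cfg, split = split_spec(),
                               method = c("evolve", "backprop"),
                               backprop = list(lr = 0.01, max_epochs = 500L),
                               replicates = 1L, datasets = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(cfg, "evolution_config"))
  windows <- cfg$window_range
  if (is.null(datasets)) {
    datasets <- build_window_splits(series, windows, split)
  }
  lr <- if (is.null(backprop$lr)) 0.01 else backprop$lr
  max_epochs <- if (is.null(backprop$max_epochs)) 500L else backprop$max_epochs

  val_mse <- rep(NA_real_, length(windows))
  models <- vector("list", length(windows))
  run_seeds <- rep(NA_integer_, length(windows))
  for (k in seq_along(windows)) {
    w <- windows[k]
    sp <- datasets[[as.character(w)]]
    best_v <- Inf
    best_m <- NULL
    best_seed <- NA_integer_
    for (r in seq_len(replicates)) {
      run_seed <- derive_seed(cfg$seed, w, r, if (method == "backprop") 1L else 0L)
      v <- Inf
      m <- NULL
      if (method == "evolve") {
        run_cfg <- cfg
        run_cfg$seed <- run_seed
        res <- evolve(sp$train, sp$val, run_cfg)
        v <- res$best_val_mse
        m <- res$best
      } else {
        topo <- nn_topology(w, hidden = cfg$hidden_layers,
                            hidden_activation = cfg$hidden_activation,
                            output_activation = cfg$output_activation,
                            bias_placement = cfg$bias_placement)
        g0 <- init_genotype(topo, cfg$init_scale, seed = run_seed)
        res <- tryCatch(
          backprop_train(g0, sp$train, sp$val, lr = lr,
                         max_epochs = max_epochs, patience = cfg$patience),
          evocgm_divergence = function(e) NULL
        )
        if (!is.null(res)) {
          v <- min(res$history$val_mse)
          m <- res$genotype
        }
      }
      if (v < best_v) {
        best_v <- v
        best_m <- m
        best_seed <- run_seed
      }
    }
    val_mse[k] <- best_v
    models[[k]] <- best_m
    run_seeds[k] <- best_seed
  }
  sel <- which.min(val_mse)  # Inf never wins while any run succeeded
  if (!is.finite(val_mse[sel])) {
    abort_evocgm("evocgm_divergence", "every window's run diverged; no model to select")
  }
  sel_split <- datasets[[as.character(windows[sel])]]
  test_mse <- mse(sel_split$test$targets,
                  forward_pass(models[[sel]], sel_split$test$inputs))
  structure(
    list(rows = data.frame(window_size = windows, validation_mse = val_mse),
         selected_window = windows[sel],
         model = models[[sel]],
         test_mse = test_mse,
         method = method, split = split, datasets = datasets,
         selected_seed = run_seeds[sel]),
    class = "sweep_report"
  )
}

# One windowed+split dataset per window size, keyed by window size.
build_window_splits <- function(series, windows, split) {
  out <- lapply(windows, function(w) {
    split_chronological(make_windows(series, w, window_range = range(windows)), split)
  })
  names(out) <- as.character(windows)
  out
}

#' @export
print.sweep_report <- function(x, ...) {
  cat(sprintf("<sweep_report> method: %s\n", x$method))
  df <- x$rows
  df$validation_mse <- sprintf("%.4f", df$validation_mse)
  print(df, row.names = FALSE)
  cat(sprintf("selected window %d | test MSE %.4f\n", x$selected_window, x$test_mse))
  invisible(x)
}

#' Write a sweep report's per-window table to CSV
#' @param report A [sweep_window_sizes()] report.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(report, path) {
  utils::write.csv(report$rows, path, row.names = FALSE)
  invisible(path)
}
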