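#' Mean squared forecast error
#'
#' The objective minimised throughout:
#' `MSE = sum_i (y_i - yhat_i)^2 / n`, in (mmol/L)^2.
#'
#' @param actual,predicted Equal-length numeric vectors, mmol/L.
#' @return The MSE, (mmol/L)^2.
#' @export
mse <- function(actual, predicted) {
  if (length(actual) != length(predicted)) {
    abort_evocgm("evocgm_shape_error",
                 sprintf("length mismatch: %d actual vs %d predicted",
                         length(actual), length(predicted)))
  }
  if (length(actual) == 0L) {
    abort_evocgm("evocgm_empty_input", "cannot compute MSE of empty vectors")
  }
  sum((actual - predicted)^2) / length(actual)
}

#' Convert an MSE to an RMSE
#'
#' RMSE is the square root of the MSE and is in the original glucose units
#' (mmol/L), which makes errors directly interpretable against readings.
#'
#' @param mse A non-negative MSE, (mmol/L)^2.
#' @return RMSE, mmol/L.
#' @export
rmse_from_mse <- function(mse) {
  if (!is.numeric(mse) || any(mse < 0)) {
    abort_evocgm("evocgm_invalid_param", "MSE must be non-negative")
  }
  sqrt(mse)
}

#' Relative improvement of a new error over a reference, in percent
#'
#' `100 * (reference - new) / reference`: positive when the new method has
#' the smaller error.
#'
#' @param new Error of the new method.
#' @param reference Error of the reference method; must be `> 0`.
#' @return Percentage improvement.
#' @export
relative_improvement <- function(new, reference) {
  if (!is.numeric(reference) || any(reference <= 0)) {
    abort_evocgm("evocgm_invalid_param", "`reference` must be positive")
  }
  100 * (reference - new) / reference
}

#' Head-to-head comparison of two window sweeps
#'
#' Extracts each method's selected window and best validation MSE from its
#' sweep report and derives the comparison arithmetic: absolute MSE drop,
#' relative MSE improvement, both RMSEs with their absolute and relative
#' drops, and the window-size reduction. The headline fields are computed
#' from best MSEs rounded to 3 decimal places — the precision at which such
#' results are quoted — with fully unrounded counterparts alongside in
#' `$unrounded`.
#'
#' @param evolved Sweep report of the evolved (genetic-algorithm) method.
#' @param baseline Sweep report of the back-propagation baseline.
#' @return A list of class `comparison_summary`.
#' @export
summarize_comparison <- function(evolved, baseline) {
  stopifnot(inherits(evolved, "sweep_report"), inherits(baseline, "sweep_report"))
  if (!identical(evolved$rows$window_size, baseline$rows$window_size)) {
    abort_evocgm("evocgm_invalid_param",
                 "the two sweeps cover different window ranges")
  }
  if (!identical(unclass(evolved$split), unclass(baseline$split))) {
    abort_evocgm("evocgm_invalid_param",
                 "the two sweeps used different split specifications")
  }
  e_mse_raw <- min(evolved$rows$validation_mse)
  b_mse_raw <- min(baseline$rows$validation_mse)
  comp <- function(e_mse, b_mse, digits_rmse = Inf) {
    e_rmse <- rmse_from_mse(e_mse)
    b_rmse <- rmse_from_mse(b_mse)
    if (is.finite(digits_rmse)) {
      e_rmse <- round(e_rmse, digits_rmse)
      b_rmse <- round(b_rmse, digits_rmse)
    }
    list(
      evolved_mse = e_mse, baseline_mse = b_mse,
      mse_drop = b_mse - e_mse,
      mse_improvement_pct = relative_improvement(e_mse, b_mse),
      evolved_rmse = e_rmse, baseline_rmse = b_rmse,
      rmse_drop = b_rmse - e_rmse,
      rmse_improvement_pct = relative_improvement(e_rmse, b_rmse)
    )
  }
  rounded <- comp(round(e_mse_raw, 3), round(b_mse_raw, 3), digits_rmse = 4)
  unrounded <- comp(e_mse_raw, b_mse_raw)
  structure(
    c(list(
        evolved_window = evolved$selected_window,
        baseline_window = baseline$selected_window,
        evolved_test_mse = evolved$test_mse,
        baseline_test_mse = baseline$test_mse,
        window_reduction_pct =
          100 * (baseline$selected_window - evolved$selected_window) /
          baseline$selected_window),
      rounded,
      list(unrounded = unrounded)),
    class = "comparison_summary"
  )
}

#' @export
print.comparison_summary <- function(x, ...) {
  cat("<comparison_summary> evolved network vs back-propagation baseline\n")
  cat(sprintf("  best validation MSE: %.3f (window %d) vs %.3f (window %d)\n",
              x$evolved_mse, x$evolved_window, x$baseline_mse, x$baseline_window))
  cat(sprintf("  test MSE: %.3f vs %.3f\n", x$evolved_test_mse, x$baseline_test_mse))
  cat(sprintf("  MSE drop %.3f (%.1f%% lower) | RMSE %.4f vs %.4f, drop %.4f (%.1f%% lower)\n",
              x$mse_drop, x$mse_improvement_pct,
              x$evolved_rmse, x$baseline_rmse, x$rmse_drop, x$rmse_improvement_pct))
  cat(sprintf("  window size reduction: %.0f%%\n", x$window_reduction_pct))
  invisible(x)
}
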