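#' Chronological train/validation/test proportions
#'
#' @param train,val,test Positive fractions summing to 1 (tolerance 1e-9).
#' @return A list of class `split_spec`.
#' @export
split_spec <- function(train = 0.70, val = 0.15, test = 0.15) {
  fr <- c(train = train, val = val, test = test)
  if (!is.numeric(fr) || any(fr <= 0)) {
    abort_evocgm("evocgm_invalid_param", "split fractions must all be positive")
  }
  if (abs(sum(fr) - 1) > 1e-9) {
    abort_evocgm("evocgm_invalid_param",
                 sprintf("split fractions must sum to 1 (got %.10f)", sum(fr)))
  }
  structure(as.list(fr), class = "split_spec")
}

#' Build the sliding-window supervised dataset
#'
#' For window size `w`, every run of `w + 1` consecutive readings inside one
#' contiguous segment yields a training pair: the first `w` readings (oldest
#' first) are the inputs and the `(w+1)`-th is the one-step-ahead target.
#' Pairs never span an unfilled gap or distinct traces, and are ordered
#' chronologically.
#'
#' @param series A [cgm_series()].
#' @param w Window size: how many past readings feed the forecast. Allowed
#'   range `window_range` (default 3 to 10).
#' @param window_range Length-2 integer vector of allowed window sizes.
#' @param jitter_tol Passed to [segment_contiguous()].
#' @return An object of class `window_dataset` with elements `inputs`
#'   (`n x w` matrix, mmol/L), `targets` (length-`n` vector),
#'   `window_size`, and `target_index` (position of each target in the
#'   source series, for provenance and chronological splitting).
#' @examples
#' s <- cgm_series(as.POSIXct("2023-01-01", tz = "UTC") + 300 * (0:3),
#'                 c(4.6, 4.3, 4.0, 3.8))
#' ds <- make_windows(s, 3)
#' ds$inputs   # 4.6 4.3 4.0
#' ds$targets  # 3.8
#' @export
make_windows <- function(series, w, window_range = c(3L, 10L), jitter_tol = 2) {
  stopifnot(inherits(series, "cgm_series"))
  if (!is.numeric(w) || length(w) != 1L || w != as.integer(w) ||
      w < window_range[1] || w > window_range[2]) {
    abort_evocgm("evocgm_window_size",
                 sprintf("window size %s outside allowed range [%d, %d]",
                         format(w), window_range[1], window_range[2]))
  }
  w <- as.integer(w)
  segs <- segment_contiguous(series, jitter_tol = jitter_tol)
  rows <- list()
  tidx <- list()
  seg_of <- list()
  for (k in seq_len(nrow(segs))) {
    a <- segs$start[k]; b <- segs$end[k] - 1L
    len <- b - a + 1L
    if (len <= w) next
    starts <- a:(b - w)
    idx <- outer(starts, 0:(w - 1L), `+`)
    rows[[length(rows) + 1L]] <- matrix(series$values[idx], nrow = length(starts))
    tidx[[length(tidx) + 1L]] <- starts + w
    seg_of[[length(seg_of) + 1L]] <- rep(k, length(starts))
  }
  if (!length(rows)) {
    abort_evocgm("evocgm_empty_dataset",
                 sprintf("no contiguous segment is longer than the window (w = %d)", w))
  }
  inputs <- do.call(rbind, rows)
  target_index <- unlist(tidx)
  ord <- order(target_index)
  structure(
    list(inputs = inputs[ord, , drop = FALSE],
         targets = series$values[target_index][ord],
         window_size = w,
         target_index = target_index[ord],
         segment = unlist(seg_of)[ord]),
    class = "window_dataset"
  )
}

#' @export
print.window_dataset <- function(x, ...) {
  cat(sprintf("<window_dataset> %d pairs | window size %d | %d segment(s)\n",
              n_pairs(x), x$window_size, length(unique(x$segment))))
  invisible(x)
}

#' Number of input/target pairs in a window dataset
#' @param ds A [make_windows()] dataset.
#' @return Integer count.
#' @export
n_pairs <- function(ds) length(ds$targets)

subset_windows <- function(ds, idx) {
  structure(
    list(inputs = ds$inputs[idx, , drop = FALSE],
         targets = ds$targets[idx],
         window_size = ds$window_size,
         target_index = ds$target_index[idx],
         segment = ds$segment[idx]),
    class = "window_dataset"
  )
}

#' Split a window dataset into chronological blocks
#'
#' The pairs are split, in chronological order, into contiguous
#' train / validation / test blocks. Validation and test receive
#' `floor(n * fraction)` pairs each and the remainder goes to training.
#' Chronological (rather than shuffled) blocks avoid look-ahead leakage:
#' the model is validated and tested strictly on data later than anything it
#' trained on.
#'
#' @param ds A [make_windows()] dataset.
#' @param spec A [split_spec()].
#' @return A list with elements `train`, `val`, `test`, each a
#'   `window_dataset`.
#' @export
split_chronological <- function(ds, spec = split_spec()) {
  stopifnot(inherits(ds, "window_dataset"), inherits(spec, "split_spec"))
  n <- n_pairs(ds)
  if (n == 0L) abort_evocgm("evocgm_empty_dataset", "cannot split an empty dataset")
  n_val <- floor(n * spec$val)
  n_test <- floor(n * spec$test)
  n_train <- n - n_val - n_test
  if (n_train < 1L || n_val < 1L || n_test < 1L) {
    abort_evocgm("evocgm_empty_split",
                 sprintf("split of %d pairs leaves an empty block (%d/%d/%d)",
                         n, n_train, n_val, n_test))
  }
  list(
    train = subset_windows(ds, seq_len(n_train)),
    val = subset_windows(ds, n_train + seq_len(n_val)),
    test = subset_windows(ds, n_train + n_val + seq_len(n_test))
  )
}

#' Standardize window splits using training statistics only
#'
#' Optional preprocessing: centres and scales inputs and targets by the mean
#' and standard deviation of the *training* inputs, so no information leaks
#' from validation or test data. Off by default throughout the package —
#' forecast errors in raw mmol/L are directly interpretable.
#'
#' @param splits Result of [split_chronological()].
#' @return The splits with standardized values; attributes `center` and
#'   `scale` hold the training statistics.
#' @export
standardize_splits <- function(splits) {
  mu <- mean(splits$train$inputs)
  sdv <- stats::sd(as.numeric(splits$train$inputs))
  if (sdv == 0) sdv <- 1
  rescale <- function(ds) {
    ds$inputs <- (ds$inputs - mu) / sdv
    ds$targets <- (ds$targets - mu) / sdv
    ds
  }
  out <- lapply(splits, rescale)
  attr(out, "center") <- mu
  attr(out, "scale") <- sdv
  out
}

#' Write a window dataset to CSV for inspection
#'
#' @param ds A [make_windows()] dataset.
#' @param path Output path. Columns `x1..xw` then `target`.
#' @return `path`, invisibly.
#' @export
write_windows_csv <- function(ds, path) {
  df <- as.data.frame(ds$inputs)
  names(df) <- paste0("x", seq_len(ncol(df)))
  df$target <- ds$targets
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
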