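#' CGM time series
#'
#' A `cgm_series` holds timestamped interstitial glucose readings in mmol/L
#' from a continuous glucose monitor. Timestamps must be strictly increasing;
#' readings are nominally 5 minutes (300 s) apart but real devices jitter the
#' interval by about a second and drop readings, leaving gaps.
#'
#' @param timestamps `POSIXct` vector (or ISO-8601 parseable character).
#' @param values Numeric glucose readings, mmol/L.
#' @param nominal_interval Nominal sampling interval in seconds (default 300).
#' @param bounds Length-2 numeric plausibility bounds in mmol/L. Readings
#'   outside the bounds are rejected. Default `c(2.0, 22.2)`, a typical CGM
#'   device reporting range.
#' @param filled Optional logical vector flagging readings that were inserted
#'   by [interpolate_gaps()] rather than measured.
#'
#' @return An object of class `cgm_series`.
#' @examples
#' t0 <- as.POSIXct("2023-01-01 00:00:00", tz = "UTC")
#' s <- cgm_series(t0 + c(0, 300, 600), c(4.6, 4.3, 4.0))
#' length(s)
#' @export
cgm_series <- function(timestamps, values, nominal_interval = 300,
                       bounds = c(2.0, 22.2), filled = NULL) {
  if (is.character(timestamps)) {
    timestamps <- parse_timestamps(timestamps, dialect = "iso8601")
  }
  if (!inherits(timestamps, "POSIXct")) {
    abort_evocgm("evocgm_parse_error", "`timestamps` must be POSIXct or ISO-8601 character")
  }
  values <- as.numeric(values)
  if (length(timestamps) != length(values)) {
    abort_evocgm("evocgm_invalid_param",
                 "`timestamps` and `values` must have the same length")
  }
  if (length(values) == 0L) {
    abort_evocgm("evocgm_empty_input", "a cgm_series must contain at least one reading")
  }
  if (anyNA(timestamps) || anyNA(values)) {
    abort_evocgm("evocgm_parse_error", "timestamps and values must not contain NA")
  }
  if (length(timestamps) > 1L && any(diff(as.numeric(timestamps)) <= 0)) {
    abort_evocgm("evocgm_monotonicity_error", "timestamps must be strictly increasing")
  }
  assert_scalar_number(nominal_interval, "nominal_interval", lower = 0, strict_lower = TRUE)
  if (length(bounds) != 2L || !is.numeric(bounds) || bounds[1] >= bounds[2]) {
    abort_evocgm("evocgm_invalid_param", "`bounds` must be c(low, high) with low < high")
  }
  bad <- which(values < bounds[1] | values > bounds[2])
  if (length(bad)) {
    abort_evocgm(
      "evocgm_bounds_error",
      sprintf("reading %d (%.1f mmol/L) is outside plausibility bounds [%.1f, %.1f]",
              bad[1], values[bad[1]], bounds[1], bounds[2])
    )
  }
  if (is.null(filled)) filled <- rep(FALSE, length(values))
  structure(
    list(timestamps = timestamps, values = values,
         nominal_interval = nominal_interval, bounds = bounds,
         filled = filled),
    class = "cgm_series"
  )
}

#' @export
length.cgm_series <- function(x) length(x$values)

#' @export
print.cgm_series <- function(x, ...) {
  n <- length(x)
  span_d <- as.numeric(difftime(x$timestamps[n], x$timestamps[1], units = "days"))
  cat(sprintf("<cgm_series> %d readings spanning %.1f days\n", n, span_d))
  cat(sprintf("  interval: %g s nominal | glucose: %.1f-%.1f mmol/L | %d interpolated\n",
              x$nominal_interval, min(x$values), max(x$values), sum(x$filled)))
  invisible(x)
}

#' @export
as.data.frame.cgm_series <- function(x, ...) {
  data.frame(timestamp = x$timestamps, value = x$values, filled = x$filled)
}

parse_timestamps <- function(x, dialect = c("iso8601", "dmy")) {
  dialect <- match.arg(dialect)
  fmts <- switch(dialect,
    iso8601 = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"),
    dmy = "%d/%m/%Y %H:%M:%S"
  )
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")
  remaining <- seq_along(x)
  for (fmt in fmts) {
    if (!length(remaining)) break
    parsed <- as.POSIXct(x[remaining], format = fmt, tz = "UTC")
    ok <- !is.na(parsed)
    out[remaining[ok]] <- parsed[ok]
    remaining <- remaining[!ok]
  }
  if (length(remaining)) {
    abort_evocgm("evocgm_parse_error",
                 sprintf("unparseable timestamp at row %d: \"%s\"",
                         remaining[1], x[remaining[1]]))
  }
  out
}

#' Read a CGM trace from CSV
#'
#' Reads the 3-column CGM export dialect: column 1 a sequential index,
#' column 2 a timestamp at (nominally) 5-minute intervals, column 3 the
#' glucose reading in mmol/L to 1 decimal place. A header row is detected
#' automatically. The index column is only checked for monotonicity and then
#' dropped.
#'
#' @param path Path to the CSV file.
#' @param bounds Plausibility bounds in mmol/L (see [cgm_series()]).
#' @param nominal_interval Nominal sampling interval, seconds.
#' @param timestamp_dialect `"iso8601"` (default) or `"dmy"`
#'   (`DD/MM/YYYY HH:MM:SS`, as written by some device export tools).
#'
#' @return A [cgm_series()].
#' @seealso [write_cgm_csv()]
#' @export
read_cgm_csv <- function(path, bounds = c(2.0, 22.2), nominal_interval = 300,
                         timestamp_dialect = c("iso8601", "dmy")) {
  timestamp_dialect <- match.arg(timestamp_dialect)
  if (!file.exists(path)) {
    abort_evocgm("evocgm_io_error", sprintf("file not found: %s", path))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    abort_evocgm("evocgm_empty_input", sprintf("empty CGM file: %s", path))
  }
  # a header starts with a non-numeric index label ("index,..."); a data row
  # with a bad glucose field must instead surface as a parse error below
  first <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  has_header <- is.na(suppressWarnings(as.numeric(first[1])))
  if (has_header) lines <- lines[-1]
  if (!length(lines)) {
    abort_evocgm("evocgm_empty_input", sprintf("CGM file has a header but no data: %s", path))
  }
  fields <- strsplit(lines, ",", fixed = TRUE)
  nfield <- lengths(fields)
  if (any(nfield < 3)) {
    abort_evocgm("evocgm_parse_error",
                 sprintf("row %d does not have 3 columns", which(nfield < 3)[1]))
  }
  idx <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 1L)))
  val <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  if (anyNA(val)) {
    abort_evocgm("evocgm_parse_error",
                 sprintf("unparseable glucose value at row %d", which(is.na(val))[1]))
  }
  if (!anyNA(idx) && length(idx) > 1L && any(diff(idx) <= 0)) {
    abort_evocgm("evocgm_monotonicity_error", "index column is not strictly increasing")
  }
  ts <- parse_timestamps(vapply(fields, `[[`, "", 2L), dialect = timestamp_dialect)
  if (length(ts) > 1L && any(diff(as.numeric(ts)) <= 0)) {
    abort_evocgm("evocgm_monotonicity_error", "timestamps are not strictly increasing")
  }
  cgm_series(ts, val, nominal_interval = nominal_interval, bounds = bounds)
}

#' Write a CGM trace to CSV
#'
#' Writes the same 3-column dialect read by [read_cgm_csv()]: a 0-based
#' sequential index, an ISO-8601 timestamp and the glucose value with exactly
#' one decimal place.
#'
#' @param series A [cgm_series()].
#' @param path Output file path.
#' @param header Write a header row? Default `TRUE`.
#' @return `path`, invisibly.
#' @export
write_cgm_csv <- function(series, path, header = TRUE) {
  stopifnot(inherits(series, "cgm_series"))
  ts <- format(series$timestamps, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  rows <- sprintf("%d,%s,%.1f", seq_along(series$values) - 1L, ts, series$values)
  if (header) rows <- c("index,timestamp,glucose_mmol_l", rows)
  writeLines(rows, path)
  invisible(path)
}

#' Fill short gaps by time-linear interpolation
#'
#' Missing readings (inter-reading spans of more than one nominal interval)
#' are filled at nominal-interval grid points by linear interpolation in
#' time, provided the whole gap spans at most `max_gap` seconds. Longer gaps
#' are left open — interpolating across hours would fabricate structure — and
#' are later respected by [segment_contiguous()] so that no training window
#' straddles them. Filled values are rounded to 1 decimal place, matching the
#' precision of measured readings.
#'
#' @param series A [cgm_series()].
#' @param max_gap Maximum gap span to fill, in seconds (default 3600 = 60 min).
#' @return A [cgm_series()] with gaps of span `<= max_gap` filled; the
#'   `filled` field marks inserted readings.
#' @export
interpolate_gaps <- function(series, max_gap = 3600) {
  stopifnot(inherits(series, "cgm_series"))
  assert_scalar_number(max_gap, "max_gap", lower = series$nominal_interval)
  n <- length(series)
  if (n < 2L) return(series)
  t_num <- as.numeric(series$timestamps)
  dt <- diff(t_num)
  nom <- series$nominal_interval
  n_miss <- pmax(round(dt / nom) - 1L, 0L)
  fill <- which(n_miss >= 1L & dt <= max_gap)
  if (!length(fill)) return(series)

  new_t <- vector("list", length(fill))
  new_v <- vector("list", length(fill))
  for (k in seq_along(fill)) {
    i <- fill[k]
    tt <- t_num[i] + seq_len(n_miss[i]) * nom
    vv <- series$values[i] +
      (series$values[i + 1] - series$values[i]) * (tt - t_num[i]) / dt[i]
    new_t[[k]] <- tt
    new_v[[k]] <- round1(vv)
  }
  all_t <- c(t_num, unlist(new_t))
  all_v <- c(series$values, unlist(new_v))
  all_f <- c(series$filled, rep(TRUE, length(unlist(new_t))))
  ord <- order(all_t)
  cgm_series(as.POSIXct(all_t[ord], origin = "1970-01-01", tz = "UTC"),
             all_v[ord],
             nominal_interval = nom, bounds = series$bounds,
             filled = all_f[ord])
}

#' Split a series into contiguous segments
#'
#' Partitions a series at every inter-reading step that deviates from the
#' nominal interval by more than `jitter_tol` seconds (i.e. at unfilled
#' gaps). Within a segment the sampling is regular up to device interval
#' jitter, so sliding windows drawn inside one segment never span a hole in
#' the record.
#'
#' @param series A [cgm_series()].
#' @param jitter_tol Allowed deviation from the nominal interval, seconds.
#'   Default 2 s: devices record 4 min 59 s / 5 min 1 s intervals, so 2 s
#'   gives margin over the documented +/- 1 s artifact.
#' @return A data frame of class `cgm_segments` with columns `start` and
#'   `end` (1-based, half-open: the segment covers readings
#'   `start, ..., end - 1`).
#' @export
segment_contiguous <- function(series, jitter_tol = 2) {
  stopifnot(inherits(series, "cgm_series"))
  assert_scalar_number(jitter_tol, "jitter_tol", lower = 0)
  n <- length(series)
  if (n == 1L) {
    segs <- data.frame(start = 1L, end = 2L)
  } else {
    dt <- diff(as.numeric(series$timestamps))
    brk <- which(abs(dt - series$nominal_interval) > jitter_tol)
    start <- c(1L, brk + 1L)
    end <- c(brk, n) + 1L
    segs <- data.frame(start = start, end = end)
  }
  class(segs) <- c("cgm_segments", "data.frame")
  attr(segs, "jitter_tol") <- jitter_tol
  segs
}
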