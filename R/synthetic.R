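#' Parameters for the synthetic CGM generator
#'
#' Bundles the knobs of [generate_cgm()]. Defaults emulate the statistical
#' texture of a roughly two-week, 5-minute-interval CGM wear: a baseline near
#' 6 mmol/L, a mild circadian swing, three daily meal excursions (linear rise,
#' exponential decay) and strongly autocorrelated sensor/physiology noise
#' whose innovation scale (0.15 mmol/L) puts typical one-step changes around
#' 0.2-0.3 mmol/L — the regime in which short-horizon CGM forecast errors of
#' ~0.3 mmol/L RMSE are meaningful.
#'
#' @param duration_days Length of the trace in days (default 13.8, a typical
#'   sensor wear).
#' @param interval Sampling interval in seconds (default 300).
#' @param baseline Baseline glucose, mmol/L.
#' @param circadian_amplitude Amplitude of the 24 h sinusoidal component,
#'   mmol/L.
#' @param meal_times Clock times of daily meals, fractional hours.
#' @param meal_amplitude Peak meal excursion, mmol/L.
#' @param meal_rise_min,meal_decay_min Meal response shape: linear rise time
#'   and exponential decay time constant, minutes.
#' @param ar_coefficient Lag-1 coefficient of the AR(1) noise, in `[0, 1)`.
#' @param noise_sd Innovation standard deviation of the AR(1) noise, mmol/L.
#' @param missing_rate Expected fraction of readings deleted by
#'   [inject_artifacts()], in `[0, 1)`.
#' @param jitter_fraction Fraction of inter-reading intervals recorded as
#'   299 s or 301 s rather than 300 s (default 0.41, as observed on real
#'   devices).
#' @param bounds Plausibility bounds to clip to, mmol/L.
#' @param seed Integer seed; the generator is deterministic given the seed.
#'
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(duration_days = 13.8, interval = 300, baseline = 6,
                       circadian_amplitude = 0.8,
                       meal_times = c(8, 13, 19), meal_amplitude = 3,
                       meal_rise_min = 30, meal_decay_min = 90,
                       ar_coefficient = 0.85, noise_sd = 0.15,
                       missing_rate = 0.02, jitter_fraction = 0.41,
                       bounds = c(2.0, 22.2), seed = 1L) {
  assert_scalar_number(duration_days, "duration_days", lower = 0, strict_lower = TRUE)
  assert_scalar_number(interval, "interval", lower = 0, strict_lower = TRUE)
  assert_scalar_number(baseline, "baseline")
  assert_scalar_number(circadian_amplitude, "circadian_amplitude", lower = 0)
  assert_scalar_number(meal_amplitude, "meal_amplitude", lower = 0)
  assert_scalar_number(meal_rise_min, "meal_rise_min", lower = 0, strict_lower = TRUE)
  assert_scalar_number(meal_decay_min, "meal_decay_min", lower = 0, strict_lower = TRUE)
  assert_scalar_number(ar_coefficient, "ar_coefficient", lower = 0, upper = 1 - 1e-9)
  assert_scalar_number(noise_sd, "noise_sd", lower = 0)
  assert_scalar_number(missing_rate, "missing_rate", lower = 0, upper = 1 - 1e-9)
  assert_scalar_number(jitter_fraction, "jitter_fraction", lower = 0, upper = 1)
  if (any(meal_times < 0 | meal_times >= 24)) {
    abort_evocgm("evocgm_invalid_param", "`meal_times` must be clock hours in [0, 24)")
  }
  structure(
    list(duration_days = duration_days, interval = interval,
         baseline = baseline, circadian_amplitude = circadian_amplitude,
         meal_times = meal_times, meal_amplitude = meal_amplitude,
         meal_rise_min = meal_rise_min, meal_decay_min = meal_decay_min,
         ar_coefficient = ar_coefficient, noise_sd = noise_sd,
         missing_rate = missing_rate, jitter_fraction = jitter_fraction,
         bounds = bounds, seed = as.integer(seed)),
    class = "sim_params"
  )
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf("<sim_params> %.1f days @ %gs | baseline %.1f mmol/L, %d meals/day\n",
              x$duration_days, x$interval, x$baseline, length(x$meal_times)))
  cat(sprintf("  AR(1) phi=%.2f sd=%.2f | missing %.0f%% | jitter %.0f%% | seed %d\n",
              x$ar_coefficient, x$noise_sd, 100 * x$missing_rate,
              100 * x$jitter_fraction, x$seed))
  invisible(x)
}

# Deterministic (noise-free) component of the simulated trace, mmol/L,
# evaluated at elapsed seconds t_sec from the trace start (midnight).
sim_deterministic <- function(params, t_sec) {
  hours <- t_sec / 3600
  circ <- params$circadian_amplitude * sin(2 * pi * (hours - 10) / 24)
  meals <- numeric(length(t_sec))
  n_days <- ceiling(params$duration_days) + 1L
  rise <- params$meal_rise_min * 60
  decay <- params$meal_decay_min * 60
  for (d in 0:(n_days - 1L)) {
    for (m in params$meal_times) {
      dt <- t_sec - (d * 24 + m) * 3600
      up <- dt >= 0 & dt < rise
      down <- dt >= rise
      meals[up] <- meals[up] + params$meal_amplitude * dt[up] / rise
      meals[down] <- meals[down] + params$meal_amplitude * exp(-(dt[down] - rise) / decay)
    }
  }
  params$baseline + circ + meals
}

#' Generate a clean synthetic CGM trace
#'
#' Simulates a gap-free, regularly sampled trace as
#' baseline + circadian sinusoid + additive meal responses + AR(1) noise,
#' clipped to the plausibility bounds and rounded to 1 decimal place (the
#' precision at which devices report). Use [inject_artifacts()] afterwards to
#' add the missing-run and interval-jitter artifacts of real exports.
#'
#' @param params A [sim_params()] object.
#' @param start Trace start time (default 2023-01-01 00:00 UTC).
#' @return A [cgm_series()]; the attribute `"deterministic"` carries the
#'   noise-free component for diagnostic use.
#' @examples
#' s <- generate_cgm(sim_params(duration_days = 1, seed = 7))
#' length(s)  # 288 readings: 24 h x 12 per hour
#' @export
generate_cgm <- function(params,
                         start = as.POSIXct("2023-01-01 00:00:00", tz = "UTC")) {
  stopifnot(inherits(params, "sim_params"))
  n <- floor(params$duration_days * 86400 / params$interval)
  if (n < 1L) abort_evocgm("evocgm_invalid_param", "duration too short for one reading")
  t_sec <- (seq_len(n) - 1L) * params$interval
  det <- sim_deterministic(params, t_sec)
  noise <- with_seed(params$seed, {
    innov <- stats::rnorm(n, 0, params$noise_sd)
    x0 <- stats::rnorm(1, 0, params$noise_sd / sqrt(1 - params$ar_coefficient^2))
    as.numeric(stats::filter(innov, params$ar_coefficient,
                             method = "recursive", init = x0))
  })
  vals <- round1(pmin(pmax(det + noise, params$bounds[1]), params$bounds[2]))
  out <- cgm_series(start + t_sec, vals,
                    nominal_interval = params$interval, bounds = params$bounds)
  attr(out, "deterministic") <- det
  out
}

#' Inject real-device artifacts into a clean trace
#'
#' Reproduces the two recording artifacts seen in CGM exports:
#' * missing data: readings are deleted in clustered runs (run length
#'   geometric with mean 3, since dropouts cluster), with `missing_rate` the
#'   expected deleted fraction;
#' * interval jitter: a fraction `jitter_fraction` of the surviving
#'   inter-reading intervals is recorded one second long or short (301 s /
#'   299 s instead of 300 s), the offsets accumulating into the timestamps
#'   just as on the device clock.
#'
#' Values of surviving readings are untouched and monotonicity is preserved.
#'
#' @param series A [cgm_series()].
#' @param missing_rate Expected deleted fraction, in `[0, 1)`.
#' @param jitter_fraction Fraction of intervals to jitter, in `[0, 1]`.
#' @param seed Optional integer seed; deterministic when given.
#' @return A [cgm_series()].
#' @export
inject_artifacts <- function(series, missing_rate = 0.02,
                             jitter_fraction = 0.41, seed = NULL) {
  stopifnot(inherits(series, "cgm_series"))
  if (!is.numeric(missing_rate) || missing_rate >= 1 || missing_rate < 0) {
    abort_evocgm("evocgm_invalid_param", "`missing_rate` must be in [0, 1)")
  }
  assert_scalar_number(jitter_fraction, "jitter_fraction", lower = 0, upper = 1)
  with_seed(seed, {
    n <- length(series)
    keep <- rep(TRUE, n)
    if (missing_rate > 0) {
      # Run starts at rate missing_rate / mean run length; geometric lengths.
      starts <- which(stats::runif(n) < missing_rate / 3)
      for (s in starts) {
        len <- stats::rgeom(1, 1 / 3) + 1L
        keep[s:min(s + len - 1L, n)] <- FALSE
      }
      if (sum(keep) < 2L) keep[] <- TRUE  # degenerate draw; keep the series usable
    }
    ts <- as.numeric(series$timestamps)[keep]
    vals <- series$values[keep]
    fil <- series$filled[keep]
    if (jitter_fraction > 0 && length(ts) > 1L) {
      m <- length(ts) - 1L
      hit <- stats::runif(m) < jitter_fraction
      delta <- ifelse(hit, sample(c(-1, 1), m, replace = TRUE), 0)
      ts <- ts[1] + cumsum(c(0, diff(ts) + delta))
    }
    cgm_series(as.POSIXct(ts, origin = "1970-01-01", tz = "UTC"), vals,
               nominal_interval = series$nominal_interval,
               bounds = series$bounds, filled = fil)
  })
}
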