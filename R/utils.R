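#' @keywords internal
"_PACKAGE"

# Classed conditions so callers can distinguish failure modes programmatically.
abort_evocgm <- function(class, message, ...) {
  cond <- structure(
    class = c(class, "evocgm_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_evocgm("evocgm_invalid_param",
                 sprintf("`%s` must be a single finite number", name))
  }
  low_ok <- if (strict_lower) x > lower else x >= lower
  if (!low_ok || x > upper) {
    abort_evocgm("evocgm_invalid_param",
                 sprintf("`%s` = %g is outside its valid range", name, x))
  }
  invisible(x)
}

# Deterministic per-stage/per-task seed derivation from one global seed.
# Keeps results reproducible while letting stages (simulation, per-window
# runs, replicates) use independent streams. Always < 2^31.
derive_seed <- function(seed, ...) {
  offsets <- c(...)
  s <- as.double(seed) %% 2147483647
  for (o in offsets) {
    s <- (s * 48271 + as.double(o) + 1) %% 2147483647
  }
  as.integer(s)
}

# Run `expr` under a fixed seed without disturbing the caller's RNG stream;
# with seed = NULL the current stream is used (and advanced).
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

round1 <- function(x) round(x, 1L)
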