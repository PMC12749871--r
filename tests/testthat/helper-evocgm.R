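# Shared fixtures and independent oracles, all built in code at test time.

t0_utc <- as.POSIXct("2023-01-01 00:00:00", tz = "UTC")

# regular 5-min series from explicit values
make_series <- function(values, interval = 300, bounds = c(2.0, 22.2)) {
  cgm_series(t0_utc + interval * (seq_along(values) - 1L), values,
             nominal_interval = interval, bounds = bounds)
}

# series realising the one-step dynamics y_{t+1} = 0.5 y_t + 0.5 y_{t-1} + e,
# e ~ N(0, sd^2); wide bounds because the process is a random walk
make_ar_series <- function(n, sd = 0.15, seed = 1) {
  set.seed(seed)
  y <- numeric(n)
  y[1:2] <- 6
  e <- rnorm(n, 0, sd)
  for (t in 3:n) y[t] <- 0.5 * y[t - 1] + 0.5 * y[t - 2] + e[t]
  make_series(y, bounds = c(-1000, 1000))
}

# Independent forward-pass oracle: explicit per-neuron loops, no matrix
# algebra, deliberately naive so it cannot share a bug with forward_pass().
oracle_forward <- function(g, inputs) {
  topo <- g$topology
  n_layers <- length(g$weights)
  out <- numeric(nrow(inputs))
  for (r in seq_len(nrow(inputs))) {
    a <- as.numeric(inputs[r, ])
    for (l in seq_len(n_layers)) {
      act_name <- if (l == n_layers) topo$output_activation else topo$hidden_activation
      n_out <- ncol(g$weights[[l]])
      nxt <- numeric(n_out)
      for (j in seq_len(n_out)) {
        z <- 0
        for (i in seq_along(a)) z <- z + a[i] * g$weights[[l]][i, j]
        if (topo$bias_placement == "pre_activation") z <- z + g$biases[[l]][1, j]
        h <- if (act_name == "relu") max(z, 0) else z
        if (topo$bias_placement == "post_activation") h <- h + g$biases[[l]][1, j]
        nxt[j] <- h
      }
      a <- nxt
    }
    out[r] <- a[1]
  }
  out
}

# flatten all parameters of a genotype into one vector (for comparisons)
flatten_params <- function(g) {
  c(unlist(lapply(g$weights, as.numeric)), unlist(lapply(g$biases, as.numeric)))
}

# central finite-difference gradient of the train MSE wrt every parameter
fd_gradient <- function(g, inputs, targets, h = 1e-6) {
  loss <- function(gg) mse(targets, forward_pass(gg, inputs))
  grads <- list(weights = list(), biases = list())
  for (l in seq_along(g$weights)) {
    for (slot in c("weights", "biases")) {
      m <- g[[slot]][[l]]
      gm <- m
      for (k in seq_along(m)) {
        gp <- g; gm2 <- g
        gp[[slot]][[l]][k] <- m[k] + h
        gm2[[slot]][[l]][k] <- m[k] - h
        gm[k] <- (loss(gp) - loss(gm2)) / (2 * h)
      }
      grads[[slot]][[l]] <- gm
    }
  }
  grads
}

tiny_cfg <- function(...) {
  evolution_config(population_size = 10L, generations = 10L, seed = 99L, ...)
}
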