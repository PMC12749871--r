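#' Feed-forward network topology
#'
#' Describes the network shape used for one-step CGM forecasting: `w` input
#' nodes (one per reading in the window), hidden layers (default three of 5
#' nodes each) and a single output node predicting the next reading.
#'
#' Bias placement is configurable because both conventions appear in
#' practice: `"post_activation"` (the default here) adds the bias row vector
#' *after* applying the activation, i.e. `a = act(x W) + b`; the conventional
#' `"pre_activation"` computes `a = act(x W + b)`. The back-propagation
#' trainer honours whichever is set.
#'
#' @param window_size Number of input nodes (the window size `w`).
#' @param hidden Integer vector of hidden layer widths, default `c(5, 5, 5)`.
#' @param hidden_activation `"relu"` (default) or `"identity"`.
#' @param output_activation `"identity"` (default) or `"relu"`. Identity is
#'   the default because a ReLU output node can saturate at 0 and stall
#'   gradient training, while glucose targets are strictly positive anyway;
#'   set `"relu"` for rectification at the output too.
#' @param bias_placement `"post_activation"` (default) or `"pre_activation"`.
#' @return A list of class `nn_topology` with element `layer_sizes`
#'   (`c(w, hidden, 1)`).
#' @export
nn_topology <- function(window_size, hidden = c(5, 5, 5),
                        hidden_activation = c("relu", "identity"),
                        output_activation = c("identity", "relu"),
                        bias_placement = c("post_activation", "pre_activation")) {
  hidden_activation <- match.arg(hidden_activation)
  output_activation <- match.arg(output_activation)
  bias_placement <- match.arg(bias_placement)
  layer_sizes <- as.integer(c(window_size, hidden, 1L))
  if (any(layer_sizes < 1L)) {
    abort_evocgm("evocgm_invalid_param", "all layer sizes must be >= 1")
  }
  structure(
    list(layer_sizes = layer_sizes,
         hidden_activation = hidden_activation,
         output_activation = output_activation,
         bias_placement = bias_placement),
    class = "nn_topology"
  )
}

activation_fun <- function(name) {
  switch(name,
    relu = list(f = function(z) pmax(z, 0), grad = function(z) (z > 0) * 1),
    identity = list(f = function(z) z, grad = function(z) array(1, dim(z))),
    abort_evocgm("evocgm_invalid_param", sprintf("unknown activation \"%s\"", name))
  )
}

#' Initialise a genotype (the GA chromosome)
#'
#' A genotype is the full parameter set of one network: per layer a weight
#' matrix `W` of shape `n_in x n_out` and a `1 x n_out` bias row vector.
#' These matrices are the genes the genetic algorithm crosses over and
#' mutates; decoded through [forward_pass()] they form the phenotype, a
#' functioning forecaster. All entries are drawn independently from
#' `U(-scale, +scale)`.
#'
#' @param topology A [nn_topology()].
#' @param scale Half-width of the uniform initialisation (default 0.5).
#' @param seed Optional integer seed; deterministic when given.
#' @return A list of class `nn_genotype` with elements `weights`, `biases`
#'   and `topology`.
#' @export
init_genotype <- function(topology, scale = 0.5, seed = NULL) {
  stopifnot(inherits(topology, "nn_topology"))
  assert_scalar_number(scale, "scale", lower = 0, strict_lower = TRUE)
  sizes <- topology$layer_sizes
  with_seed(seed, {
    weights <- list()
    biases <- list()
    for (l in seq_len(length(sizes) - 1L)) {
      weights[[l]] <- matrix(stats::runif(sizes[l] * sizes[l + 1], -scale, scale),
                             nrow = sizes[l], ncol = sizes[l + 1])
      biases[[l]] <- matrix(stats::runif(sizes[l + 1], -scale, scale), nrow = 1)
    }
    structure(list(weights = weights, biases = biases, topology = topology),
              class = "nn_genotype")
  })
}

#' @export
print.nn_genotype <- function(x, ...) {
  cat(sprintf("<nn_genotype> layers [%s] | %d parameters | %s, bias %s\n",
              paste(x$topology$layer_sizes, collapse = ","),
              n_params(x), x$topology$hidden_activation,
              x$topology$bias_placement))
  invisible(x)
}

#' Total number of parameters in a genotype
#' @param g An [init_genotype()] object.
#' @return Integer.
#' @export
n_params <- function(g) {
  sum(vapply(g$weights, length, 1L)) + sum(vapply(g$biases, length, 1L))
}

same_topology <- function(a, b) {
  identical(a$topology$layer_sizes, b$topology$layer_sizes) &&
    identical(a$topology$hidden_activation, b$topology$hidden_activation) &&
    identical(a$topology$output_activation, b$topology$output_activation) &&
    identical(a$topology$bias_placement, b$topology$bias_placement)
}

# Forward pass keeping per-layer intermediates (needed for gradients).
forward_full <- function(g, inputs) {
  topo <- g$topology
  n_layers <- length(g$weights)
  a <- vector("list", n_layers + 1L)
  z <- vector("list", n_layers)
  a[[1]] <- inputs
  for (l in seq_len(n_layers)) {
    act <- activation_fun(
      if (l == n_layers) topo$output_activation else topo$hidden_activation
    )
    zl <- a[[l]] %*% g$weights[[l]]
    b_rep <- matrix(g$biases[[l]], nrow = nrow(zl), ncol = ncol(zl), byrow = TRUE)
    if (topo$bias_placement == "post_activation") {
      a[[l + 1]] <- act$f(zl) + b_rep
    } else {
      zl <- zl + b_rep
      a[[l + 1]] <- act$f(zl)
    }
    z[[l]] <- zl
  }
  list(a = a, z = z)
}

#' Run the network forward
#'
#' Propagates a matrix of input windows through the network: at each layer
#' the activations are multiplied by the weight matrix, the activation
#' function applied, and the bias row added (after or before the activation
#' according to the topology's `bias_placement`). Pure function of the
#' genotype and inputs.
#'
#' @param g An [init_genotype()] genotype.
#' @param inputs Numeric matrix `n x w` (or a length-`w` vector for a single
#'   window), oldest reading first.
#' @return Numeric vector of `n` one-step-ahead predictions, mmol/L.
#' @export
forward_pass <- function(g, inputs) {
  stopifnot(inherits(g, "nn_genotype"))
  if (is.vector(inputs)) inputs <- matrix(inputs, nrow = 1)
  if (ncol(inputs) != g$topology$layer_sizes[1]) {
    abort_evocgm("evocgm_shape_error",
                 sprintf("input width %d does not match topology input size %d",
                         ncol(inputs), g$topology$layer_sizes[1]))
  }
  out <- forward_full(g, inputs)
  as.numeric(out$a[[length(out$a)]])
}

#' @export
predict.nn_genotype <- function(object, newdata, ...) {
  if (inherits(newdata, "window_dataset")) newdata <- newdata$inputs
  forward_pass(object, newdata)
}

# MSE gradient wrt every weight and bias, honouring bias placement.
# Returns list(weights = ..., biases = ...) with shapes matching g.
mse_gradient <- function(g, inputs, targets) {
  topo <- g$topology
  n_layers <- length(g$weights)
  ff <- forward_full(g, inputs)
  n <- nrow(inputs)
  yhat <- ff$a[[n_layers + 1L]]
  g_a <- 2 * (yhat - matrix(targets, ncol = 1)) / n
  dW <- vector("list", n_layers)
  db <- vector("list", n_layers)
  for (l in rev(seq_len(n_layers))) {
    act <- activation_fun(
      if (l == n_layers) topo$output_activation else topo$hidden_activation
    )
    if (topo$bias_placement == "post_activation") {
      # a_l = act(z_l) + b_l, z_l = a_{l-1} W_l
      db[[l]] <- matrix(colSums(g_a), nrow = 1)
      g_z <- g_a * act$grad(ff$z[[l]])
    } else {
      # a_l = act(z_l), z_l = a_{l-1} W_l + b_l
      g_z <- g_a * act$grad(ff$z[[l]])
      db[[l]] <- matrix(colSums(g_z), nrow = 1)
    }
    dW[[l]] <- t(ff$a[[l]]) %*% g_z
    g_a <- g_z %*% t(g$weights[[l]])
  }
  list(weights = dW, biases = db)
}

#' Train a network by full-batch back-propagation
#'
#' The gradient-descent baseline against which the evolved network is
#' compared. Minimises the mean squared one-step forecast error by
#' full-batch gradient descent, with the same early-stopping rule as the
#' genetic algorithm: training halts when the validation MSE has risen for
#' `patience` consecutive epochs, and the parameters from the best-validation
#' epoch are returned.
#'
#' @param g Starting genotype (see [init_genotype()]).
#' @param train,val `window_dataset`s for training and early
#'   stopping/selection.
#' @param lr Learning rate (default 0.01).
#' @param max_epochs Maximum epochs (default 500).
#' @param patience Consecutive validation-MSE increases tolerated before
#'   stopping (default 3).
#' @return A list with `genotype` (best-validation parameters) and `history`,
#'   a data frame with columns `epoch`, `train_mse`, `val_mse` and attributes
#'   `stop_reason` (`"early_stop"` or `"max_epochs"`) and `epochs_run`.
#'   Raises a `evocgm_divergence` error (naming the epoch) if the loss
#'   becomes non-finite, as can happen at this learning rate on unfavourable
#'   initialisations.
#' @export
backprop_train <- function(g, train, val, lr = 0.01, max_epochs = 500L,
                           patience = 3L) {
  stopifnot(inherits(g, "nn_genotype"),
            inherits(train, "window_dataset"), inherits(val, "window_dataset"))
  if (n_pairs(train) == 0L || n_pairs(val) == 0L) {
    abort_evocgm("evocgm_empty_dataset", "train and validation sets must be non-empty")
  }
  if (ncol(train$inputs) != g$topology$layer_sizes[1]) {
    abort_evocgm("evocgm_shape_error", "dataset width does not match network input size")
  }
  assert_scalar_number(lr, "lr", lower = 0)
  hist_train <- numeric(0)
  hist_val <- numeric(0)
  best <- g
  best_val <- Inf
  stop_reason <- "max_epochs"
  epoch <- 0L
  for (epoch in seq_len(max_epochs)) {
    if (lr > 0) {
      gr <- mse_gradient(g, train$inputs, train$targets)
      for (l in seq_along(g$weights)) {
        g$weights[[l]] <- g$weights[[l]] - lr * gr$weights[[l]]
        g$biases[[l]] <- g$biases[[l]] - lr * gr$biases[[l]]
      }
    }
    tr_mse <- mse(train$targets, forward_pass(g, train$inputs))
    va_mse <- mse(val$targets, forward_pass(g, val$inputs))
    if (!is.finite(tr_mse) || !is.finite(va_mse)) {
      abort_evocgm("evocgm_divergence",
                   sprintf("training diverged (non-finite loss) at epoch %d", epoch),
                   epoch = epoch)
    }
    hist_train <- c(hist_train, tr_mse)
    hist_val <- c(hist_val, va_mse)
    if (va_mse < best_val) {
      best_val <- va_mse
      best <- g
    }
    if (isTRUE(early_stop_generation(hist_val, patience) == epoch)) {
      stop_reason <- "early_stop"
      break
    }
  }
  history <- data.frame(epoch = seq_along(hist_train),
                        train_mse = hist_train, val_mse = hist_val)
  attr(history, "stop_reason") <- stop_reason
  attr(history, "epochs_run") <- length(hist_train)
  list(genotype = best, history = history)
}

#' Save / load a genotype as JSON
#'
#' Serialises the topology and all weight and bias matrices to a plain JSON
#' document, so evolved or trained forecasters can be stored and reloaded
#' without binary formats.
#'
#' @param g An [init_genotype()] genotype.
#' @param path File path.
#' @return `write_genotype_json()` returns `path` invisibly;
#'   `read_genotype_json()` returns the reconstructed `nn_genotype`.
#' @export
write_genotype_json <- function(g, path) {
  stopifnot(inherits(g, "nn_genotype"))
  doc <- list(
    layer_sizes = g$topology$layer_sizes,
    hidden_activation = g$topology$hidden_activation,
    output_activation = g$topology$output_activation,
    bias_placement = g$topology$bias_placement,
    weights = g$weights,
    biases = g$biases
  )
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_genotype_json
#' @export
read_genotype_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  sizes <- as.integer(doc$layer_sizes)
  topo <- nn_topology(sizes[1], hidden = sizes[-c(1, length(sizes))],
                      hidden_activation = doc$hidden_activation,
                      output_activation = doc$output_activation,
                      bias_placement = doc$bias_placement)
  to_mat <- function(m, nr, nc) {
    if (is.matrix(m)) {
      matrix(as.numeric(m), nrow = nr, ncol = nc)
    } else {
      # simplification collapsed a 1 x nc or nr x 1 matrix to a vector
      matrix(as.numeric(unlist(m)), nrow = nr, ncol = nc, byrow = TRUE)
    }
  }
  weights <- list()
  biases <- list()
  for (l in seq_len(length(sizes) - 1L)) {
    weights[[l]] <- to_mat(doc$weights[[l]], sizes[l], sizes[l + 1])
    biases[[l]] <- to_mat(doc$biases[[l]], 1L, sizes[l + 1])
  }
  structure(list(weights = weights, biases = biases, topology = topo),
            class = "nn_genotype")
}
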