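test_that("genotype initialisation has the contracted shapes, bounds and determinism", {
  topo <- nn_topology(3)
  g <- init_genotype(topo, scale = 0.5, seed = 1)
  expect_equal(lapply(g$weights, dim),
               list(c(3L, 5L), c(5L, 5L), c(5L, 5L), c(5L, 1L)))
  expect_equal(lapply(g$biases, dim),
               list(c(1L, 5L), c(1L, 5L), c(1L, 5L), c(1L, 1L)))
  expect_equal(n_params(g), 86L)  # 15+25+25+5 weights + 16 biases
  expect_true(all(abs(flatten_params(g)) <= 0.5))

  g2 <- init_genotype(topo, scale = 0.5, seed = 1)
  expect_identical(flatten_params(g2), flatten_params(g))
  expect_error(init_genotype(topo, scale = 0), class = "evocgm_invalid_param")
})

test_that("forward pass follows the layer recurrence for simple hand cases", {
  topo <- nn_topology(3)
  g <- init_genotype(topo, seed = 2)
  # all-zero parameters with identity output annihilate any input
  g0 <- g
  for (l in seq_along(g0$weights)) {
    g0$weights[[l]][] <- 0
    g0$biases[[l]][] <- 0
  }
  expect_equal(forward_pass(g0, matrix(c(5, 6, 7), 1)), 0)

  # 1-1-1 net, hidden W=2 b=1 (post-activation), output W=1 b=0: relu(3*2)+1 = 7
  t1 <- nn_topology(1, hidden = 1)
  g1 <- init_genotype(t1, seed = 1)
  g1$weights[[1]][] <- 2; g1$biases[[1]][] <- 1
  g1$weights[[2]][] <- 1; g1$biases[[2]][] <- 0
  expect_equal(forward_pass(g1, matrix(3)), 7)
  # same parameters, pre-activation bias: output relu(3*2+1)*1 + 0 = 7 at the
  # hidden layer too, so distinguish with a negative pre-activation
  g1$weights[[1]][] <- -2
  expect_equal(forward_pass(g1, matrix(3)), 1)  # relu(-6)+1
  t1p <- nn_topology(1, hidden = 1, bias_placement = "pre_activation")
  g1p <- init_genotype(t1p, seed = 1)
  g1p$weights[[1]][] <- -2; g1p$biases[[1]][] <- 1
  g1p$weights[[2]][] <- 1; g1p$biases[[2]][] <- 0
  expect_equal(forward_pass(g1p, matrix(3)), 0)  # relu(-6+1)

  expect_error(forward_pass(g, matrix(1, 1, 4)), class = "evocgm_shape_error")
})

test_that("forward pass matches the per-neuron oracle across random shapes and settings", {
  set.seed(42)
  for (rep in 1:30) {
    w <- sample(3:10, 1)
    hidden <- sample(1:6, sample(1:3, 1), replace = TRUE)
    bias <- sample(c("post_activation", "pre_activation"), 1)
    out_act <- sample(c("identity", "relu"), 1)
    topo <- nn_topology(w, hidden = hidden, output_activation = out_act,
                        bias_placement = bias)
    g <- init_genotype(topo, scale = 1)
    x <- matrix(runif(4 * w, -2, 10), nrow = 4)
    expect_equal(forward_pass(g, x), oracle_forward(g, x), tolerance = 1e-12)
  }
})

test_that("hidden ReLU activations are non-negative before the bias is added", {
  topo <- nn_topology(4)
  g <- init_genotype(topo, seed = 6)
  x <- matrix(runif(20, 2, 12), nrow = 5)
  a <- x
  for (l in seq_len(length(g$weights) - 1L)) {
    pre_bias <- pmax(a %*% g$weights[[l]], 0)
    expect_true(all(pre_bias >= 0))
    a <- pre_bias + matrix(g$biases[[l]], nrow(pre_bias), ncol(pre_bias), byrow = TRUE)
  }
})

test_that("analytic gradients match central finite differences for both bias placements", {
  set.seed(10)
  for (bias in c("post_activation", "pre_activation")) {
    topo <- nn_topology(3, hidden = 5, bias_placement = bias)
    g <- init_genotype(topo, scale = 0.5)
    x <- matrix(runif(15, 3, 9), nrow = 5)
    y <- runif(5, 3, 9)
    analytic <- evocgm:::mse_gradient(g, x, y)
    numeric <- fd_gradient(g, x, y)
    for (l in seq_along(g$weights)) {
      for (slot in c("weights", "biases")) {
        a <- as.numeric(analytic[[slot]][[l]])
        n <- as.numeric(numeric[[slot]][[l]])
        denom <- pmax(abs(a), abs(n), 1e-3)
        expect_lt(max(abs(a - n) / denom), 1e-5)
      }
    }
  }
})

test_that("backprop training obeys its contracts", {
  s <- make_series(round(4 + 2 * abs(sin((1:103) / 9)), 1))
  sp <- split_chronological(make_windows(s, 3))
  topo <- nn_topology(3)
  g0 <- init_genotype(topo, seed = 4)

  # lr = 0: parameters unchanged
  frozen <- backprop_train(g0, sp$train, sp$val, lr = 0, max_epochs = 3)
  expect_identical(flatten_params(frozen$genotype), flatten_params(g0))

  # one small step strictly decreases training MSE when the gradient is nonzero
  one <- backprop_train(g0, sp$train, sp$val, lr = 1e-4, max_epochs = 1,
                        patience = 10)
  mse0 <- mse(sp$train$targets, forward_pass(g0, sp$train$inputs))
  expect_lt(one$history$train_mse[1], mse0)

  # single training pair converges to near-zero error
  pair <- list(inputs = matrix(c(4.6, 4.3, 4.0), 1), targets = 3.8,
               window_size = 3L, target_index = 4L, segment = 1L)
  class(pair) <- "window_dataset"
  fit <- backprop_train(init_genotype(topo, seed = 8), pair, pair,
                        lr = 0.01, max_epochs = 5000, patience = 5000)
  expect_lt(min(fit$history$train_mse), 1e-4)

  # divergence is surfaced as a named error carrying the epoch (huge step
  # size; patience large enough that early stopping cannot intervene first)
  err <- tryCatch(
    backprop_train(init_genotype(topo, seed = 1), sp$train, sp$val,
                   lr = 1e6, max_epochs = 200, patience = 1000),
    evocgm_divergence = function(e) e
  )
  expect_s3_class(err, "evocgm_divergence")
  expect_true(is.numeric(err$epoch) && err$epoch >= 1)
  expect_match(conditionMessage(err), "epoch")
})

test_that("genotype JSON serialization round-trips parameters and topology", {
  topo <- nn_topology(5, hidden = c(4, 3), output_activation = "relu",
                      bias_placement = "pre_activation")
  g <- init_genotype(topo, seed = 12)
  path <- withr::local_tempfile(fileext = ".json")
  write_genotype_json(g, path)
  g2 <- read_genotype_json(path)
  expect_identical(g2$topology, g$topology)
  expect_equal(g2$weights, g$weights)
  expect_equal(g2$biases, g$biases)
  x <- matrix(runif(10, 3, 8), 2)
  expect_equal(forward_pass(g2, x), forward_pass(g, x))
})
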