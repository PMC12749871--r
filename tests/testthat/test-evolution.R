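test_that("fitness scaling inverts error monotonically with an epsilon guard", {
  f <- scale_fitness(c(0.1, 0.3))
  expect_gt(f[1], f[2])
  expect_equal(scale_fitness(c(0.2, 0.2))[1], scale_fitness(c(0.2, 0.2))[2])
  expect_equal(scale_fitness(0), 1e8)
  expect_error(scale_fitness(c(0.1, Inf)), class = "evocgm_invalid_param")
  expect_error(scale_fitness(c(0.1, -0.1)), class = "evocgm_invalid_param")
})

test_that("roulette selection draws in proportion to fitness", {
  expect_true(all(roulette_select(c(1, 0, 0), 50, seed = 1) == 1L))
  expect_error(roulette_select(c(1, -1), 5), class = "evocgm_invalid_param")

  draws <- roulette_select(c(1, 1), 10000, seed = 2)
  expect_gte(mean(draws == 1L), 0.485)
  expect_lte(mean(draws == 1L), 0.515)

  # all-zero fitness falls back to uniform over all indices
  z <- roulette_select(c(0, 0), 2000, seed = 3)
  expect_setequal(unique(z), c(1L, 2L))

  # chi-square goodness of fit against the fitness proportions at 1e5 draws
  fit <- c(5, 1, 3, 0.5, 2)
  big <- roulette_select(fit, 1e5, seed = 4)
  counts <- tabulate(big, nbins = 5)
  expect_gt(stats::chisq.test(counts, p = fit / sum(fit))$p.value, 0.01)
})

test_that("averaging crossover is an element-wise linear combination", {
  topo <- nn_topology(3)
  p1 <- init_genotype(topo, seed = 1)
  p2 <- init_genotype(topo, seed = 2)

  expect_identical(flatten_params(crossover(p1, p2, 1)), flatten_params(p1))
  expect_identical(flatten_params(crossover(p1, p2, 0)), flatten_params(p2))

  mid <- crossover(p1, p2, 0.5)
  expect_equal(flatten_params(mid),
               0.5 * flatten_params(p1) + 0.5 * flatten_params(p2))
  # concrete midpoint: weights 2 and 4 -> 3
  q1 <- p1; q1$weights[[1]][1, 1] <- 2
  q2 <- p2; q2$weights[[1]][1, 1] <- 4
  expect_equal(crossover(q1, q2, 0.5)$weights[[1]][1, 1], 3)

  self <- crossover(p1, p1, 0.3)
  expect_equal(flatten_params(self), flatten_params(p1))

  other <- init_genotype(nn_topology(4), seed = 1)
  expect_error(crossover(p1, other, 0.5), class = "evocgm_shape_error")
})

test_that("mutation is bounded, seed-deterministic and non-destructive", {
  topo <- nn_topology(3)
  g <- init_genotype(topo, seed = 5)
  before <- flatten_params(g)

  m <- mutate_genotype(g, max_mutation = 0.1, seed = 11)
  delta <- flatten_params(m) - before
  expect_true(all(abs(delta) <= 0.1))
  expect_true(any(delta != 0))
  expect_identical(flatten_params(g), before)  # original untouched

  expect_identical(flatten_params(mutate_genotype(g, 0.1, seed = 11)),
                   flatten_params(m))
  expect_identical(flatten_params(mutate_genotype(g, 0)), before)
})

test_that("family reproduction pools parents with four children and keeps the fittest", {
  s <- make_series(round(5 + sin((1:60) / 5), 1))
  sp <- split_chronological(make_windows(s, 3))
  cfg <- tiny_cfg()
  topo <- nn_topology(3)
  p1 <- init_genotype(topo, seed = 1)
  p2 <- init_genotype(topo, seed = 2)

  # with identical parents and no mutation, all six pool members coincide
  nomut <- tiny_cfg(max_mutation = 0)
  fam <- reproduce_family(p1, p1, sp$train, nomut)
  expect_identical(flatten_params(fam$genotype), flatten_params(p1))

  # survivor never beats the pool: equals the explicit argmin over the six
  set.seed(30)
  for (rep in 1:10) {
    a <- init_genotype(topo)
    b <- init_genotype(topo)
    set.seed(1000 + rep)
    fam <- reproduce_family(a, b, sp$train, cfg)
    set.seed(1000 + rep)  # replay the same mutation draws
    kids <- lapply(cfg$crossover_coefficients, function(al) crossover(a, b, al))
    kids[[3]] <- mutate_genotype(kids[[3]], cfg$max_mutation)
    kids[[4]] <- mutate_genotype(kids[[4]], cfg$max_mutation)
    pool_mse <- vapply(c(list(a, b), kids),
                       function(g) mse(sp$train$targets, forward_pass(g, sp$train$inputs)), 0)
    expect_equal(fam$train_mse, min(pool_mse))
    # family elitism: survivor no worse than either parent
    expect_lte(fam$train_mse, min(pool_mse[1:2]))
  }
})

test_that("early stopping fires exactly after `patience` consecutive increases", {
  expect_equal(early_stop_generation(c(5, 4, 3, 3.1, 3.2, 3.3, 2, 1), patience = 3), 6L)
  expect_true(is.na(early_stop_generation(c(5, 4, 3, 2, 1), patience = 3)))
  # a plateau (no strict increase) resets the counter
  expect_true(is.na(early_stop_generation(c(3, 3.1, 3.1, 3.2, 3.2, 3.3), patience = 3)))
  expect_equal(early_stop_generation(c(1, 2, 3), patience = 2), 3L)
})

test_that("evolution is deterministic, keeps population size, and improves the champion", {
  s <- generate_cgm(sim_params(duration_days = 1, seed = 17))
  sp <- split_chronological(make_windows(s, 3))
  cfg <- evolution_config(population_size = 12, generations = 25, seed = 21)

  r1 <- evolve(sp$train, sp$val, cfg)
  r2 <- evolve(sp$train, sp$val, cfg)
  expect_identical(r1$history, r2$history)  # bitwise-identical history
  expect_identical(flatten_params(r1$best), flatten_params(r2$best))

  expect_equal(nrow(r1$history), r1$generations_run)
  expect_true(r1$stop_reason %in% c("max_generations", "early_stop"))
  # per-generation best training error never worsens under family elitism
  expect_true(all(diff(r1$history$best_train_mse) <= 1e-12))
  # archived champion is the best validation MSE ever observed
  expect_equal(r1$champion_val_mse, min(r1$history$best_val_mse))
})

test_that("the window sweep reports one row per window and selects the validation argmin", {
  s <- generate_cgm(sim_params(duration_days = 1.5, seed = 23))
  cfg <- evolution_config(population_size = 8, generations = 8, seed = 2,
                          window_range = 3:10)
  rep_ <- sweep_window_sizes(s, cfg, method = "evolve")
  expect_equal(nrow(rep_$rows), 8L)
  expect_identical(rep_$rows$window_size, 3:10)
  expect_equal(rep_$selected_window,
               rep_$rows$window_size[which.min(rep_$rows$validation_mse)])
  expect_true(is.finite(rep_$test_mse))
  # the selected model's input width matches the selected window
  expect_equal(rep_$model$topology$layer_sizes[1], rep_$selected_window)

  bp <- sweep_window_sizes(s, cfg, method = "backprop",
                           backprop = list(lr = 0.01, max_epochs = 60))
  expect_equal(nrow(bp$rows), 8L)
  expect_true(is.finite(bp$test_mse))
})

test_that("an evolved model beats the constant-mean predictor on synthetic data", {
  s <- generate_cgm(sim_params(duration_days = 2, seed = 29))
  sp <- split_chronological(make_windows(s, 3))
  cfg <- evolution_config(population_size = 20, generations = 40, seed = 31)
  res <- evolve(sp$train, sp$val, cfg)
  evolved_test <- mse(sp$test$targets, forward_pass(res$best, sp$test$inputs))
  const_test <- mse(sp$test$targets,
                    rep(mean(sp$train$targets), n_pairs(sp$test)))
  expect_lte(evolved_test, const_test)
})
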