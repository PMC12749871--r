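#' Configuration of the genetic algorithm
#'
#' Bundles every knob of the neuro-evolution run. The defaults are the
#' configuration used for the full experiments: 200 generations, population
#' 100, maximum mutation 0.1 and a `[5,5,5]` hidden architecture.
#'
#' @param population_size Number of individuals (default 100).
#' @param generations Maximum generations (default 200).
#' @param max_mutation Half-width of the uniform perturbation added by
#'   [mutate_genotype()] (default 0.1).
#' @param hidden_layers Hidden layer widths (default `c(5, 5, 5)`).
#' @param window_range Window sizes swept by [sweep_window_sizes()]
#'   (default `3:10`).
#' @param patience Consecutive validation-error increases before early
#'   stopping (default 3).
#' @param init_scale Initialisation half-width for [init_genotype()].
#' @param seed Integer seed; every run is deterministic given the seed.
#' @param crossover_coefficients The four mixing coefficients used to create
#'   the four crossover children of each family (default
#'   `c(0.2, 0.4, 0.6, 0.8)`).
#' @param early_stop_statistic Which validation statistic drives early
#'   stopping: the population `"mean"` (default) or the `"best"` individual's
#'   validation MSE.
#' @param hidden_activation,output_activation,bias_placement Passed to
#'   [nn_topology()].
#' @return A list of class `evolution_config`.
#' @export
evolution_config <- function(population_size = 100L, generations = 200L,
                             max_mutation = 0.1, hidden_layers = c(5, 5, 5),
                             window_range = 3:10, patience = 3L,
                             init_scale = 0.5, seed = 1L,
                             crossover_coefficients = c(0.2, 0.4, 0.6, 0.8),
                             early_stop_statistic = c("mean", "best"),
                             hidden_activation = "relu",
                             output_activation = "identity",
                             bias_placement = "post_activation") {
  early_stop_statistic <- match.arg(early_stop_statistic)
  assert_scalar_number(population_size, "population_size", lower = 2)
  assert_scalar_number(generations, "generations", lower = 1)
  assert_scalar_number(max_mutation, "max_mutation", lower = 0)
  assert_scalar_number(patience, "patience", lower = 1)
  assert_scalar_number(init_scale, "init_scale", lower = 0, strict_lower = TRUE)
  if (length(crossover_coefficients) != 4L ||
      any(crossover_coefficients < 0 | crossover_coefficients > 1)) {
    abort_evocgm("evocgm_invalid_param",
                 "`crossover_coefficients` must be 4 values in [0, 1]")
  }
  structure(
    list(population_size = as.integer(population_size),
         generations = as.integer(generations),
         max_mutation = max_mutation,
         hidden_layers = as.integer(hidden_layers),
         window_range = as.integer(window_range),
         patience = as.integer(patience),
         init_scale = init_scale, seed = as.integer(seed),
         crossover_coefficients = crossover_coefficients,
         early_stop_statistic = early_stop_statistic,
         hidden_activation = hidden_activation,
         output_activation = output_activation,
         bias_placement = bias_placement),
    class = "evolution_config"
  )
}

#' @export
print.evolution_config <- function(x, ...) {
  cat(sprintf("<evolution_config> pop %d x %d generations | mutation +/-%g | hidden [%s]\n",
              x$population_size, x$generations, x$max_mutation,
              paste(x$hidden_layers, collapse = ",")))
  cat(sprintf("  windows %d-%d | patience %d on %s val MSE | seed %d\n",
              min(x$window_range), max(x$window_range), x$patience,
              x$early_stop_statistic, x$seed))
  invisible(x)
}

#' Scale MSEs to positive fitness values
#'
#' The GA maximises fitness while the objective (mean squared forecast
#' error) is minimised, so errors are inverted: `fitness = 1 / (mse + eps)`.
#' The small `eps` keeps a perfect predictor's fitness finite. Strictly
#' decreasing in MSE.
#'
#' @param mses Numeric vector of MSEs, all finite and `>= 0`.
#' @param eps Guard constant, default 1e-8.
#' @return Positive fitness vector of the same length.
#' @export
scale_fitness <- function(mses, eps = 1e-8) {
  if (!is.numeric(mses) || any(!is.finite(mses)) || any(mses < 0)) {
    abort_evocgm("evocgm_invalid_param", "MSEs must be finite and non-negative")
  }
  1 / (mses + eps)
}

#' Roulette-wheel selection
#'
#' Samples indices with replacement, each index drawn independently with
#' probability proportional to its fitness (via the cumulative fitness
#' distribution). If every fitness is zero the draw falls back to uniform.
#'
#' @param fitness Non-negative fitness vector.
#' @param count Number of draws.
#' @param seed Optional integer seed; otherwise the current RNG stream is
#'   used.
#' @return Integer vector of `count` selected indices.
#' @export
roulette_select <- function(fitness, count, seed = NULL) {
  if (!is.numeric(fitness) || any(is.na(fitness)) || any(fitness < 0)) {
    abort_evocgm("evocgm_invalid_param", "fitness values must be non-negative")
  }
  prob <- if (sum(fitness) == 0) rep(1, length(fitness)) else fitness
  with_seed(seed, sample.int(length(fitness), size = count,
                             replace = TRUE, prob = prob))
}

#' Averaging crossover
#'
#' Every weight and bias matrix of the child is the element-wise linear
#' combination `alpha * parent1 + (1 - alpha) * parent2` of the
#' corresponding parental matrices.
#'
#' @param p1,p2 Parent genotypes with identical topology.
#' @param alpha Mixing coefficient in `[0, 1]`.
#' @return A child `nn_genotype`.
#' @export
crossover <- function(p1, p2, alpha) {
  stopifnot(inherits(p1, "nn_genotype"), inherits(p2, "nn_genotype"))
  if (!same_topology(p1, p2)) {
    abort_evocgm("evocgm_shape_error", "parents have different topologies")
  }
  assert_scalar_number(alpha, "alpha", lower = 0, upper = 1)
  child <- p1
  for (l in seq_along(p1$weights)) {
    child$weights[[l]] <- alpha * p1$weights[[l]] + (1 - alpha) * p2$weights[[l]]
    child$biases[[l]] <- alpha * p1$biases[[l]] + (1 - alpha) * p2$biases[[l]]
  }
  child
}

#' Bounded uniform mutation
#'
#' Adds an independent `U(-max_mutation, +max_mutation)` draw to every
#' weight and bias entry. The input genotype is not modified.
#'
#' @param g A genotype.
#' @param max_mutation Perturbation bound (default 0.1).
#' @param seed Optional integer seed.
#' @return The mutated `nn_genotype`.
#' @export
mutate_genotype <- function(g, max_mutation = 0.1, seed = NULL) {
  stopifnot(inherits(g, "nn_genotype"))
  assert_scalar_number(max_mutation, "max_mutation", lower = 0)
  with_seed(seed, {
    out <- g
    for (l in seq_along(g$weights)) {
      out$weights[[l]] <- g$weights[[l]] +
        matrix(stats::runif(length(g$weights[[l]]), -max_mutation, max_mutation),
               nrow = nrow(g$weights[[l]]))
      out$biases[[l]] <- g$biases[[l]] +
        matrix(stats::runif(length(g$biases[[l]]), -max_mutation, max_mutation),
               nrow = 1)
    }
    out
  })
}

train_mse_of <- function(g, ds) mse(ds$targets, forward_pass(g, ds$inputs))

#' One family of the hyper-parameter-free reproduction scheme
#'
#' Two parents produce four children by averaging crossover at the four
#' configured coefficients; the last two children are additionally mutated
#' (with independent draws). The six individuals — both parents and all four
#' children — are pooled and the one with the lowest training MSE survives.
#' Because the parents are in the pool, a family can never get worse
#' (family elitism), which is what guarantees convergence without crossover
#' or elitism probability hyper-parameters. Ties go to the earliest pool
#' member (parents first).
#'
#' @param p1,p2 Parent genotypes.
#' @param train Training `window_dataset` defining fitness.
#' @param cfg An [evolution_config()].
#' @param parent_mses Optional pre-computed training MSEs `c(mse1, mse2)` to
#'   avoid re-evaluating cached parents.
#' @return A list with `genotype` (the survivor) and `train_mse`.
#' @export
reproduce_family <- function(p1, p2, train, cfg, parent_mses = NULL) {
  if (!same_topology(p1, p2)) {
    abort_evocgm("evocgm_shape_error", "parents have different topologies")
  }
  alphas <- cfg$crossover_coefficients
  children <- lapply(alphas, function(a) crossover(p1, p2, a))
  children[[3]] <- mutate_genotype(children[[3]], cfg$max_mutation)
  children[[4]] <- mutate_genotype(children[[4]], cfg$max_mutation)
  pool <- c(list(p1, p2), children)
  if (is.null(parent_mses)) {
    parent_mses <- c(train_mse_of(p1, train), train_mse_of(p2, train))
  }
  mses <- c(parent_mses, vapply(children, train_mse_of, 0, ds = train))
  k <- which.min(mses)  # first minimum: parents win ties
  list(genotype = pool[[k]], train_mse = mses[k])
}

#' Generation index at which early stopping fires
#'
#' Scans a per-generation validation-error sequence and returns the first
#' generation at which the error has *strictly* increased for `patience`
#' consecutive generations — the overfitting signal on which both the GA and
#' the back-propagation baseline halt. Returns `NA` if the rule never fires.
#'
#' @param val_errors Numeric vector, one validation error per generation.
#' @param patience Number of consecutive increases required (default 3).
#' @return Integer generation index, or `NA_integer_`.
#' @export
early_stop_generation <- function(val_errors, patience = 3L) {
  rises <- 0L
  for (g in seq_along(val_errors)) {
    rises <- if (g > 1L && val_errors[g] > val_errors[g - 1L]) rises + 1L else 0L
    if (rises >= patience) return(g)
  }
  NA_integer_
}

#' Evolve a population of forecasting networks
#'
#' Runs the genetic algorithm: a population of `population_size` random
#' genotypes is evolved for up to `generations` generations. Each
#' generation, training MSEs are scaled to fitness, `population_size`
#' parent pairs are drawn by roulette-wheel selection (a pair's two indices
#' are re-drawn until distinct) and each family contributes one survivor via
#' [reproduce_family()], keeping the population size constant. Training data
#' alone defines fitness; validation data is reserved for early stopping
#' (population-mean validation MSE rising for `patience` consecutive
#' generations) and for picking the final model from the last generation.
#'
#' @param train,val `window_dataset`s.
#' @param cfg An [evolution_config()]; `cfg$seed` makes the run
#'   deterministic.
#' @return A list of class `evolve_result`: `best` (minimum-validation-MSE
#'   individual of the final generation), `best_val_mse`, `champion`
#'   (best-by-validation individual seen in any generation, archived for
#'   reporting only — it is never re-injected into the population),
#'   `history` (data frame: `generation`, `best_train_mse`, `best_val_mse`,
#'   `mean_val_mse`), `stop_reason` and `generations_run`.
#' @export
evolve <- function(train, val, cfg) {
  stopifnot(inherits(train, "window_dataset"), inherits(val, "window_dataset"),
            inherits(cfg, "evolution_config"))
  if (n_pairs(train) == 0L || n_pairs(val) == 0L) {
    abort_evocgm("evocgm_empty_dataset", "train and validation sets must be non-empty")
  }
  topo <- nn_topology(ncol(train$inputs), hidden = cfg$hidden_layers,
                      hidden_activation = cfg$hidden_activation,
                      output_activation = cfg$output_activation,
                      bias_placement = cfg$bias_placement)
  P <- cfg$population_size
  with_seed(cfg$seed, {
    pop <- lapply(seq_len(P), function(i) init_genotype(topo, cfg$init_scale))
    pop_train_mse <- vapply(pop, train_mse_of, 0, ds = train)

    hist_best_train <- numeric(0)
    hist_best_val <- numeric(0)
    hist_mean_val <- numeric(0)
    champion <- NULL
    champion_val <- Inf
    stop_reason <- "max_generations"
    signal_hist <- numeric(0)

    for (gen in seq_len(cfg$generations)) {
      val_mse <- vapply(pop, function(g) mse(val$targets, forward_pass(g, val$inputs)), 0)
      if (any(!is.finite(val_mse)) || any(!is.finite(pop_train_mse))) {
        abort_evocgm("evocgm_divergence",
                     sprintf("non-finite fitness in generation %d", gen))
      }
      hist_best_train <- c(hist_best_train, min(pop_train_mse))
      hist_best_val <- c(hist_best_val, min(val_mse))
      hist_mean_val <- c(hist_mean_val, mean(val_mse))
      gen_champ <- which.min(val_mse)
      if (val_mse[gen_champ] < champion_val) {
        champion_val <- val_mse[gen_champ]
        champion <- pop[[gen_champ]]
      }

      signal <- if (cfg$early_stop_statistic == "mean") mean(val_mse) else min(val_mse)
      signal_hist <- c(signal_hist, signal)
      if (isTRUE(early_stop_generation(signal_hist, cfg$patience) == gen)) {
        stop_reason <- "early_stop"
        break
      }
      if (gen == cfg$generations) break

      fitness <- scale_fitness(pop_train_mse)
      new_pop <- vector("list", P)
      new_mse <- numeric(P)
      for (f in seq_len(P)) {
        i <- roulette_select(fitness, 1L)
        j <- roulette_select(fitness, 1L)
        while (j == i) j <- roulette_select(fitness, 1L)
        fam <- reproduce_family(pop[[i]], pop[[j]], train, cfg,
                                parent_mses = pop_train_mse[c(i, j)])
        new_pop[[f]] <- fam$genotype
        new_mse[f] <- fam$train_mse
      }
      pop <- new_pop
      pop_train_mse <- new_mse
    }

    final_val <- vapply(pop, function(g) mse(val$targets, forward_pass(g, val$inputs)), 0)
    best_idx <- which.min(final_val)
    history <- data.frame(generation = seq_along(hist_best_train),
                          best_train_mse = hist_best_train,
                          best_val_mse = hist_best_val,
                          mean_val_mse = hist_mean_val)
    structure(
      list(best = pop[[best_idx]], best_val_mse = final_val[best_idx],
           champion = champion, champion_val_mse = champion_val,
           history = history, stop_reason = stop_reason,
           generations_run = nrow(history)),
      class = "evolve_result"
    )
  })
}

#' @export
print.evolve_result <- function(x, ...) {
  cat(sprintf("<evolve_result> %d generation(s), stopped: %s\n",
              x$generations_run, x$stop_reason))
  cat(sprintf("  final best val MSE %.4f | archived champion val MSE %.4f\n",
              x$best_val_mse, x$champion_val_mse))
  invisible(x)
}
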