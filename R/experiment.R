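#' End-to-end experiment configuration
#'
#' Describes a full comparison experiment: where the CGM data come from (a
#' CSV file or a synthetic-trace specification — exactly one), how pairs are
#' split, the genetic-algorithm settings, the baseline settings and where to
#' write results. A single global seed deterministically derives per-stage
#' seeds so any stage can be re-run in isolation.
#'
#' @param data Either a path to a CGM CSV file or a [sim_params()] object.
#' @param split A [split_spec()].
#' @param evolution An [evolution_config()].
#' @param backprop List of baseline options: `lr`, `max_epochs`.
#' @param out_dir Output directory (created if needed).
#' @param seed Global integer seed.
#' @param max_gap Gap-interpolation limit in seconds (see
#'   [interpolate_gaps()]).
#' @param replicates Runs per window per method, best kept.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(data, split = split_spec(),
                              evolution = evolution_config(),
                              backprop = list(lr = 0.01, max_epochs = 500L),
                              out_dir = tempfile("evocgm_run_"),
                              seed = 1L, max_gap = 3600, replicates = 1L) {
  if (missing(data) || is.null(data)) {
    abort_evocgm("evocgm_invalid_param",
                 "`data` is required: a CGM CSV path or a sim_params object")
  }
  if (!(is.character(data) && length(data) == 1L) && !inherits(data, "sim_params")) {
    abort_evocgm("evocgm_invalid_param",
                 "`data` must be a single file path or a sim_params object")
  }
  stopifnot(inherits(split, "split_spec"), inherits(evolution, "evolution_config"))
  structure(
    list(data = data, split = split, evolution = evolution,
         backprop = backprop, out_dir = out_dir, seed = as.integer(seed),
         max_gap = max_gap, replicates = as.integer(replicates)),
    class = "experiment_config"
  )
}

#' Run the full forecasting experiment
#'
#' Executes the whole protocol: load or simulate the CGM trace, interpolate
#' short gaps, build the per-window datasets *once* (so both methods see
#' byte-identical training, validation and test blocks — a fairness
#' requirement that is asserted, not assumed), sweep every window size with
#' the genetic algorithm and with the back-propagation baseline, select each
#' method's best window on validation error, evaluate the selected models on
#' the test block, and summarise the comparison.
#'
#' Writes to `config$out_dir`: `evolved_sweep.csv` and `backprop_sweep.csv`
#' (per-window validation MSEs), `evolved_history.csv` (generation-level GA
#' history at the selected window), `evolved_model.json` and
#' `backprop_model.json` (the selected genotypes) and `summary.json`.
#' Deterministic given `config$seed`: a re-run reproduces `summary.json`
#' byte for byte.
#'
#' @param config An [experiment_config()].
#' @param verbose Print progress messages? Default `FALSE`.
#' @return The [summarize_comparison()] summary, with the report file paths
#'   in attribute `"paths"`.
#' @export
run_experiment <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  say <- function(...) if (verbose) message(sprintf(...))

  # stage seeds derived from the single global seed
  sim_seed <- derive_seed(config$seed, 1)
  evo_seed <- derive_seed(config$seed, 2)
  bp_seed <- derive_seed(config$seed, 3)

  if (inherits(config$data, "sim_params")) {
    params <- config$data
    params$seed <- sim_seed
    say("simulating %.1f-day synthetic trace (seed %d)", params$duration_days, sim_seed)
    series <- generate_cgm(params)
    if (params$missing_rate > 0 || params$jitter_fraction > 0) {
      series <- inject_artifacts(series, params$missing_rate,
                                 params$jitter_fraction,
                                 seed = derive_seed(config$seed, 4))
    }
  } else {
    say("reading CGM trace from %s", config$data)
    series <- read_cgm_csv(config$data)
  }
  series <- interpolate_gaps(series, max_gap = config$max_gap)
  say("series: %d readings after interpolation", length(series))

  windows <- config$evolution$window_range
  datasets <- build_window_splits(series, windows, config$split)

  evo_cfg <- config$evolution
  evo_cfg$seed <- evo_seed
  say("sweeping windows %d-%d with the genetic algorithm", min(windows), max(windows))
  evolved <- sweep_window_sizes(series, evo_cfg, config$split, method = "evolve",
                                replicates = config$replicates, datasets = datasets)
  bp_cfg <- config$evolution
  bp_cfg$seed <- bp_seed
  say("sweeping windows %d-%d with back-propagation", min(windows), max(windows))
  baseline <- sweep_window_sizes(series, bp_cfg, config$split, method = "backprop",
                                 backprop = config$backprop,
                                 replicates = config$replicates,
                                 datasets = datasets)
  # fairness: both methods must have consumed byte-identical splits
  stopifnot(identical(evolved$datasets, baseline$datasets))

  summary <- summarize_comparison(evolved, baseline)

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    evolved_sweep = file.path(config$out_dir, "evolved_sweep.csv"),
    backprop_sweep = file.path(config$out_dir, "backprop_sweep.csv"),
    evolved_history = file.path(config$out_dir, "evolved_history.csv"),
    evolved_model = file.path(config$out_dir, "evolved_model.json"),
    backprop_model = file.path(config$out_dir, "backprop_model.json"),
    summary = file.path(config$out_dir, "summary.json")
  )
  write_sweep_csv(evolved, paths$evolved_sweep)
  write_sweep_csv(baseline, paths$backprop_sweep)
  # regenerate GA history at the selected window for the report
  sel_cfg <- evo_cfg
  sel_cfg$seed <- evolved$selected_seed
  sel_split <- datasets[[as.character(evolved$selected_window)]]
  sel_run <- evolve(sel_split$train, sel_split$val, sel_cfg)
  utils::write.csv(sel_run$history, paths$evolved_history, row.names = FALSE)
  write_genotype_json(evolved$model, paths$evolved_model)
  write_genotype_json(baseline$model, paths$backprop_model)

  summary_doc <- unclass(summary)
  summary_doc$seed <- config$seed
  summary_doc$evolved_rows <- evolved$rows
  summary_doc$backprop_rows <- baseline$rows
  jsonlite::write_json(summary_doc, paths$summary, digits = NA,
                       auto_unbox = TRUE, pretty = TRUE, dataframe = "columns")
  say("report written to %s", config$out_dir)
  attr(summary, "paths") <- paths
  summary
}
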