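---
title: "Evolving neural networks for one-step CGM glucose forecasting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolving neural networks for one-step CGM glucose forecasting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evocgm)
```

## The forecasting problem

A continuous glucose monitor reports interstitial glucose in mmol/L at a
nominal 5-minute interval. One-step forecasting asks: given the last $w$
readings, what will the next reading be? `evocgm` frames this as supervised
regression with a sliding window: every run of $w + 1$ consecutive readings
inside a contiguous stretch of the record contributes one training pair —
the first $w$ readings (oldest first) as inputs, the last as target. The
prediction horizon is a single step, i.e. 5 minutes; longer horizons
(30–120 min) are a different problem and out of scope here.

Two properties of real CGM exports shape the preprocessing:

* **missing runs.** Sensors drop readings, often several in a row. Short
  gaps (up to `max_gap`, default 60 min) are filled by time-linear
  interpolation at nominal-interval grid points, rounded to the 1-decimal
  precision of measured readings. Longer gaps are left open and
  `segment_contiguous()` splits the series there, so no window ever spans a
  multi-hour hole — forecasting across one would be meaningless. The 60-min
  cap is a deliberate limit: unbounded interpolation over long gaps would
  fabricate smooth structure that the model could then "forecast".
* **interval jitter.** Devices frequently record intervals of 4 min 59 s or
  5 min 1 s instead of exactly 5 min. This ±1 s artifact (about 41 % of
  intervals in our experience) is physiologically irrelevant (0.33 % of the
  interval), so jittered steps are treated as nominal for windowing; the
  segmentation tolerance (`jitter_tol`, default 2 s) is just wide enough to
  absorb it while still splitting at genuine gaps.

## Network and genotype

The forecaster is a deliberately small feed-forward network: $w$ inputs,
three hidden layers of 5 nodes, one output, ReLU activations in the hidden
layers. Its entire parameter set — one weight matrix and one bias row vector
per layer — is the *genotype* the genetic algorithm manipulates; decoded by
`forward_pass()` it becomes the *phenotype*, a functioning forecaster.

Two layer-arithmetic conventions are supported because descriptions of such
networks are ambiguous about where the bias enters:

* `post_activation` (package default): $a_\ell = \mathrm{act}(a_{\ell-1} W_\ell) + b_\ell$;
* `pre_activation` (the textbook convention): $a_\ell = \mathrm{act}(a_{\ell-1} W_\ell + b_\ell)$.

For evolution the distinction is cosmetic — the GA only sees a fitness
landscape — but the back-propagation gradients differ, and
`mse_gradient()` honours whichever is configured (verified against central
finite differences in the test suite). The output activation defaults to
identity rather than ReLU: a rectified output node whose pre-activation goes
negative produces zero gradient everywhere and can dead-lock gradient
training, while glucose targets are strictly positive so rectification buys
nothing. The literal all-ReLU reading remains available via
`nn_topology(..., output_activation = "relu")`.

Initialisation is $U(-0.5, 0.5)$ on every parameter. Nothing in the method
depends delicately on this; it merely puts initial forecasts on a scale
where selection pressure is informative.

## The genetic algorithm

Fitness is the inverse training MSE, $1/(\mathrm{MSE} + \varepsilon)$ with
$\varepsilon = 10^{-8}$ guarding the (never observed) perfect-predictor
case. Each generation:

1. training MSEs are scaled to fitness and `population_size` parent pairs
   are drawn by roulette-wheel selection (cumulative fitness distribution,
   with replacement; a pair's indices are re-drawn until distinct);
2. each pair produces four children by averaging crossover
   $\alpha p_1 + (1-\alpha) p_2$ at $\alpha = 0.2, 0.4, 0.6, 0.8$; the last
   two children are additionally mutated by adding independent
   $U(-0.1, 0.1)$ noise to every parameter;
3. the two parents and four children are pooled and the member with the
   lowest training MSE survives — one survivor per family, so the
   population size is constant by construction.

Family elitism is the scheme's hyper-parameter-free convergence guarantee:
since the parents sit in the pool, a family's best training error can never
worsen. The per-generation best training MSE is therefore non-increasing,
which the test suite asserts over full runs.

Several choices here were genuinely open and are worth recording:

* **family formation.** How pairs are formed and how the population count is
  maintained admits many schemes; we use the simplest consistent with
  four-children families and a constant population: one family (and one
  survivor) per population slot, parents drawn by roulette with
  replacement. Re-drawing identical indices avoids degenerate self-families
  that mutation alone would have to diversify.
* **crossover coefficients** default to $\{0.2, 0.4, 0.6, 0.8\}$ — spread
  across the simplex rather than clustered at the midpoint, so a family
  explores both parent-like and blended children. They are configurable.
* **fitness uses training error only**; validation error is reserved for
  early stopping and final model selection. Mixing the two would let the
  stopping signal leak into selection and undermine its role as an
  overfitting detector.
* **tie-breaking** is first-in-pool (parents first) everywhere, for exact
  reproducibility across runs and platforms.

## Early stopping and model selection

Overfitting shows up as validation error rising while training error still
falls. Both training loops halt via the same rule, implemented once in
`early_stop_generation()`: stop at the first generation (or epoch) where the
validation signal has *strictly* increased for `patience = 3` consecutive
generations; plateaus reset the counter, and the increase threshold is 0.
For the GA the signal is the population-mean validation MSE — "mean error on
the validation data" could also mean the best individual's error, so the
choice is exposed as `early_stop_statistic = "mean" | "best"`, with `"mean"`
the default because the population mean is the smoother, more conservative
overfitting signal.

On halt (or at the generation limit), the final model is the
minimum-validation-MSE individual of the *final generation*. A best-ever
champion (by validation MSE) is archived for reporting, but deliberately
never re-injected into the population: convergence rests on family elitism
alone, and re-injection would change the scheme being studied.

The data are split chronologically 70/15/15 (train/validation/test),
validation and test receiving $\lfloor n \cdot f \rfloor$ pairs and the
remainder going to training. Chronological blocks — rather than a shuffled
split — prevent look-ahead leakage in an autocorrelated series; the cost is
that absolute errors are not comparable with shuffled-split results.
Inputs are not normalised by default (errors in raw mmol/L are directly
interpretable; `standardize_splits()` exists, fitting on training data
only).

The window sweep trains at every $w \in \{3, \dots, 10\}$, selects the
window with minimum validation MSE, and evaluates that single model once on
the test block. A back-propagation run that diverges (non-finite loss — a
real behaviour of full-batch gradient descent at fixed learning rate on
unfavourable initialisations) is surfaced as a classed error by
`backprop_train()` and recorded as validation MSE `Inf` by the sweep, so the
report always carries one row per window. The baseline's defaults
(`lr = 0.01`, 500 full-batch epochs) are ordinary choices for a network of
this size; the occasional erratic window is reported, not hidden, since the
baseline's fragility is itself part of the comparison.

## The synthetic generator

Real clinical traces cannot be redistributed, so `generate_cgm()` produces
traces with the statistical texture that matters to this pipeline:

| component | default | why |
|---|---|---|
| baseline | 6 mmol/L | mid-normal glucose |
| circadian sinusoid | 0.8 mmol/L amplitude | mild diurnal swing |
| meals | 3/day at 08:00, 13:00, 19:00; amplitude 3 mmol/L; 30 min linear rise, 90 min exponential decay | typical postprandial excursion shape and size |
| AR(1) noise | $\phi = 0.85$, innovation sd 0.15 mmol/L | strongly autocorrelated sensor/physiology noise; one-step changes ~0.2–0.3 mmol/L, the regime where RMSEs around 0.3 mmol/L are meaningful |
| rounding / clipping | 1 dp, [2.0, 22.2] mmol/L | device reporting precision and range |

`inject_artifacts()` then deletes readings in geometric-length runs (mean 3
— dropouts cluster) at a configurable expected rate, and jitters a
configurable fraction (default 0.41) of inter-reading intervals to
299 s/301 s, the offsets accumulating into the timestamps as on a device
clock. Both steps are seed-deterministic.

What the generator does *not* emulate: insulin–glucose kinetics, exercise
effects, sensor compression artifacts, calibration drift, or inter-patient
variability. Passing tests on synthetic data therefore demonstrate that the
algorithms are implemented correctly and that evolution can drive this
architecture to a known noise floor — not that any particular accuracy will
transfer to a given patient's data. The duration default (13.8 days) is a
typical sensor wear; note that a stated wear of 13.8 days and a stated count
of ~3854 readings at 5-min intervals are mutually inconsistent
(13.8 × 288 ≈ 3974), and the generator treats duration as ground truth.

## Numerical and testing choices

* All randomness flows from explicit integer seeds; `run_experiment()`
  derives per-stage seeds (simulation, per-window runs, baseline
  initialisation) from one global seed so stages can be reproduced in
  isolation. Re-running an experiment with the same seed reproduces the
  summary JSON byte for byte.
* Degenerate inputs fail loudly with classed conditions
  (`evocgm_empty_input`, `evocgm_monotonicity_error`, `evocgm_bounds_error`,
  `evocgm_divergence`, …) rather than propagating NA.
* The test suite sizes its simulations for depth per minute: forward-pass
  and gradient oracles on dozens of random shapes; GA invariants over full
  (small) runs; dynamics recovery with ~2000 windows, population 50 and 100
  generations, where the evolved network reaches the $\sigma^2 = 0.0225$
  noise floor of $y_{t+1} = 0.5 y_t + 0.5 y_{t-1} + N(0, 0.15^2)$ within a
  factor of two; and a full two-method protocol on one synthetic day with
  population 30 and 50 generations. These scales were chosen so the entire
  suite runs in well under a minute while each check still exercises the
  full code path at meaningful convergence.

## Known limitations

* Only one-step (5-min) horizons; no multi-step or adjustable windows.
* Weight evolution only: topology and GA hyper-parameters are fixed, not
  evolved.
* The baseline is plain full-batch gradient descent — no momentum, Adam, or
  learning-rate schedules — because it is the comparison point, not a
  state-of-the-art contender.
* Synthetic data, however carefully textured, is not clinical data; absolute
  error levels reported on it characterise the simulation, not patients.
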