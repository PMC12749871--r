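# evocgm

Neuro-evolution of feed-forward networks for short-horizon blood-glucose
forecasting from continuous glucose monitoring (CGM) data.

## The problem

People with diabetes need to anticipate where their blood glucose is heading
in the next few minutes to avoid hypo- and hyperglycaemia. A CGM sensor
records interstitial glucose (mmol/L) roughly every 5 minutes, which makes
one-step-ahead forecasting a supervised learning problem: given the *w* most
recent readings *y*<sub>t−w+1</sub>, …, *y*<sub>t</sub> (a sliding window,
*w* ∈ {3, …, 10}), predict the next reading *y*<sub>t+1</sub>.

`evocgm` implements and compares two ways of fitting the same small
feed-forward network (*w* inputs, three hidden layers of 5 ReLU nodes, one
output) to this task:

* **neuro-evolution** — a genetic algorithm evolves the full set of weight
  and bias matrices (the genotype). Fitness is the inverse of the mean
  squared forecast error,

  MSE = Σᵢ (yᵢ − ŷᵢ)² / n,

  scaled as 1/(MSE + ε) so that smaller errors mean higher fitness. Parents
  are drawn by roulette-wheel selection; each pair produces four children by
  averaging crossover (child = α·p₁ + (1−α)·p₂ at α = 0.2, 0.4, 0.6, 0.8, the
  last two children also mutated by bounded uniform noise, |Δ| ≤ 0.1); the
  six family members are pooled and only the fittest survives (family
  elitism), so no crossover/mutation/elitism probabilities need tuning;
* **back-propagation** — full-batch gradient descent on the same MSE, the
  conventional baseline.

Both use the same validation-based protocol: chronological
train/validation/test splits, early stopping once the validation error has
risen for 3 consecutive generations (or epochs), a sweep over window sizes
3–10, selection of the window with the lowest validation MSE, and a single
final evaluation of the selected model on the test block.

Because real clinical CGM traces are rarely shareable, the package also ships
a synthetic CGM generator (circadian rhythm + meal responses + AR(1) noise,
plus the recording artifacts of real exports: clustered missing runs and
±1 s interval jitter) so that the entire pipeline is reproducible from a
seed.

## Worked example

```r
library(evocgm)

# two synthetic days with realistic recording artifacts
params <- sim_params(duration_days = 2, seed = 42)
trace  <- inject_artifacts(generate_cgm(params), missing_rate = 0.02,
                           jitter_fraction = 0.41, seed = 43)
trace  <- interpolate_gaps(trace)    # fill gaps up to 60 min
trace
#> <cgm_series> 576 readings spanning 2.0 days
#>   interval: 300 s nominal | glucose: 4.6-10.0 mmol/L | 6 interpolated

cfg <- evolution_config(population_size = 30, generations = 60,
                        window_range = 3:6, seed = 7)
report <- sweep_window_sizes(trace, cfg, method = "evolve")
report
#> <sweep_report> method: evolve
#>  window_size validation_mse
#>            3         0.0415
#>            4         0.0414
#>            5         0.0442
#>            6         0.0469
#> selected window 4 | test MSE 0.0447

baseline <- sweep_window_sizes(trace, cfg, method = "backprop")
summarize_comparison(report, baseline)
#> <comparison_summary> evolved network vs back-propagation baseline
#>   best validation MSE: 0.041 (window 4) vs 0.247 (window 4)
#>   test MSE: 0.045 vs 0.349
#>   MSE drop 0.206 (83.4% lower) | RMSE 0.2025 vs 0.4970, drop 0.2945 (59.3% lower)
#>   window size reduction: 0%
```

Reading the numbers: validation MSE is in (mmol/L)², so the evolved model's
0.0414 corresponds to a typical one-step error (RMSE) of √0.0414 ≈ 0.20
mmol/L, close to this simulation's noise floor; the gradient-descent
baseline lands an order of magnitude higher on the same splits (and at
window 3 it performs erratically — gradient descent on this small
architecture is sensitive to initialisation, which is part of the motivation
for evolving the weights instead). The comparison summary quotes the drop in
MSE and RMSE and the relative improvements computed from each method's best
window.

`run_experiment()` wraps the whole protocol (simulate/read → interpolate →
both sweeps on byte-identical splits → comparison report on disk),
deterministic from one seed.

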