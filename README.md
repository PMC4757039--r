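# tdrcapture

Capture behaviour and stress physiology of sharks on demersal longlines,
from hook-mounted time-depth recorders (TDRs).

## What problem this solves

Hook a shark on a bottom-set longline and a depth recorder on the gangion
(the branch line joining hook and mainline) watches the whole capture. For
fisheries ecophysiologists the trace answers three questions that are
otherwise unobservable in the wild: when was the animal hooked, how long did
it fight the gear, and what fraction of that time did it spend moving?
Movement matters because species that can ventilate while stationary
(buccal pumpers) may ride out capture resting on the sea floor — a
behavioural buffer against the stress response that blood biochemistry (pH,
lactate, glucose, potassium, osmolality, haematocrit) measures at landing.

`tdrcapture` provides:

* **`tdr_behaviour`** — the depth-trace pipeline. The capture point is the
  first sustained deviation from a trailing 1-min steady baseline. Baselines
  are recalculated every 30 min (tide) and across movement periods
  straddling significant tidal shifts. Per-sample absolute deviations are
  scored against thresholds `f × E + s`, where `E = 0.60 m` is the effective
  gangion extension (0.70 m gangion − 0.10 m device offset), `f ∈ {0.5, 1}`
  and `s` is the baseline standard deviation (swell). Supra-threshold runs
  with sub-threshold gaps ≤ 4 s bridged are movement bouts; everything past
  the haul point is discarded.
* **`synth_tdr`** — a seeded trace simulator (set depth + tidal sinusoid +
  Gaussian swell + bout excursions + haul ramp) with closed-form ground
  truth for recovery testing.
* **`bayes_infer`** — Bayesian additive linear regression
  `y ~ duration + SST` by Gibbs sampling (vague normal priors, precision
  1e-6; inverse-gamma residual prior; 50,000 iterations, burn-in 2,000,
  thinning 10), natural-log lactate, credibility-interval significance
  (significant ⇔ the 2.5–97.5% interval excludes 0), per-draw
  back-transformed predicted means, and BEST-style two-group differences.
* **`synth_blood`** — blood cohorts generated under the fitted additive
  models, plus coverage/power recovery experiments.
* **`cli_pipeline`** — `analyze-tdr`, `fit-blood`, `simulate`, `recovery`
  subcommands with provenance blocks (`inst/cli/tdrcapture`).

## Worked example

```r
library(tdrcapture)

# simulate one capture and run the behavioural pipeline on it
st  <- simulate_trace(trace_scenario(seed = 42))
res <- analyze_trace(st$trace, haul_time_s = st$truth$haul_time_s)
res$summary
#> Capture summary for SIM
#>   capture at 1800 s (baseline depth 7.87 m), hauled at 11400 s
#>   capture duration: 160.0 min
#>    50% threshold: 9 bout(s), 20.8 min moving (13.0% of capture)
#>   100% threshold: 8 bout(s), 0.3 min moving (0.2% of capture)
```

The detected capture time (1800 s) matches the simulator's ground truth
exactly, and the 13.0% movement at the 50%-extension threshold is within
half a point of the true occupancy (13.5%). The 100% threshold scores far
less movement — it only triggers when the animal pulls to full gangion
extension.

```r
# a synthetic blood cohort at the study's scale, and the lactate regression
cohort <- generate_cohort(blood_scenario(n = 22, seed = 1))
fit <- fit_additive_regression(cohort, "lactate", mcmc = mcmc_config(seed = 1))
fit
#> Bayesian additive regression: lactate (log scale) (n = 22)
#>                  term       mean      sd   ci_2.5   ci_97.5 significant
#>             intercept -1.7920000 0.89670 -3.53100 -0.012510           *
#>  capture_duration_min -0.0005284 0.00248 -0.00538  0.004441
#>                 sst_c  0.2456000 0.05693  0.13250  0.360800           *
#> residual s.d.: 0.5728 (0.4195, 0.7985)
```

Capture duration does nothing (its interval straddles 0) while warmer water
raises log-lactate by ~0.25 per °C — the generating truth (0 and 0.221) sits
inside both intervals. Predicted means back on the concentration scale, with
duration standardised at 0 min:

```r
predict_mean(fit, c(12, 16.4, 20))
#>   sst_c duration_min      mean   ci_2.5   ci_97.5
#> 1  12.0            0  3.405654 1.520301  6.673107
#> 2  16.4            0  9.988653 4.477334 19.181340
#> 3  20.0            0 25.279175 8.928330 57.542275
```

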