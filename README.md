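# phasecurve

Does cognitive training improve a general capacity, or just the trained
task? One way to tell the two apart is their time course: task-specific
gains are fast and saturate within days, while capacity gains are slow
and keep accruing for weeks. `phasecurve` implements a per-subject
dual-process model of daily training performance that separates and
quantifies the two, for researchers analysing longitudinal
cognitive-training data (e.g. daily spatial working-memory scores over
an 8-week program).

## The model

Each subject's daily level `y_t` follows a piecewise-linear learning
curve with a hidden switch:

```
phase 1:  y_t = (beta_cap + beta_TS) t + alpha + w_t
phase 2:  y_t =  beta_cap t + Delta_TS + alpha + w_t,   Delta_TS = beta_TS / tau
```

with Gaussian noise `w_t ~ N(0, sigma^2)`. The phase is the hidden state
of a two-state left-to-right HMM: training starts in phase 1 and
switches to phase 2 with per-day probability `tau` (geometric dwell
time, no return). The last day generated by phase 1 — the *transition
day* — gets a posterior distribution over days `1..10`, and all five
parameters are estimated per subject by expectation–maximization
(weighted least-squares M-step profiled over `tau`, multiple restarts,
exhaustive-oracle-verified on short series).

The package also ships the surrounding workflow: reading/writing the
training and transfer-test CSV dialects, transfer-panel preprocessing
(exclusion of subjects with too many missed tests, 35-nearest-neighbour
imputation, standardization to the first test session), a synthetic
cohort generator with known ground truth, and a parameter-recovery
study reporting bias, RMSE and transition-day accuracy.

## Worked example

```r
library(phasecurve)

cohort <- simulate_population(simulation_config(n_subjects = 3, seed = 42))
fit <- fit_em(dplyr::filter(cohort$training, subject_id == "S0001"))
fit
#> <phase_fit> 22 sessions, loglik -18.5049
#> <hmm_params>
#>   beta_cap = 0.0980418  beta_TS = 1.35941  alpha = 4.37055
#>   tau = 0.126943  sigma = 0.510948  (delta_TS = 10.7089)
#>   transition day: mean 7.595, MAP 7 (converged, 7 EM iterations)

tidy(fit)
#> # A tibble: 7 x 2
#>   term           estimate
#>   <chr>             <dbl>
#> 1 beta_cap         0.0980
#> 2 beta_TS          1.36
#> 3 alpha            4.37
#> 4 tau              0.127
#> 5 sigma            0.511
#> 6 delta_TS        10.7
#> 7 transition_day   7.60
```

This subject was generated with `beta_cap = 0.076`, `beta_TS = 1.46`,
`alpha = 3.83` and a true switch after day 8: the fit recovers a slow
capacity slope of about 0.1 levels/day, a fast task-specific rate of
about 1.4 levels/day that plateaus around day 7–8, and `delta_TS` — the
total task-specific gain — of about 10.7 levels. `autoplot(fit)` draws
the data with both fitted phase lines and the estimated switch;
`fit_cohort()` does the same for a whole table of subjects and
`autoplot()` on its result shows the population's transition-day
distribution. `tidy()`/`glance()` methods return tibbles throughout, so
results pipe straight into dplyr/ggplot2.

The end-to-end validation loop:

```r
study <- run_simulation_study(simulation_config(n_subjects = 100, seed = 1))
glance(study)   # within-1/2-day fractions, transition-day RMSE, counts
```

A command-line wrapper over the same functions
(`simulate` / `fit` / `recover` / `study`) lives in
`inst/scripts/phasecurve-cli.R`.

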