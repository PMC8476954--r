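# sitmotif

Office workers' low-back pain (LBP) waxes and wanes within a day, and how a
person *sits* — not just how long — may explain part of that change.
`sitmotif` analyzes dynamic sitting behavior recorded by a "smart chair":
four load cells under the seat corners stream the load distribution, from
which a center-of-pressure (COP) time series is computed. The package

* reduces raw four-channel load-cell recordings to a 1 Hz COP series with
  presence detection and sitting time (`compute_cop()`, `downsample_1hz()`),
* segments the COP series into recurring **sitting states** — stable
  sitting, slight sway, big sway, off chair — by Toeplitz
  inverse-covariance clustering (`fit_ticc()`, `select_k()`),
* discovers recurring **motifs**, ordered state patterns such as the
  stable-sit/slight-sway alternation, by motif-aware state assignment
  (`fit_masa()`),
* predicts the within-day **change of LBP** (exacerbated / no change /
  improved, the sign of morning-minus-evening pain score) from per-day
  features with a feature-weighted Parzen-window probabilistic neural
  network tuned by the social spider algorithm under nested stratified
  cross-validation (`nested_cv_train()`, `repeat_cv()`),
* explains the classifier by exact Shapley attribution (`exact_shapley()`,
  `shapley_cv()`) and compares motif rates across LBP-change groups
  (`kruskal_wallis()`, `dunn_posthoc()`).

Because chair recordings of this kind are rarely shareable, the package
ships a first-class synthetic cohort generator (`simulate_cohort()`) that
emulates the study design end to end — state dynamics, planted motifs,
load-cell physics, questionnaires and a planted motif-rate/LBP association
— so every stage is testable from scratch.

## The models in brief

**States.** Each second's COP sample is embedded in a window of `w = 5`
consecutive samples. A state is a Gaussian over windows whose precision
(inverse covariance) is symmetric block Toeplitz — time-invariant
within-window dependencies. Fitting alternates an exact dynamic-programming
assignment under a switching penalty `beta` with a block-Toeplitz
constrained graphical lasso (ADMM) per cluster:

    min over assignments and Thetas of
      sum_i [ ||lambda o Theta_i||_1
              + sum_{t in P_i} ( -loglik(X_t, Theta_i) + beta 1{s_{t-1} != s_t} ) ]

Defaults `K = 4`, `w = 5`, `beta = 50`, `lambda = 0.001`; `K` can be chosen
by a BIC sweep.

**Motifs.** A motif is an ordered state sequence (length > 2, no adjacent
repeats) appearing more than `L` times as non-overlapping, variable-length
instances. Decoding maximizes the state-assignment likelihood plus
`log(gamma)` for every measurement left outside a motif instance, exactly,
over an expanded state space; candidates come from the run-length
compressed sequence and are ranked by occurrence count.

**Prediction.** Per participant-day features (sex, sitting hours, motif
rate per 30 sitting minutes, morning sleepiness, morning fullness) feed a
PNN whose kernel is shrunk per feature by weights `omega` and smoothed by
`sigma`, both tuned by the social spider algorithm to minimize inner
5-fold validation cross-entropy inside each of 6 outer folds.

## Worked example

Simulate one 4-hour office day with the stable/slight alternation planted
at 2 occurrences per 30 minutes, regenerate the raw load-cell stream, and
run the full signal path:

```r
library(sitmotif)

specs <- default_state_specs(include_off_chair = FALSE)
dyn <- office_dynamics()
sim <- simulate_state_sequence(specs, T = 14400, dwell = dyn$dwell,
                               planted_motif = c(1L, 2L, 1L), motif_rate = 2,
                               trans = dyn$trans, seed = 42)
cop <- emit_cop(sim$states, specs, seed = 43)
loadcells <- emit_loadcells(cop, body_weight = 65, hz = 1, seed = 44)

cop1 <- downsample_1hz(compute_cop(loadcells))
windows <- stack_windows(cop1, w = 5)
sel <- select_k(windows, 2:5, ticc_config(w = 5, beta = 50, lam = 0.001, seed = 1))
print(sel$table)
#>   K        bic error
#> 1 2  -95218.03  <NA>
#> 2 3 -100964.89  <NA>
#> 3 4 -100750.05  <NA>
#> 4 5 -100465.14  <NA>
tm <- fit_ticc(windows, ticc_config(K = sel$k_best, w = 5, beta = 50,
                                    lam = 0.001, seed = 1))
mm <- fit_masa(windows, tm, masa_config(gamma = 0.9, L = 5, seed = 1))

print(tm)
#> TICC model: K = 3, w = 5, beta = 50, lam = 0.001
#>   14396 windows, 5 EM iterations, final objective -48198.769
#>   cluster sizes: 13245, 572, 579
print(mm)
#> MASA model: gamma = 0.9, L = 5, 33 instances
#>   common motif: 1-3-1
labs <- label_states(tm)
cat("common motif:", paste(labs[mm$common_motif], collapse = " -> "), "\n")
#> common motif: stable_sit -> slight_sway -> stable_sit
rate <- motif_occurrence_rate(sum(mm$instances$motif_id == 1), sitting_time(cop1))
cat(sprintf("motif occurrence rate: %.2f per 30 min\n", rate))
#> motif occurrence rate: 2.12 per 30 min
```

The BIC sweep lands on the three seated states (off-chair periods never
enter the windows), the segmentation finds a dominant stable-sitting
cluster plus slight- and big-sway clusters, and the top-scored motif is the
planted stable-sit/slight-sway alternation, recovered near the planted rate
(the generator planted 14 instances in 4 h; spontaneous background slight
sways contribute a few more). On cohort simulations the per-day motif rate
is then the
headline predictor of the LBP-change label; see the methods vignette
(`vignettes/sitmotif-methods.Rmd`) for the full model descriptions and
`run_pipeline()` for the assembled analysis.

A thin command-line front end for the simulate / segment / motifs steps is
at `inst/cli/sitmotif-cli.R`.

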