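# cstcontrol

Optimal-feedback-control simulation and control-strategy inference for the
Critical Stability Task (CST).

## The problem

In the CST a subject balances an unstable virtual system: lateral hand
position `p` drives a cursor `x` on a screen through the first-order dynamics

    dx/dt = lambda * (x + p),        -c <= x <= c

where `lambda > 0` sets the instability (task difficulty) and `c` is the
workspace half-width (10 cm). A trial succeeds if the cursor stays inside the
workspace for 6 s. The task is redundant: one can succeed by keeping the
cursor *at the center* (Position Control) or merely by keeping it *still*
anywhere on the screen (Velocity Control). Which objective a subject — human
or monkey — is pursuing cannot be observed directly; this package infers it
from movement kinematics alone.

`cstcontrol` implements the generative model end to end:

* **Plant.** A five-state linear system `[x, xdot, p, pdot, F]`: the hand is
  a 1 kg point mass driven by a muscle-like first-order filter
  (`tau * dF/dt = -F + u`, `d2p/dt2 = F/M`, `tau = 0.06 s`), coupled to the
  cursor dynamics above. Discretized by forward Euler at `dt = 10 ms`
  (`Ad = I + dt A`, `Bd = dt B`), with a 50 ms sensory delay represented by
  state augmentation.
* **Stochastic optimal control.** Finite-horizon LQG gains for the cost
  `J = sum_t x' Q x + u' U u` with signal-dependent motor noise
  (`u -> (1 + 1.5 eps) u`, `eps ~ N(0,1)`), additive motor noise
  `N(0, 0.4 Bd Bd')`, and additive sensory noise. Position Control sets
  `Q = diag(q, 0, 0, 0, 0)`; Velocity Control sets `Q = diag(0, v, 0, 0, 0)`.
* **Simulator.** Seeded, vectorized trial generation over the difficulty grid
  `lambda = 1.5, 1.7, ..., 7` with post-hoc success evaluation.
* **Behavioural metrics.** Per-trial hand-cursor peak cross-correlation and
  lag, hand/cursor RMS ratio, state-space summaries, lambda-binned success
  rates, and a psychometric fit
  `% success = 100 (1 - Phi((lambda - lambda_c) / sigma))` giving the
  critical instability `lambda_c`.
* **Strategy classifier.** A linear-kernel SVM with Platt-style posterior
  calibration on the per-trial `(RMS cursor position, RMS cursor velocity)`
  features, trained purely on simulated trials; posteriors >= 95 % label a
  trial Position Control, < 5 % Velocity Control, anything between Uncertain.

## Worked example

```r
library(cstcontrol)

# simulate 60 trials per difficulty under each objective (28 levels)
cache <- new.env(parent = emptyenv())
pos <- run_batch("position", n_per_lam = 60, base_seed = 11, cache = cache)
vel <- run_batch("velocity", n_per_lam = 60, base_seed = 22, cache = cache)

fp <- trial_features(pos)
fit <- fit_psychometric(bin_success_rate(fp))
fit
#> Psychometric fit: lambda_c = 5.391, sigma = 0.753 (19 bins, rss = 142)

# Velocity Control lets the cursor drift: mean position and mean velocity
# correlate across trials, and the RMS-space slope is shallow
fv <- trial_features(vel)
fitv <- fit_psychometric(bin_success_rate(fv))
meanstate_correlation(fp, lam_max = fit$lam_c)$r    #> 0.162
meanstate_correlation(fv, lam_max = fitv$lam_c)$r   #> 0.769
rms_slope(fp, lam_max = fit$lam_c)$slope            #> 2.15
rms_slope(fv, lam_max = fitv$lam_c)$slope           #> 0.372

# infer the objective of individual trials
model <- train_classifier(dplyr::bind_rows(
  dplyr::filter(fp, success, lam <= fit$lam_c),
  dplyr::filter(fv, success, lam <= fitv$lam_c)), seed = 1)
classify_trials(model, fp[1:3, ])[, c("trial_id", "p_pos", "label")]
#> # A tibble: 3 x 3
#>   trial_id               p_pos label
#>   <chr>                  <dbl> <chr>
#> 1 position_lam1.50_00001 0.216 uncertain
#> 2 position_lam1.50_00002 0.583 uncertain
#> 3 position_lam1.50_00003 0.752 uncertain
```

Easy trials barely move the cursor, so single easy trials are often
`uncertain` — the strategy signal lives in how a subject handles difficulty.
Averaging `p_pos` over a subject's trials (`subject_probability()`) gives the
per-individual measure of control objective.

`lambda_c` is where the fitted success curve crosses 50 %. The mean-state
correlation and RMS-space slope separate the two objectives: drift under
Velocity Control produces the large correlation, while tight position
regulation under Position Control produces the steep RMS-space slope. The
posterior `p_pos` is the calibrated probability that a trial was generated
under Position Control.

The full pipeline — training pools, psychometric fits, classifier, held-out
confusion rates — is one call:

```r
report <- cst_reproduce(cst_config(list(seed = 1)))
report$confusion
```

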