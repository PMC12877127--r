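# dynstates

Time-varying functional network connectivity (FNC) states for fMRI
component time-series: estimation, task modulation, and behavioural
association.

## The problem

Functional connectivity between brain networks is not static over a
scanning session. A now-standard way to quantify its dynamics is to slide
a tapered window along the component time-courses of an ICA decomposition,
estimate a regularized whole-brain connectivity matrix per window, and
cluster the windowed matrices into a small number of reoccurring **FNC
states**. How often each state occurs, how long subjects dwell in it, and
how its occurrence tracks task events then become interpretable,
behaviour-relevant quantities. `dynstates` implements that whole analysis
as a tested, reusable R package for researchers working with
component-level fMRI data (or any multivariate time-series with comparable
structure), together with a synthetic cohort generator that plants known
covariance states so every stage can be validated against ground truth.

## The model at a glance

* **Windowed connectivity.** For window length w (TRs), taper
  `rect(w) * N(0, sigma = 3 TR)`, the taper-weighted covariance of each
  w-TR segment is correlation-scaled and regularized by the graphical
  lasso: `max_Theta log det Theta - tr(R Theta) - lambda ||Theta||_1`;
  the correlation form of `Theta^{-1}` is the window's FNC profile, one
  per start TR (`W = T - w` windows).
* **States.** Two-stage k-means (cityblock distance by default):
  150-restart clustering of high-variance "exemplar" windows, then a
  single pass over all windows from the exemplar centroids. k via the
  elbow of a cluster validity index.
* **Graph structure.** Signed modularity
  `Q = Q+ - s-/(s+ + s-) Q-` by Louvain, and sign-stratified
  participation coefficients, normalized against degree-preserving
  randomized networks.
* **Task coupling.** Condition boxcars convolved with the canonical
  double-gamma HRF, correlated with group state occurrence; permutation
  nulls over subjects' label sequences (circular-shift surrogate for
  autocorrelated dynamics); Pearson–Filon z for condition contrasts;
  partial correlations with one-sample t at the individual level.
* **Behaviour.** Per-state mean connectivity of the top task-modulated
  pairs (time-varying) versus the full-session mean (static), compared by
  OLS R²/log-likelihood and logistic Nagelkerke pseudo-R²; sparse PLS with
  a multiple-holdout permutation frame for dwell-time/behaviour batteries.

See the vignette (`vignettes/dynamic-states.Rmd`) for the full methods
account, parameter defaults, and design decisions.

## Worked example

Simulate a task-coupled cohort, estimate windowed FNC, fit four states,
and test task modulation:

```r
library(dynstates)

cfg <- synthetic_config(n_subjects = 20, seed = 1)      # 20 x 200 TR, 4 states
des <- block_design(conditions = "task", total_s = 440)
coh <- simulate_cohort(cfg, des, seed = 1)

wfnc  <- lapply(coh$subjects, function(s)
  compute_windowed_fnc(s$ts, w = 8, sigma = 3, lambda = 0.1))
model <- fit_states(wfnc, k = 4, n_replicates = 50, seed = 1)
model
#> <state_model> k = 4 (cityblock metric), 20 subjects, inertia 1.706e+05

# recovered centroids vs the planted ones; perm[s] is the fitted label
# matched to planted state s
perm <- match_states(coh$truth$centroids, model$centroids)
perm
#> [1] 2 4 1 3
round(attr(perm, "r"), 3)
#> [1] 0.951 0.980 0.994 0.993

reg <- convolve_conditions(des, tr = 2.2, n_tr = 200, w = 8)
mod <- group_modulation(model, reg, n_perm = 1000, seed = 1,
                        null_method = "circular")
mod$table
#>   state condition          r           p     q_value significant
#> 1     1      task -0.4467468 0.001998002 0.003996004        TRUE
#> 2     2      task  0.6112562 0.000999001 0.003996004        TRUE
#> 3     3      task -0.3788578 0.005994006 0.005994006        TRUE
#> 4     4      task -0.4705612 0.002997003 0.003996004        TRUE
```

The matched centroid correlations (0.95–0.99) say the clustering recovered
all four planted connectivity states. In the modulation table the engaged
integrated state — planted state 1, i.e. fitted state `perm[1] = 2` —
rises with the stimulus (r = 0.61) while the segregated states are
suppressed (negative r), all surviving FDR: the generative task coupling
read back out of the estimated states.

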