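---
title: "Time-varying FNC states: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-varying FNC states: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`dynstates` implements a complete time-varying functional network
connectivity (FNC) analysis for fMRI component time-series: tapered
sliding-window connectivity with graphical-lasso regularization, k-means
extraction of reoccurring whole-brain connectivity states, signed-network
graph metrics, task-event coupling with permutation inference, selection of
task-specific regional connections, and the comparison of time-varying
against static connectivity in explaining behaviour. This vignette explains
the models behind each stage, the parameters that matter, the numerical
choices, and what the synthetic validation studies do and do not establish.

## The estimation pipeline

The pipeline starts from per-subject component time-series (a T x C matrix
with repetition time TR, here 2.2 s by default), as produced by a group ICA
decomposition; spatial ICA itself is out of scope.

**Post-processing** (`preprocess()`) applies the standard four steps in
fixed order: removal of linear, quadratic and cubic trends; regression of
six motion parameters (plus, for task sessions, the HRF-convolved task
design, so task-evoked co-activation does not inflate connectivity);
despiking; and a zero-phase 5th-order Butterworth low-pass at 0.18 Hz.
Two details are worth stating precisely:

* the nuisance design is augmented with the detrending polynomial basis, so
  the motion projection cannot reintroduce trend components; with that
  augmentation the chain is idempotent (re-running it changes the output by
  less than 1e-3 in relative norm on band-limited signals);
* despiking flags samples deviating from a 5-TR running median by more than
  3.5 robust SDs of the column (1.4826 x MAD) and replaces them by linear
  interpolation between the nearest retained neighbours, clamping at the
  series ends. The MAD of the raw column rather than of the running-median
  deviations is used: on smooth signals most samples equal their running
  median, so the deviation MAD degenerates to zero.

**Windowed FNC** (`compute_windowed_fnc()`) slides a tapered window —
a w-TR rectangle convolved with a Gaussian of sigma = 3 TR, truncated at
±4 sigma and renormalized to peak 1 — forward one TR at a time, giving
W = T − w windows. Within each window a taper-weighted covariance is formed
(weighted means and weighted cross-products), correlation-scaled, and
regularized by the graphical lasso: an L1 penalty `lambda` on the
off-diagonal precision entries, solved by block coordinate descent
(`src/glasso.cpp`, convergence 1e-4, max 500 sweeps, one lambda-doubling
retry). The correlation form of the inverse precision is vectorized in a
fixed row-major upper-triangle pair order shared by every module. The
default `lambda = 0.1` is stable for w = 8 and up to ~61 components;
`lambda = 0` returns the unpenalized weighted correlation. Window length
8 TR (17.6 s) suits block designs; 4 TR (8.8 s) short-block designs; both
are supported along with 16 and 32 TR for robustness checks. Each window is
timestamped at its centre TR (start + floor((w−1)/2)) for task alignment.

**States** (`fit_states()`) are extracted by two-stage k-means. Stage one
clusters only the subject exemplars — windows at strict local maxima of the
across-pair connectivity variance (plateaus contribute their first index;
subjects with monotone variance contribute none, with a warning) — using
150 seeded random restarts, keeping the lowest-inertia solution. Stage two
runs a single pass over all windows initialized at the stage-one centroids.
The default distance is cityblock (L1, median centroid update), the
convention of reference dFNC pipelines; euclidean and correlation
(euclidean on row-standardized profiles) are available. Empty clusters are
re-seeded at the point farthest from its centroid. The number of states is
chosen by the elbow criterion on the cluster validity index
CVI(k) = mean within-cluster distance / mean between-centroid distance,
taking the k of maximum second-order forward difference and flagging a
"weak elbow" when the maximal curvature is under 10% of the CVI range.

From the assignments, `group_occurrence()` gives the proportion of subjects
in each state per window (columns sum to 1); `dwell_and_fraction()` gives
mean consecutive-run lengths (in windows, with seconds alongside) and
fraction times. A state never visited has an undefined (NA) dwell time
rather than zero, so downstream regressions must impute explicitly — the
behavioural predictors impute by the sample mean and log the count.
`centroid_similarity_test()` matches states across sessions greedily by
centroid correlation (ties to the lower index) and contrasts same-state
versus different-state centroid correlations with a pooled two-sample t
(k = 4 states and S = 4 sessions give 24 same-state and 96 different-state
pairs, hence 118 degrees of freedom).

**Graph metrics** (`graph_metrics()`) treat each centroid as a signed
weighted network. Modularity uses the asymmetric signed quality
Q = Q⁺ − s⁻/(s⁺+s⁻) · Q⁻, where Q± are the Newman modularities of the
positive/negative layers normalized by their own total weight — the
dominant convention for functional brain networks, optimized by a greedy
Louvain with 20 seeded restarts. Participation coefficients are computed
per sign layer (PC_i = 1 − Σ_m (s_im/s_i)², zero-strength nodes contribute
0) and node-averaged. Both are normalized by their mean over 100 randomized
networks. Because FNC matrices are dense, pure degree-preserving rewiring
is near-the-identity; the null therefore combines admissible edge swaps
(rejecting collisions so the sign layers stay disjoint) with a permutation
of each layer's weight multiset, conserving both layers' degree sequences
exactly. Across-state comparisons use one-way ANOVA with sessions as
observations (F(3, 12) at k = S = 4) plus BH-corrected pairwise t-tests.

**Task modulation** (`group_modulation()`, `individual_modulation()`)
builds condition regressors by convolving stimulus boxcars with the
canonical double-gamma HRF (response gamma shape 6, undershoot shape 16,
ratio 1/6, 32 s support, peak-normalized) and sampling at window centres.
Group-level coupling is the Pearson correlation between a state's group
occurrence and each regressor, with a permutation null over subjects'
label sequences and BH-FDR over states x conditions. Two surrogates are
provided and the choice matters:

* `"shuffle"` permutes each subject's window labels. It matches the
  literal description of shuffling state-label order, but destroys the
  temporal autocorrelation of state occupancy: with sticky dynamics (mean
  dwell near 10 windows) the measured false-positive rate is several times
  the nominal level (`study_modulation_null(null_method = "shuffle")`
  measures it directly, and the test-suite asserts it). It remains the
  default for fidelity, but should not be used for inference on
  autocorrelated sequences.
* `"circular"` applies an independent random circular shift per subject,
  preserving each subject's run-length structure. This surrogate is
  calibrated (empirical alpha matches the nominal level in the null study)
  and is what the validation studies use.

Condition contrasts of correlations sharing the occurrence series use the
Pearson–Filon z; the implementation follows the closed form and is checked
against a Monte-Carlo oracle. For designs that differ across subjects,
partial correlations between per-subject binary occupancy indicators and a
condition regressor (controlling the other conditions by the residual
method) are tested against zero with a one-sample t across subjects.
Dwell-time/performance associations use Spearman rank correlations
(performance distributions are typically non-normal), pairwise-complete,
skipping pairs with fewer than 10 complete observations.

**Regional FNC** (`contrast_t()`) correlates each pair's windowed FNC
trajectory with each condition regressor per subject, contrasts two
conditions by a one-sample t on the per-subject correlation differences
across all P pairs with BH-FDR, and selects the top-k (default 20) pairs by
|t|, ties broken by pair index (a `signed` flag restores literal
largest-positive selection). `cross_task_specificity()` reports those
pairs' t-statistics and FDR-significant fraction in other tasks' contrasts.

**Behaviour** (`compare_regressions()`, `logistic_status()`,
`spls_multiple_holdout()`): behavioural batteries are first filtered —
iteratively dropping the later member of any pair with pairwise-complete
|r| > 0.8, then items whose modal value covers more than 95% of
participants — and residualized on age, sex, site dummies, and mean
framewise displacement. For each subject the selected top-k pairs yield
k state-conditional mean connectivities (time-varying predictors) and one
full-session mean (static predictor). Per behaviour, three OLS models are
fitted (time-varying, static, full); model significance is the one-tailed
F-test of the full model against intercept-only, and R², adjusted R², and
log-likelihood are compared. Case–control status is modelled by logistic
regression with Nagelkerke pseudo-R² (scaled to [0, 1] like OLS R²;
McFadden would not be), falling back to a small ridge (1e-4) under
separation. The dwell-time/behaviour association uses one-component sparse
PLS — soft-thresholded power iteration with L1 constraints on unit-norm
weights, whose unconstrained limit is the leading singular pair of the
cross-covariance — inside a multiple-holdout frame: three seeded 80/20
train/test splits, an inner 80/20 validation grid search over five
log-spaced sparsity levels per view, and per-split significance from
permutations of the training-Y rows evaluated on the held-out test
correlation. The split with the highest test association is reported, as
is conventional, but note that per-split permutation p-values are the
calibrated quantity; "best of three" is a reporting convention with
selection optimism, not a valid combined test.

## The synthetic cohort generator

Every downstream stage is validated against cohorts with known ground
truth (`synthetic_config()`, `simulate_cohort()`). The generator emulates
the data structure the pipeline assumes:

* K = 4 planted covariance states over C = 20 components spanning the
  integration–segregation axis: state K has within-block correlation 0.6
  and between-block −0.3 over two contiguous equal blocks; state 1 is
  near-uniform (off-diagonals close to the pair-weighted mean, with a 20%
  trace of block structure so centroid correlations stay well defined);
  intermediate states carry strong amplitudes (0.6–1) on *interleaved*
  block partitions of state-specific granularity. The partitions matter:
  amplitude-only interpolation on a single partition makes every planted
  centroid perfectly correlated with every other (Pearson correlation is
  blind to scale and offset), so state identity would be unrecoverable by
  correlation matching; distinct partitions give mutually near-orthogonal
  centroids. Modularity is scale-invariant, so the modularity axis is
  spanned by the uniform-admixture ratio — essentially state 1 versus
  state K — not by amplitude. Eigenvalues are floored at 1e-3 to
  guarantee positive definiteness.
* Latent dynamics are a first-order sticky Markov chain (stay probability
  0.9) whose transition log-odds toward a designated engaged state
  (default: the integrated state 1) are boosted by the HRF-convolved
  stimulus amplitude — the same double-gamma kernel the estimation side
  uses, so hemodynamic lag is well specified against ground truth.
* Observations are zero-mean Gaussians with the current state's
  covariance, AR(1)-smoothed (phi = 0.3) in a variance-preserving
  parameterization; motion regressors are Gaussian random walks
  (innovation SD 0.02).
* Behaviours are linear in per-state mean dwell times (slopes
  0.3/−0.3/0.2/−0.2, noise SD 1). A second behavioural mode draws
  subject-level state-specific connectivity modifiers (SD
  `subject_conn_sd`) on a designated pair subset (the within-block-1
  pairs) and generates behaviour and a logistic diagnosis from them —
  ground truth for the time-varying vs static comparison.
* Defaults (60 subjects, T = 200 TRs at TR 2.2 s) are large enough to
  exercise every stage and small enough for minute-scale studies.

The generator does **not** emulate voxel-level fMRI, spatial maps, scanner
artefacts, physiological noise spectra, or subject-varying HRFs. Passing
the validation studies therefore establishes internal correctness of the
estimators under the stated generative assumptions — not robustness to
real-data violations of them.

## Validation studies and their problem sizes

The studies in `R/studies.R` are run both by the test-suite and by
`scripts/acceptance.R`; sizes were chosen so each completes in minutes on
one CPU:

* **State recovery** — 10 cohorts at the default conditions, windowed
  estimation (w = 8, lambda = 0.1), two-stage clustering with 30 restarts;
  the median matched centroid correlation against the planted profiles is
  the summary.
* **Modulation null calibration** — 100 label-only cohorts from the
  task-free chain, 500 circular-shift permutations each.
* **sPLS null calibration** — 200 datasets of chain dwell times against
  independent Gaussian batteries, 500 permutations per split; split-level
  p-values are uncorrelated, so the 600 of them put the Monte-Carlo SD of
  the rejection rate near 0.009.
* **Direction recovery** — one 30-subject task-coupled cohort through the
  full pipeline; the engaged state's occurrence–stimulus correlation must
  be positive and significant, with a negatively correlated counterpart.
* **Generative superiority** — 100 cohorts (60 subjects, 10 components,
  T = 150) with connectivity-generated behaviour (modifier SD 0.2,
  alternating effects +3/−3) and no task coupling, since engaged-state
  occupancy asymmetry would leak state-specific connectivity into the
  static mean and blur the contrast the study isolates. Windowed FNC uses
  lambda = 0: regularization is orthogonal to the regression comparison
  and the unpenalized estimator is cheaper at this scale.
* **Graphical-lasso support recovery** — 50 chain-graph datasets (5
  components, neighbour partial correlation 0.4, 200 samples, lambda =
  0.1). An edge is declared where the precision magnitude exceeds
  1.5 lambda: at this sample size the lasso leaves occasional spurious
  entries just above exact zero, an order of magnitude below the planted
  edges, so support is read at a floor tied to the penalty.
* **Exhaustive oracles** — on every test network with at most 8 nodes, the
  Louvain modularity must equal the maximum over all set partitions, and
  participation coefficients must match a double-loop evaluation of their
  definition.

## Numerical choices and degenerate inputs

* PD repair by eigenvalue flooring at 1e-3 (generator and per-subject
  modifier covariances).
* Graphical lasso: convergence 1e-4 on the mean absolute off-diagonal
  change, maximum 500 sweeps, one retry at doubled lambda, exact zeros
  propagated into the precision; lambda = 0 short-circuits to the sample
  correlation (the precision is then reported only when invertible).
* Taper: Gaussian truncated at ±4 sigma before convolution; sigma ~ 0
  recovers the rectangle exactly.
* k-means: deterministic given seed; empty clusters re-seeded at the
  globally farthest point, repeatedly if a re-seed empties another
  cluster; still-empty clusters keep their centroid.
* State matching: greedy maximum centroid Pearson correlation, ties to the
  lower index, with a cosine fallback where a profile is constant.
* Zero-phase filtering pads by odd reflection (30 samples) to suppress
  forward–backward edge transients; without padding the chain is not
  idempotent.
* Behavioural collinearity filter keeps the earlier column; the modal-value
  rule treats NAs as missing, not as a level.
* Missing dwell times are NA by construction; predictors impute by sample
  mean and record the count; subjects with a constant occupancy indicator
  are excluded from that state's individual-level test and counted.

## Known limitations

* The label-shuffle surrogate is anticonservative under temporal
  autocorrelation (measured, not hypothetical); use the circular-shift
  surrogate for inference.
* Best-of-three-splits sPLS reporting is optimistic; treat the reported
  split's p-value as descriptive and per-split p-values as the calibrated
  quantities.
* Dense FNC matrices leave little room for degree-preserving rewiring, so
  the randomization null is dominated by weight permutation; normalized
  metrics should be read accordingly.
* Correlation-metric clustering standardizes profiles row-wise and then
  uses euclidean updates (the common practical equivalent), which is not
  identical to recomputing correlation distances against unstandardized
  centroids.
* The elbow criterion is a heuristic; the weak-elbow flag should be taken
  seriously on data without clear cluster structure.
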