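---
title: "Methods: predicting Wingate power outputs from incremental CPET features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: predicting Wingate power outputs from incremental CPET features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aeropower)
```

## The problem

The Wingate anaerobic test (WAnT) — 30 s of all-out cycling against a brake
load of 0.075 of body mass — is the reference measure of anaerobic mechanical
power: peak power (PP, W), mean power (MP, W) and the fatigue index (percent
drop from maximal to minimal power). It is also brutally hard, which limits
its use outside athlete populations. A maximal incremental cardiopulmonary
exercise test (CPET), by contrast, is routine. `aeropower` implements a
pipeline that predicts WAnT outputs from breath-by-breath CPET recordings:

1. extract a canonical vector of 51 aerobic features per subject
   (`extract_features()`),
2. select a small linear predictor by greedy forward selection with
   stability voting over repeated random splits (`run_full_protocol()`),
3. interpret the features by clustering their Spearman correlation network
   with Newman modularity maximization (`cluster_network()`),
4. and, because the cohort that motivated this design is not available in
   machine-readable form, generate synthetic cohorts with known planted
   structure so every stage can be verified end-to-end
   (`simulate_cohort()`).

The final predictor has the form

$$\hat{y} = \alpha + \beta\,z(f_1) + \gamma\,z(f_2) + \delta\,z(f_3) + \dots$$

where $z(\cdot)$ denotes column standardization (mean 0, SD 1, sample SD with
the $n-1$ denominator). The package ships two published equations of exactly
this form — a 6-term PP equation (intercept 638.4 W) and a 4-term MP equation
(intercept 476.8 W) — as JSON fixtures (`published_equation()`).

## The synthetic cohort generator

The generator defines the study conditions; it is deliberately a *minimal*
statistical model, not a physiological one.

**Protocol.** Warm-up (default 120 s) at the starting speed, then treadmill
speed +1 km/h per minute. Once the modeled respiratory exchange ratio (RER =
VCO2/VO2) reaches 1.0, the grade rises by 2% — by default again at each later
minute boundary (`grade_mode = "per_minute"`), because a single one-shot
increment would make the maximal grade identical for every subject and
degenerate the grade-based features (`max_slope`, `max_slope_x_speed`, ...)
that the published equations use. The warm-up and starting speeds are
configurable defaults (5 km/h), not values taken from any study protocol,
which does not state them.

**Gas exchange.** VO2 rises linearly from a walking baseline (25% of
VO2max) to the subject's true VO2max over a per-subject ramp duration
(default 600 +- 60 s); the test terminates when modeled heart rate — linear
in %VO2max — reaches the subject's maximum, which coincides with the end of
the ramp. VCO2 follows a two-segment relation in VO2 with breakpoint at the
planted ventilatory anaerobic threshold (VAT, default 0.65 +- 0.05 of
VO2max): slope ~0.85 below, steeper above, calibrated so the RER at
exhaustion matches the subject's `rer_max` (~1.12). This makes the modeled
RER cross 1.0 exactly once. VE is proportional to VCO2 (scaled to the
subject's true maximal ventilation), so it inherits the above-VAT
steepening. Breaths arrive every 2 s with +-0.5 s uniform jitter;
channel noise is multiplicative Gaussian (default 2-5% per channel).

**Cohort anthropometrics** are sex-specific truncated normals (+-3 SD, with
physiologic floors) with the female/male means and SDs of the reference
cohort (e.g. VO2max 2585.9 +- 382.7 vs 4169.2 +- 605.8 ml/min; default mix
36:52 female:male).

**Outcomes.** One outcome (default PP) is *planted* as an exact linear
function of standardized features plus Gaussian noise, per a
`generative_spec()`; the true coefficients are returned for recovery
testing. `noise_sd = "r2"` calibrates the residual SD so the planted model
explains a chosen population $R^2$. The other outcomes are filled with
simple correlates (MP ~ 0.72 PP; fatigue ~ N(50, 12), truncated) so
manifests are complete. Per-subject Wingate power curves are reconstructed
to match (PP, MP, fatigue) where a two-segment decay geometry allows; the
planted values remain authoritative for analysis.

**What this does not emulate:** VO2 on-kinetics (slow component), breath-by-
breath autocorrelation, plateau behavior at exhaustion, day-to-day
variability, or any causal physiology linking aerobic features to anaerobic
power. Passing tests therefore demonstrate that the *algorithms* behave as
specified on data with the assumed statistical structure — not that the
prediction generalizes to real athletes. One consequence to keep in mind:
because all 51 features derive from a handful of latent subject parameters,
the simulated feature matrix is strongly collinear, which is realistic and
makes exact support recovery by any selector impossible in general (features
can substitute for one another); recovery tests therefore plant signals on
features with distinct latent drivers.

## Feature extraction

The registry (`feature_registry()`) holds exactly 51 features: 12 direct and
39 calculated. Published tables name ~44 of them; the remaining slots are
filled with the natural companions the text implies (maximal speed, grade,
RER and heart rate; minute-4 VO2 level and slope; minute-1 VE), and an alias
table (`feature_aliases()`) maps published spellings — including variants
like "slop VCO2 versus VE" — onto canonical names. "max RF" and "max RR" are
deliberately distinct: RF is the device-reported respiratory-frequency
channel, RR the rate recomputed from breath timestamps. Names whose exact
published formula exists only in supplementary material (`vo2_1_at_vat`,
`vo2_2_at_vat`, `vslope`, `predicted_vo2`, ...) carry provisional,
documented formulas and are flagged in the registry rather than guessed
silently.

Numerical choices:

- Maxima are taken on a centered rolling mean over 10 breaths (configurable);
  raw breath-by-breath maxima are noise-dominated.
- Minute-wise features use half-open windows $[60(k-1), 60k)$ s from the
  start of the incremental phase; warm-up breaths are excluded.
- Slope features are ordinary least-squares slopes (VCO2 on VE, VO2 on VE,
  VO2 on time within a minute), so doubling VE doubles `max_ve` and halves
  `slope_vco2_ve` — an equivariance the tests assert.
- Areas A and B are trapezoidal areas under VO2 as a function of VCO2 (both
  in l/min) below/above the VAT breakpoint; they share the breakpoint node,
  so A + B equals the total area exactly.
- Subjects whose VAT is unreliable get `NA` VAT features and are dropped
  from the feature matrix with a message; dropping is conservative and
  visible.

**V-slope VAT detection** (`detect_vat_vslope()`) fits two independent
least-squares lines to VCO2-vs-VO2 with an exhaustive breakpoint search
(prefix-sum implementation, >= 5 breaths per segment) and declares the
threshold unreliable when the two-segment fit improves the one-segment SSE
by < 5% (configurable), when the upper slope is not steeper than the lower,
or when the one-segment fit is already essentially exact. Tests verify
recovery of planted breakpoints to one grid point noiselessly and to < 5%
median error at 1% noise, against a naive `lm()`-per-split oracle.

## Greedy selection with stability voting

Subjects are split 40/30/30 into train/test/validation, stratified on
VO2max tertiles with largest-remainder rounding, so each tertile's subset
proportions deviate from the global fractions by at most one subject.

Forward selection (`greedy_select()`) starts from the intercept-only model
and at each step adds the candidate minimizing the training SSE (computed by
successive orthogonalization, which is algebraically identical to refitting
each candidate model). The test-set Spearman correlation is recorded per
step as a monitor only; it does not feed back into selection. Selection
stops when the best candidate's adjusted $R^2$,
$1 - (1 - R^2)(n-1)/(n-p-1)$, falls more than 2% below the current model's.
"2% smaller" is read as a *relative* drop (`adj_new < 0.98 * adj_cur`); the
absolute reading is available via `relative = FALSE`. Additional guards stop
on an essentially perfect fit, on exhausted degrees of freedom, and at a
configurable `max_features` cap (default 12 in the full protocol — roughly
double the largest model the stopping rule produces in practice — since the
relative-drop rule alone need not terminate at small model sizes).
Numerically collinear candidates are skipped; ties in training SSE resolve
to the lower registry index.

Because random splits change which features are chosen,
`stability_select()` re-splits the calibration pool (train + test, in their
4:3 ratio) `n_runs` times (default 1000), reruns the greedy selector, and
votes: the consensus set contains features selected in at least half the
runs (threshold configurable; the source procedure says only that the most
common features were kept), ordered by frequency with ties broken by mean
selection step. The consensus equation is then refit on the full calibration
pool by OLS and evaluated on the validation set: Spearman rank correlation
(average ranks on ties), RMSE, and percent error $100\,|\hat y - y|/y$
reported as mean +- SD, with non-positive observations excluded from percent
error. The outer loop (`run_full_protocol()`) repeats everything
(default 100 times) and reports per-repeat and aggregate metrics.

Standardization is fit on the calibration pool and *applied* to the
validation set, the leak-free default; `paper_faithful = TRUE` standardizes
the whole cohort before splitting, reproducing the source procedure's
(mildly leaky) order of operations. Fatigue is a supported outcome but not
part of default reports: its prediction was weak and non-significant in the
motivating study.

The `stage` filter reproduces the early-test variant: `"early_minutes"`
restricts candidates to the nine features computable from the first four
incremental minutes, `"full_test"` to whole-test features, and the default
`"all"` uses the complete registry (the full-duration model includes the
minute features — the published MP equation contains the minute-1 VO2
slope).

## The feature correlation network

`correlation_matrix()` computes the 51x51 Spearman matrix;
`build_network()` keeps the top 30% of the $\binom{51}{2}$ feature pairs by
$|\rho|$ as edges weighted $|\rho|$ (modularity assumes nonnegative
weights; a signed extension is out of scope). "30% of the most highly
correlated" is read as an *edge* threshold — the standard construction — with
ceiling rounding of the edge count and lexical tie-breaks at the cutoff for
determinism; all 51 nodes are retained, isolated or not.

Clustering maximizes Newman's modularity
$$Q = \frac{1}{4m}\sum_{ij}\left(A_{ij} - \frac{k_i k_j}{2m}\right)(S_iS_j + 1)$$
with strengths $k_i$ and total weight $m$, by iterative spectral bisection:
split by the sign of the leading eigenvector of the (generalized, for
subgroups) modularity matrix, then refine deterministically — first a sweep
over every prefix split of the eigenvector ordering, then the vertex-moving
fine-tuning stage that conventionally accompanies the leading-eigenvector
method (each node moved at most once per pass in best-gain order, keeping
the best intermediate state, repeated to convergence). Fine-tuning is
included because the bare sign split demonstrably falls short of the
exhaustive-best bisection on small graphs, and the package's acceptance
oracle requires >= 95% of it. Splits are accepted only when
$\Delta Q > 10^{-10}$; indivisibility is a result, not an error. Zero
eigenvector entries join the +1 side by convention. The accumulated
$\sum \Delta Q$ equals the modularity of the final partition to $10^{-9}$,
and both are checked against `igraph::modularity()` as an independent
oracle in the tests.

## Problem sizes used in the test suite

The package's own checks run at reduced but statistically meaningful sizes,
chosen once as part of the study conditions: cohorts of n = 88 (the
reference cohort size, 36 female / 52 male); greedy-recovery checks on
n = 200 with a planted 2-feature signal at SNR 10 over 100 noise replicates,
compared against exhaustive best-subset search; protocol-stability checks at
20 outer repeats x 50 stability runs against an 80 x 200 replication of the
same pipeline; bisection oracles on 20 seeded random graphs of 4-10 nodes
against full enumeration; and V-slope recovery over 100 seeded noise
replicates. The end-to-end demo (`run_pipeline()`) uses n = 88 with 10 outer
repeats x 50 stability runs and is byte-identical across reruns of the same
configuration.

## Known limitations

- The simulator's collinearity structure is cruder than real CPET data;
  absolute performance numbers on simulated cohorts say nothing about real
  validation correlations.
- Provisional registry formulas stand in for supplementary-material
  definitions and are flagged as such; swap them via the registry if the
  authoritative definitions become available.
- The greedy stopping rule's behavior depends strongly on the
  candidates-to-subjects ratio; with few candidates and many subjects it can
  run to the `max_features` guard rather than stopping naturally.
- No regularized or nonlinear models, no anthropometric predictors (by
  design), no signed-network modularity, and no alternative community
  detectors.
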