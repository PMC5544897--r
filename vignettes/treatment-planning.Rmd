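---
title: "Idiographic treatment planning from symptom time series: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Idiographic treatment planning from symptom time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idioplan)
```

## The problem

Cross-sectional diagnosis tells a clinician *which* symptoms a patient has,
but not which symptom to treat *first*. When a patient completes a short
symptom questionnaire several times a day for a few weeks (ecological
momentary assessment), the resulting multivariate time series carries two
kinds of structure that bear on that decision:

* **synchronous structure** — which symptoms covary at the same moment,
  summarized by a P-technique factor model (factor analysis across
  occasions within one person rather than across persons);
* **temporal structure** — which latent symptom dimensions drive themselves
  and each other over time, summarized by a vector autoregression (VAR) on
  the factor-score series.

`idioplan` combines both into a per-symptom *priority score*: symptoms that
are severe, that mark a dimension explaining much synchronous variance, and
that belong to a dimension with strong lagged influence, score high. The
package also provides process-monitoring statistics (dynamic complexity,
recurrence matrices, LOESS trend bands, weekly percent change) for use
during the subsequent therapy.

## The planning pipeline

Given a cleaned series of $T$ assessments on $I$ Likert-type items
(treated as continuous; items are z-scored for all fitting, so only the
correlation structure matters):

**Step 1 — exploratory P-factor analysis.** Maximum-likelihood factor
analysis of the item correlation matrix for $k = 2, 3, 4$ candidate
factors, each followed by direct oblimin rotation (quartimin criterion,
gradient projection), because latent dimensions of psychopathology are
expected to intercorrelate. Each candidate is gated on the Hu–Bentler
joint criteria, TLI $\ge .95$ and RMS $\le .08$; the smallest passing $k$
wins. Two guards matter in practice:

* *Sphericity prerequisite.* The TLI compares the model to the
  independence baseline; when the data are structureless the baseline
  itself fits ($\chi^2_0 \approx df_0$), the TLI denominator crosses zero
  and the index becomes numerically meaningless — on simulated pure noise
  it exceeds the cutoff in roughly half of replications. A candidate can
  therefore only pass when Bartlett's sphericity test rejects independence
  ($\alpha = .05$), the standard "is there anything to factor?" check.
  Structureless data then reliably returns `no_model`.
* *Rotation starts.* Gradient-projection rotation from the identity alone
  can stall: for perfectly balanced loading patterns the identity is a
  saddle point of the quartimin criterion. `rotate_oblimin()` runs a fixed
  set of eight deterministic oblique starts plus the identity and keeps
  the best solution; the caller's RNG state is untouched, so identical
  input always gives identical output.

The $\chi^2$ uses Bartlett's correction
$(T - 1 - (2I+5)/6 - 2k/3)\,F_{ML}$ in the exploratory stage, mirroring
the convention of the standard exploratory tools; the confirmatory stage
uses the plain $(T-1)\,F_{ML}$.

**Step 2 — confirmatory model.** Items with exploratory loadings
$|\lambda| > .30$ (strict) enter the confirmatory pattern on that factor;
items exceeding the cutoff nowhere are excluded. The confirmatory model
$\Sigma(\theta) = \Lambda\Phi\Lambda' + \Theta$ is estimated by ML
(quasi-Newton on the discrepancy, factor variances fixed at 1, factor
correlations free, residual variances bounded at 0.005 — the Heywood
floor, flagged when active; factor correlations are parameterized through
spherical coordinates of a Cholesky factor so $\Phi$ is a correlation
matrix by construction). The gate is TLI $\ge .95$ and SRMR $\le .08$,
with SRMR taken over all unique elements of the standardized residual
matrix including the diagonal. Cross-loading items are estimated freely on
every factor that includes them.

**Step 3 — factor scores and VAR.** Factor scores are the standardized
included-item data times a weighting matrix. The default weighting matrix
is the estimated confirmatory loading matrix itself (the reading most
consistent with the worked example this algebra reproduces); regression
(Thurstone) weights $\hat\Sigma^{-1}\Lambda\Phi$ are available via
`weights_type = "regression"`. Each factor-score equation is then
estimated by OLS on an intercept, a linear trend in the observation index,
and all factors at lags $1..p$. The lag order $p \in \{1..5\}$ minimizes
$AIC = T_{\rm eff}\log|\hat\Sigma_{\rm res}| + 2m$ on a common estimation
sample (the first `max_lag` rows are withheld for every candidate so the
criteria are comparable; additive constants are dropped consistently).
Ties break toward fewer lags. The trend regressor is the observation
index, not calendar time: observations are treated as equally spaced in
index order, and a warning is raised at read time when timestamp gaps
deviate more than 50% from the modal gap.

**Step 4 — factor scores (planning sense).** Two variance summaries are
multiplied per factor and normalized by the largest product:

* *within-time share*: $\sum_i \lambda_{ij}^2 / k^2$ from the confirmatory
  loadings. The procedure is described in words as "squared loadings
  divided by the number of factors and summed", but only the $k^2$ divisor
  reproduces the printed worked-example shares (34.27% and 47.27% from the
  published two-factor loading matrix; the single-$k$ divisor gives 68.6%
  and 94.6%). The literal reading stays available via `divisor = "k"`.
* *between-time share*: the incremental $R^2$ of the lagged block — the
  full-equation $R^2$ minus the $R^2$ of the intercept+trend-only
  regression on the same sample, clipped to $[0,1]$
  (`lagged_block_r2()`). This operationalizes "variance explained by the
  auto- and cross-regressive parameters" in a bounded, trend-adjusted way;
  a sum-of-squared-coefficients reading was rejected as unbounded. The
  exact computation behind the worked example's printed between-time
  values is not recoverable from printed material, so this definition is
  this package's documented choice.

**Step 5 — symptom scores.** Raw item means (scale units, computed after
cleaning) are normalized by the largest mean among modeled items; each
item's confirmatory loading is multiplied by its factor's Step-4 score,
summed over every factor the item loads on, multiplied by the normalized
mean, and rescaled so the top item scores exactly 100. Items excluded in
Step 2 are listed separately without a score. The whole pipeline is
deterministic and scale-invariant: multiplying all ratings (and bounds) by
a positive constant leaves every priority unchanged.

A failed gate at any stage returns `status = "no_model"` with the failed
gate named in the diagnostics; fewer than `min_measurements` (default 40)
assessments is an *error*, because "not enough data yet" and "no adequate
model exists" call for different clinical responses.

## Cleaning and scheduling

Missing responses are handled by a fixed, auditable policy: internal
per-item gaps up to `max_gap` (default 1) are linearly interpolated over
the observation index; rows still incomplete afterwards are dropped; a
`cleaning_report` tallies every action. Assessment schedules split the
patient's waking window into equal parts with wake and sleep as the first
and last assessments (a single daily assessment sits at the window
midpoint).

## Monitoring statistics

**Dynamic complexity** is a moving-window early-warning statistic,
$C = F \cdot D$ per window of width $m$ (default 7, typical range 5–7),
assigned causally to the window's last index. The concept — fluctuation
intensity times distribution of values — comes from the dynamic-systems
literature on critical instabilities; since no closed formula is printed
there, the definitions here are this package's own and both components are
returned so alternatives can be swapped in:

* $F$: the window's points of return (first point, last point, interior
  local extrema) cut it into segments; each segment contributes its
  absolute slope $|\Delta y|/\Delta t$, and the sum is divided by
  $R \cdot n_{\rm segments}$ with $R$ the theoretical scale range. Thus a
  constant window has $F = 0$, full-range alternation every step attains
  $F = 1$, and a monotone full-range ramp has $F = 1/(m-1)$.
* $D$: with $g_i$ the gaps of the sorted window values,
  $D = \max(0,\, 1 - \sum_i |g_i - R/(m-1)|/R)$ — 1 when the values cover
  the scale uniformly, 0 for a constant window.

Both components and hence $C$ lie in $[0,1]$; `rescale_complexity()` maps
$C$ affinely onto a raw-plot axis. **Recurrence matrices** are plain
(unthresholded) Euclidean distance matrices between assessment points.
**LOESS trend curves** use degree-1 local regression with the tricube
kernel (span 0.75 default) and a pointwise 95% t-interval from the local
fit variance. **Weekly change** is the signed percent change between
consecutive weekly outcome scores.

## The synthetic-patient generator

`simulate_patient()` draws the exact structure the pipeline assumes, with
the generating truth retained: a stable latent VAR($p$) with innovation
correlation $\Phi$ (stability enforced via the companion-matrix spectral
radius), optional linear trends, loadings mapping latents to items,
independent Gaussian observation noise, baseline item means, and
discretization by rounding to the Likert grid with clamping at the scale
bounds (simpler than thresholding a latent normal, and downstream fitting
treats responses as continuous anyway). Burn-in of 50 steps is discarded.
`inject_missing()` masks cells (or whole assessments) at a configurable
rate; the default 12% reflects the missing-data rates reported for daily
symptom questionnaires in inpatient and outpatient feasibility work
(roughly 10–13%).

Three presets define the regimes used throughout the tests: a
`"two-factor-dominant"` patient (oblique two-factor structure shaped like
the worked example — 3 + 6 items on a 0–8 scale, factor correlation .243,
one item loading on nothing — with factor 1 dominant in loadings,
autoregression, and item means, so its symptoms should top the priority
table), `"pure-noise"` (ten independent items; the planning run must end
in `no_model`), and `"three-factor"` (well-separated moderate structure
for factor-number selection). What the generator does *not* emulate:
ordinal measurement distortion beyond rounding, time-of-day cyclicity,
regime switches/phase transitions, and informative (non-random)
missingness. Passing recovery tests on these data therefore shows the
pipeline is correct under its own assumptions, not that real patients
satisfy them.

## Numerical choices and test scale

* Item standardization uses the sample SD; zero-variance items are dropped
  (exploratory stage) or yield all-zero scores (scoring stage) with
  warnings.
* ML convergence: the exploratory fit inherits the standard `factanal`
  optimizer with uniquenesses bounded at 0.005; the confirmatory fit uses
  BFGS with relative tolerance $10^{-14}$, which reproduces an exactly
  model-implied correlation matrix to $\chi^2 < 10^{-6}$.
* Normalization ties (two items or factors sharing the maximum) keep the
  first index for reporting; scores are unaffected.
* The serial dependence of P-technique data violates the independence
  assumption behind every ML $\chi^2$ used here; following the approach
  this pipeline automates, that is accepted and not corrected.
* Simulation-based validation uses $T = 500$ draws for parameter-recovery
  checks (50 replications for loading RMSE and VAR bias), $T = 120$
  synthetic patients for end-to-end runs (the intensive-assessment regime
  of roughly 100–120 observations in 4–6 weeks), and 20–25 seeds per
  selection/end-to-end property — sizes chosen so the full suite stays
  comfortably within a routine check while keeping binomial pass margins
  meaningful.

## Known limitations

* Factor-count candidates stop at 4 (configurable); no parallel analysis
  or polychoric factoring.
* The confirmatory estimator is plain ML — no robust or categorical
  (WLSMV) variants, modification indices, or multi-group support.
* The VAR offers no Granger tests, impulse responses, or structural
  identification; "between-time variance" is an incremental $R^2$, not a
  causal decomposition.
* Equal index spacing is assumed even across overnight gaps, as in the
  design this package automates.
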