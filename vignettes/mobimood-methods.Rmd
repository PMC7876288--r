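---
title: "Digital phenotyping of mood: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital phenotyping of mood: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mobimood)
```

## The problem

`mobimood` implements a complete digital-phenotyping analysis for a
30-day observational design: participants carry a smartphone that samples
GPS continuously and logs screen events, wear a ring-style device that
reports daily activity, sleep and heart-rate-variability summaries, answer
three brief mood prompts per day, and complete the DASS-21 questionnaire
at enrollment (T0), the study midpoint (day 16, T1) and the end (day 31,
T2). The scientific question is whether passively sensed behaviour —
mobility, phone usage, activity, sleep, heart-rate variability — and
momentary mood predict subsequent depression, anxiety and stress severity.

Because participant-level sensor data of this kind cannot be shared, the
package ships a synthetic cohort generator whose outputs have the
statistical structure the analysis assumes, with *planted* standardized
effects. Every pipeline stage is exercised and validated against that
generator; what the tests demonstrate is therefore correctness of the
machinery and calibration of the estimators under the assumed data model,
not any empirical claim about real cohorts.

## GPS preprocessing and the five mobility features

Raw GPS fixes arrive with UNIX-millisecond timestamps, WGS84 coordinates
and a reported accuracy. Preprocessing follows four rules:

1. **Localization.** Each timestamp is resolved to local civil time with
   the most recent timezone record at or before it, and local dates map to
   per-participant study days 1–30.
2. **Cleaning.** Exact duplicates are dropped; fixes at exactly (0, 0) —
   a known sensing failure mode — are dropped; fixes with accuracy
   strictly worse than the 80th percentile of *all* participants' pooled
   accuracies (type-7 percentile) are dropped. Every removal is counted in
   a ledger by reason. Cleaning is idempotent.
3. **State labeling.** The movement speed at each fix is the time
   derivative of position (haversine distance to the previous fix over
   elapsed time). Speeds strictly above 1 km/h mark *transition*;
   otherwise *stationary*. Sampling gaps longer than 15 minutes split the
   trace into segments: no dwell time or travel distance is credited
   across a gap, though the derivative itself is still defined over the
   gap interval (this is what the threshold rule requires for sparse
   traces). Each stationary fix is credited dwell equal to the time to
   the next fix, capped at the gap threshold.
4. **Stay-point clustering.** K-means runs on the stationary fixes
   (projected to a local planar frame) for K = 1, 2, …, selecting the
   smallest K at which every fix lies within 500 m of its centroid,
   capped at K = 20. Ten restarts per K; ties resolve to the lowest
   within-cluster sum of squares. The 500 m threshold and the cap are
   configuration parameters; the K-selection rule itself is a design
   choice, since a fixed K is not meaningful across participants with
   different movement ranges.

The five mobility features over a window of study days:

* **Total distance** (km): sum of consecutive within-segment hop
  distances.
* **Location variance**: $\log(\mathrm{var}(\text{lat}) +
  \mathrm{var}(\text{lon}))$ over stationary fixes, in raw squared
  degrees. Undefined below 3 stationary fixes or at zero variance (we
  return a reason-coded missing value, not $-\infty$).
* **Location entropy** (nats): $H = -\sum_i p_i \log p_i$ where $p_i$ is
  the share of stationary *dwell time* spent in stay cluster $i$.
* **Normalized entropy**: $H / \log N$ over the $N$ clusters with dwell,
  defined as 0 when $N = 1$ (the $0/0$ convention: all time in one
  cluster carries no locational variability).
* **Homestay**: dwell seconds in the home cluster divided by 86,400 ×
  (days in window), clipped to [0, 1]. The home cluster holds the most
  stationary fixes with local time in [00:00, 06:00). A tracked-time
  denominator is available behind a flag, but the 24 h denominator is the
  default because the instrument defines homestay against the full day.

Two weighting choices deserve note, since irregular sampling makes them
non-equivalent: entropy shares are *dwell-time* weighted (robust to
sampling-rate variation), while home-cluster identification counts
*fixes* (the literal "most coordinates at night" rule). Natural
logarithms are used throughout; normalized entropy is base-invariant.
Clustering is fitted per assessment window, because features are paired
with the assessment closing that window.

## Phone usage, wearable summaries, momentary mood

A usage session spans unlock → lock. Missing lock events close the open
session at the next unlock; an unmatched trailing unlock closes at the
last event; sessions are capped at 12 h (guarding against lost locks);
sessions crossing local midnight are split at midnight so daily
attribution conserves total time. *Usage frequency* is the raw count of
unlock events per local day — deliberately independent of sessionization
edge cases — and *usage duration* is the summed session minutes
attributed to the day.

Wearable records enter as daily summaries (steps, 24-h MET average, TST,
SOL, WASO, TIB in minutes, nightly RMSSD in ms) and are range-validated:
non-negativity, TST ≤ TIB, SOL + WASO ≤ TIB − TST + 30 min, RMSSD ≤ 500
ms. Violations null the offending field with a flag; validation never
rejects a whole record. Momentary mood (valence and arousal, 9-point
integer scales from −4 to 4) aggregates to daily unweighted means;
default-zero responses are retained unless explicitly dropped, since an
untouched default is not distinguishable from a genuine neutral report.

## DASS-21 scoring

Each of depression, anxiety and stress is the raw sum of its seven item
ratings (0–3), giving the 0–21 range; there is no DASS-42-style doubling.
Severity categories use the standard cut-offs (depression: normal 0–4,
mild 5–6, moderate 7–10, severe 11–13, extremely severe 14+; anxiety:
0–3 / 4–5 / 6–7 / 8–9 / 10+; stress: 0–7 / 8–9 / 10–12 / 13–16 / 17+).
The test suite asserts by enumeration that the bands are exhaustive,
non-overlapping and monotone.

## Windowing and standardization

Daily features pool into two 15-day windows — days 1–15 pair with T1 and
days 16–30 with T2 — by the mean over defined daily values, requiring at
least 5 defined days (windows built from one or two days would be noise;
the threshold is configurable). Day 16, an assessment day, belongs to
window 2 only. Predictors *and* outcomes are z-standardized by their
grand mean and SD over all observed participant-window rows. Grand (not
within-person) standardization of both sides is what makes the fitted
intercepts exactly zero with a nonzero standard error, and it puts the
fixed-effect slopes on the standardized scale on which effect sizes are
reported.

## The inference layer

**Correlations.** Spearman's rho (Pearson correlation of mid-ranks,
average ties; t-approximation p values) between each pooled feature and
each outcome. Holm's step-down adjustment runs separately within each
feature-cluster × outcome family (GPS, usage, wearable, EMA), a
deliberately local correction for an exploratory design.

**Intraclass correlation.** ICC(1,1) from one-way random-effects ANOVA
variance components with the unbalanced-design group size, floored at 0;
values above ~0.05 justify the multilevel structure.

**Multilevel models.** Assessment windows (level 1) nest in participants
(level 2). The model for outcome $y_{ij}$ of participant $j$ in window
$i$ with standardized predictors $x_{ij}$:

$$y_{ij} = \beta_0 + \beta^\top x_{ij} + u_{0j} + u_j^\top x_{ij} +
\varepsilon_{ij},$$

with independent random intercepts $u_{0j}$ and random slopes $u_j$
(uncorrelated random effects: with at most two observations per
participant a full covariance is not identifiable). Estimation is maximum
likelihood via `lme4`, as nested fixed-effect structures are compared by
likelihood ratio. If a slope variance lands on the zero boundary the
model refits with a random intercept only and flags the fact.
Fixed-effect degrees of freedom use the Satterthwaite approximation
(`lmerTest`); per-imputation fits destined for Rubin pooling may skip it,
since pooling substitutes Barnard–Rubin degrees of freedom.

**Missing data.** Missingness is assumed missing-at-random and handled by
multilevel multiple imputation: chained equations over the incomplete
columns, 20 imputations, 15 iterations per chain, with per-iteration
chain statistics retained for convergence inspection. Each column's
imputation model is a linear regression on the *participant means* and
*within-person deviations* of the other registered variables — a
two-level predictor set carrying both person-level and occasion-level
information. Imputation is predictive mean matching, type 1: least-squares
coefficients for the observed cases, a Bayesian coefficient draw for the
missing cases, and each missing entry copies the observed value of one
donor drawn from the 5 closest predicted values. PMM keeps imputations on
the support of the observed data. The auxiliary set is configurable; by
default every numeric column participates, which is what lets variables
related to non-response inform the imputation.

**Pooling.** Estimates pool by Rubin's rules (total variance
$W + (1 + 1/m)B$) with Barnard–Rubin degrees of freedom. Nested models
compare by the pooled likelihood-ratio statistic $D_3$: the mean LR
statistic at per-dataset estimates, the mean LR statistic re-evaluated at
the pooled fixed effects (variance components re-optimized via an offset
refit), and the relative-increase-in-variance correction combine into an
F statistic. With a single complete dataset the statistic reduces exactly
to the classical chi-square test. Type-I error of this test is verified
by simulation at the 5% level using matched random structures in the null
and alternative — comparing models whose random structures differ would
conflate the fixed-effect contrast with a variance parameter and inflate
the size.

**Model ladder.** Each of the 16 features is screened in its own
single-predictor model; features with pooled two-sided p < 0.05 advance.
The ladder then fits: intercept-only baseline; EMA model; GPS model;
extended digital-phenotyping model (GPS + wearable); combined model (EMA
+ GPS + wearable), comparing stages by pooled LRT. Empty stages are
reported as "No predictors identified", never silently skipped. Usage
features are screened and reported but have no dedicated ladder stage.

## The synthetic cohort generator

The generator is first-class, tested code with two layers.

The *window-level* layer (`simulate_model_table()`) draws standardized
features $x_{ijf} = a_{jf} + e_{ijf}$ (person SD 0.6, window SD 0.8, unit
total variance; optionally exchangeably correlated through a common
factor) and builds each outcome from the planted linear combination of
the noiseless features plus a person intercept, person-specific slope
deviations (SD 0.1) and residual noise, with the residual split 40/60
between person and window level and scaled so the outcome has unit total
variance — this keeps planted slopes on exactly the standardized scale
the analysis estimates. Missing-at-random masking is a deterministic
logistic function (slope 1.5) of the observed usage-frequency covariate,
with the intercept solved numerically so the expected rates equal the
registered 10% (assessments) and 9.1% (sensing) values; the driver itself
is never masked. Under correlated features, the reference truth for a
single-predictor fit is the implied marginal slope $(\Sigma\beta)_f$,
available from `implied_slopes()`.

The *raw-stream* layer (`simulate_cohort()`) emits AWARE-style GPS
traces (home anchor plus secondary anchors, visit schedules shaped by the
latent mobility values, Gaussian jitter, log-normal accuracies, injected
duplicate/zero/outlier artifacts), screen event streams matching the
latent usage values, wearable daily summaries constructed to satisfy the
validation invariants, three mood prompts per day, and DASS-21 item
responses whose subscale sums equal the planted subscore mapped to the
raw scale (means/SDs 3.78/3.48, 2.73/2.68, 6.00/3.82 for depression,
anxiety, stress) and distributed over the seven items by
largest-remainder rounding — only the sums matter downstream. Movement
profiles are *plausible, not calibrated*: real cohorts' movement regimes
(especially under pandemic-era restrictions) are unknown, so GPS-planted
effects are attenuated by extraction noise in a way wearable/EMA-planted
effects (passed through as daily summaries) are not. Exact
slope-recovery claims therefore attach to the window-level layer; the
raw-stream layer is validated for structural fidelity (planted path
lengths, artifact counts, dwell shares, determinism).

What the generator does **not** emulate: autocorrelated day-to-day
dynamics beyond the person/window decomposition, measurement-error
heteroscedasticity across devices, informative (non-MAR) dropout, and
real movement topology. Passing tests show estimator correctness under
the assumed model, not robustness to those violations.

## Numerical and design choices

* Haversine distances on a sphere of radius 6371.0088 km; sub-0.5% error
  at city scale.
* Strict inequalities at the 1 km/h and accuracy-percentile boundaries;
  half-open night window [00:00, 06:00).
* Type-7 (linear interpolation) percentiles.
* Mixed models: ML, `lme4` defaults with singular-fit checks disabled in
  favour of an explicit boundary-refit-and-flag policy.
* Every stochastic operation takes an explicit seed; pipeline stages
  derive per-operation seeds from one root seed via a string-hash mix, so
  one integer reproduces a run byte-for-byte.
* Undefined features are NA with machine-readable reason codes and never
  poison other features.

## Problem sizes used in validation

The simulation-based checks run at: parameter recovery, 200 participants
× 8 windows × 200 replicates (slopes −0.21 and +0.25, the magnitudes the
design targets); LRT size, 400 null replicates at 100 participants × 2
windows; imputation benefit, 100 replicates at 100 participants × 2
windows with m = 20 and 15 iterations; end-to-end, a 10-participant
30-day cohort (~400k GPS fixes) with m = 5. These sizes give Monte Carlo
error comfortably inside the asserted tolerances while keeping the suite
fast enough to run routinely.

## Known limitations

* The two-level PMM uses participant-mean/deviation regressors rather
  than a full random-effects imputation model; with two observations per
  participant the difference is minor, but with long panels a dedicated
  multilevel imputation engine would be preferable.
* With two windows per participant, random slopes are not identifiable
  from the data alone; the boundary-fallback policy makes this explicit
  rather than hiding it.
* The D3 offset refit re-optimizes variance components at pooled fixed
  effects; in tiny samples with boundary variance estimates the
  relative-increase-in-variance term can be noisy (it is floored at 0).
* Homestay uses the full-day denominator, so low-coverage days bias it
  downward; the tracked-time alternative flag exists for
  sensitivity analyses.
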