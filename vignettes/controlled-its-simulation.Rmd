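---
title: "Evaluating control-group formulations in interrupted time series: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating control-group formulations in interrupted time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(citsim)
```

## The estimation problem

A controlled interrupted time series (CITS) design observes an outcome for
an exposed unit and an unexposed control at equally spaced times, with an
intervention starting at a known point. The intervention effect is a level
change τ. The statistical question `citsim` studies is not *whether* to use
a control but *how*: the same information can enter a segmented regression
as a second panel unit (CITS or DiD), as a differenced single series, or as
a covariate — and these formulations degrade very differently when the
assumptions tying the two series together fail.

## The data-generating process

$$Y_{it} = X_{it}\beta_1 + Post_t\,\beta_2 + \tau\,(D_i \times Post_t)
  + \lambda_t \mu_i + \varepsilon_{it}$$

with the intervention at the series midpoint (`Post = 1` for `t > n/2`,
1-based). The `Post` main effect is a *common confounder*: it moves both
series after the interruption, so designs that exploit the control can
separate it from τ while uncontrolled designs estimate τ + β2.

Tunable parameters, defaults and rationale:

| parameter | default | meaning / why this value |
|---|---|---|
| τ | 2 | intervention level change (outcome units) |
| β2 | 1 | post-period common confounder; calibrated so misspecified designs show \|bias\| ≈ 1 ≈ 50% of τ, the designed misspecification penalty |
| β1, X | 0.5, X ~ N(1, 0.05²) | observed covariate, weakly informative; drawn independently per group and time so differenced covariates retain signal |
| μ_treat, μ_ctrl | 1, 0.5 | unobserved group levels; intervention series sits above the control |
| σ (homoscedastic) | 0.1 | small relative to τ: the base case is a clean DiD world |
| ρ | 0.7 | AR(1) coefficient for the autocorrelated error regime |
| δ | 0.0775 | per-step linear trend divergence; calibrated (see below) |
| irregular amplitude | 4 | peak of the control-only smooth trend profile; ±4·μ_ctrl = ±2 outcome units ≈ τ |
| n | 24–312 | ten series lengths, fortnightly-data scale |

Heteroscedastic regimes set the error SD of the designated high-variance
group to half the absolute systematic mean level, and the other group to
half of that: variance grows with the level of the series and the high
group's SD is twice the low group's at matched levels. (The alternative
reading — squaring the mean level — would give post-period SDs near 20 on
a series of level 4.5, which is inconsistent with a usable outcome series;
we document and adopt the divide-by-two reading.) SDs are floored at 1e-6.

AR(1) errors are initialised from the stationary distribution
N(0, σ²/(1−ρ²)), so no burn-in is needed; the test suite checks the result
is indistinguishable from a 100-step burn-in oracle.

### Calibration of δ

The paper-gap here is that the divergence magnitude of the unparallel
regime is not published. We calibrate it through the pre-trend test itself:
δ is chosen by bisection so that a two-sided t-test (α = 0.05) of the
pre-period difference-on-time slope rejects in 80% of homoscedastic
replicates at n = 24. Replicate seeds are shared across candidate δ values,
making the estimated power curve monotone and the search stable. The frozen
default 0.0775 came from this procedure with 2000 replicates (root seed 1,
achieved power 0.7995). The rejection rate at n = 312 (≈ 100%) is then an
out-of-sample check, not a fitted quantity.

### The irregular-trend sensitivity regime

This regime must violate *both* the DiD parallel-trend assumption and the
CITS constant-slope-difference assumption. Two candidate constructions
fail on inspection and were rejected:

* a sign-alternating slope flipping at symmetric fractions (quarters) of
  the series cancels between the pre and post periods, so every pre/post
  contrast is unbiased and nothing is violated;
* a kinked (piecewise-linear) profile cannot be represented by restricted
  cubic splines with percentile knots at any sample size, so the
  flexible-spline specifications carry an O(amplitude) bias at every n —
  the regime would then measure spline approximation of non-smooth
  functions, not design flexibility.

The implemented default is a smooth curve — a natural cubic through nodes
alternating between +1 and −1 at irregular fractions (20%, 45%, 85%) of
the series, projected onto the k = 5 restricted-cubic-spline span of time —
with fixed amplitude in rescaled time, applied to the control series only.
What the regime then probes is the genuine design contrast: the
differenced-series ITS can deploy its spline *against the group-specific
trend directly* and becomes unbiased as n grows, while panel CITS/DiD can
only offer a common spline plus a linear group×time term, which cannot
absorb a group-specific curve. The amplitude default (control wander ≈ ±τ
in outcome units) makes the violation material without dwarfing the series.

## Estimators and inference

All 21 formulations of the evaluation grid are least-squares fits of the
designs in `model_catalog()`. Points worth recording:

* **Fixed effects** are explicit group dummies; the suite verifies
  equivalence with the within (demeaning) transformation.
* **CI conventions**: t critical values with residual degrees of freedom
  for OLS-based fits (classical, White, Driscoll-Kraay); normal critical
  values for FGLS and AR(1)-ML, whose reference distributions are
  asymptotic. 95% throughout.
* **White estimator**: HC1 small-sample factor n/(n−k); short series
  dominate the size grid. Coefficients are untouched.
* **Driscoll-Kraay**: period-summed moment vectors, Bartlett weights up to
  lag ⌊4(T/100)^{2/9}⌋, same n/(n−k) factor — so with one panel and lag 0
  it reduces exactly to White.
* **Panel FGLS**: two-step with one AR(1) coefficient pooled across the
  two panels, per-panel variances and one cross-panel covariance, iterated
  once from GLS residuals. The estimated group covariance is clamped to
  positive definiteness; non-invertibility is reported as non-convergence,
  never an error.
* **AR(1)-ML**: regression with AR(1) errors by full maximum likelihood
  (`stats::arima`); the order is fixed at 1 to match the generating
  process, since order selection at n = 24 is unstable. Optimizer warnings
  are treated as non-convergence and the replicate is dropped with a count.
* **Single-series models** always include an intercept.
* The subtract-two-ITS estimator combines SEs under independence
  (√(se₁² + se₂²)); this ignores any dependence between the two fits and is
  reported for completeness, not recommended.

### Splines

Restricted cubic splines of time use Harrell's percentile knot placements
(k = 3..7) with R's type-7 quantiles (interpolation conventions differ
across software, so the choice is fixed and logged). Knots are *not*
forced at the interruption: anchoring a knot at the intervention point
would manufacture a break exactly where the effect is estimated, a
confirmation-bias hazard, so the option exists but is off by default. The
candidate knot counts default to {3, 4, 5} — splines are noise-sensitive
in the short-series settings this grid targets — with AIC as the default
criterion and ties broken toward fewer knots.

One engine-level design choice deserves emphasis: within a simulation
cell, the knot count is selected **once** (on the first replicate's data)
and held fixed across replicates. Re-selecting per replicate injects
model-selection variability into the spread of τ̂ that no per-fit model SE
accounts for; measured consequence was SE ratios of 0.7–0.8 and coverage
of 86–92% for spline models *even when correctly specified*. Per-cell
selection restores ≈ 95% coverage. Single-dataset fits via `fit_model()`
still select per dataset, which is the right behaviour for applied use.

## The Monte Carlo engine

Each cell (scenario × n) derives its seed from the root seed by cell
index, and each replicate from the cell seed, so any cell is reproducible
in isolation and results are invariant to execution order. Every model in
a cell consumes the identical panel per replicate (paired comparison).
Scenario-driven SE switching: heteroscedastic cells upgrade classical SEs
to White; autocorrelated cells switch single-series designs
(control-as-covariate, uncontrolled) to AR(1)-ML. Misspecified
(scenario-incompatible) models are still run — quantifying misspecification
is the point — except structurally impossible pairs, which the
`model_spec()` constructor rejects.

Performance measures follow the standard simulation-study definitions:
absolute bias (signed retained), EmpSE (SD of τ̂ across replicates),
avgModSE as the *arithmetic mean* of reported SEs — the definition used in
the source literature for this grid, not the root-mean-variance form some
texts prefer — their ratio, coverage, and the Monte Carlo SE of the bias.
300 replicates per cell trades precision for runtime; the
`stability_check()` operation quantifies what that choice costs by
recomputing bias on nested replicate subsets.

## What the generator does and does not emulate

The synthetic world mirrors a two-series public-health evaluation
(fortnightly counts aggregated enough to treat as Gaussian): one
intervention and one control series, a mid-series level-change-only
intervention, no seasonality, no underlying trend in the base case, at
most AR(1) dependence. A green test therefore establishes correctness of
the estimators and the designed behaviour under *these* violations; it
says nothing about count outcomes, seasonal patterns, slope-change
effects, multiple controls, or non-stationary processes, all of which are
out of scope by design.

## Numerical choices and degenerate inputs

* Zero-variance covariate columns (e.g. the degenerate X of noiseless
  oracle fixtures) are dropped from design matrices; the intercept and the
  effect column are never dropped. Rank-deficient designs after that are
  flagged `converged = FALSE`, excluded from summaries and counted.
* `sigma_base = 0` is allowed and produces exactly noiseless panels — the
  basis of the package's exact-identity oracle tests.
* Knot-count ties break toward fewer knots; knot selection failure for
  every candidate is an error listing per-candidate failures.
* With fewer than 2 converged replicates, dispersion measures are NA and
  flagged rather than fabricated.
* Seed derivation uses a 69069-multiplier congruential mix modulo 2³¹−1,
  keeping every derived seed a valid 32-bit integer.

## Known limitations

* The FGLS error model assumes a common AR(1) coefficient across the two
  panels; with only two panels the cross-sectional correlation is a single
  parameter, and T must comfortably exceed the coefficient count.
* HC1-based intervals undercover modestly (≈ 92–93%) at n = 24 under
  strong heteroscedasticity; this is a property of the estimator the grid
  is designed to expose, not a defect of the implementation.
* The irregular-trend regime is a reconstruction: its exact published form
  is unavailable, so only directional conclusions (which design family
  tracks it) are supported, never magnitudes.
* Minimum-over-many-cells coverage summaries at 300 replicates are noisy:
  a correctly specified model with exact 95% coverage will show cell
  minima near 92–93% across 40 cells purely from binomial variation.
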