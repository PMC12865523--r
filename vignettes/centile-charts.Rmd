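---
title: "Age-conditional centile charts for placental perfusion: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Age-conditional centile charts for placental perfusion: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(placentile)
```

## The problem

First-trimester placental perfusion, measured as a 3D single-vessel
fractional moving blood volume (a fraction in (0, 1)) at five locations in
the uteroplacental vasculature, is positively skewed and its distribution
drifts with gestational age over the scanning window of 79-99 days. A
clinically usable reference range therefore has to model the full
age-conditional distribution, not just a mean and standard deviation, and
it has to be built from a *proscriptive* cohort: pregnancies with no
evidence of the pathologies the measurement is eventually meant to
predict. This vignette describes the models the package fits, the
numerical choices behind them, and what the synthetic-cohort machinery
does and does not establish.

## Response families

Four families are implemented, all in their standard GAMLSS-catalog
parameterizations (`?dist_params`):

* **BCCGo** - the classic LMS model. The Box-Cox transform
  `z = ((y/mu)^nu - 1)/(nu sigma)` of a positive response is standard
  normal. `mu > 0` is (approximately) the age-specific median, `sigma` the
  coefficient of variation, `nu` the skewness-governing power (`nu < 1`
  gives positive skew).
* **BCPEo** - the same transform, but the latent standardized variable
  follows a power exponential with kurtosis parameter `tau` (variance-1
  standardization; `tau = 2` is Gaussian, so BCPEo contains BCCGo).
* **SEP1** - Azzalini-type skewing `2 f_PE(z) F_PE(nu z)` of the same
  power-exponential kernel, `z = (y - mu)/sigma`; `nu = 0` is symmetric.
* **SEP3** - two-piece scale skewing: scale `1/nu` left of `mu` and `nu`
  right of it; `nu = 1` is symmetric, and `nu` must be positive.

For the Box-Cox families the transform maps (0, Inf) to a half-bounded
latent interval whenever `nu != 0`; every density, CDF and quantile in the
package includes the resulting truncation normalizer, and
`truncation_mass()` reports the latent mass beyond the bound so that users
(and tests) can verify it is negligible in the parameter ranges that
matter. The `nu = 0` branch of the transform is taken when `|nu| < 1e-7`;
continuity across that switch is tested.

A deliberate modeling wrinkle inherited from the chart-construction
practice this package follows: the measurement lives in (0, 1) but the
Box-Cox families are supported on (0, Inf) and the SEP families on the
whole real line. The fitted distributions are used as-is; with the
parameter values that arise here the mass outside (0, 1) is negligible,
and the synthetic generator rejects and redraws the rare sample outside
the physical range. The tail mass is surfaced as a diagnostic rather than
silently renormalized.

## LMS fitting

`fit_lms()` maximizes the penalized log-likelihood of a chosen family with
each parameter a smooth function of age. Design choices:

* **Curves.** Cubic B-splines with interior knots at quantiles of the
  observed ages (default 6 interior knots), with a ridge penalty on second
  differences of the coefficients (P-splines). Smoothness is expressed as
  target effective degrees of freedom; the penalty weight is solved from
  the target by root-finding on `tr[(B'WB + lambda P)^{-1} B'WB]`. An edf
  target of 1 degenerates to a constant; the penalty null space makes
  edf -> 2 (a line) the large-penalty limit. Links: log for `mu`, `sigma`,
  `tau`; identity for `nu`, except SEP3 where `nu > 0` forces a log link.
* **Algorithm.** Cyclic backfitting: each parameter curve in turn is
  updated by a penalized Fisher-scoring step, with the per-observation
  score and curvature obtained by central differences of the
  log-likelihood in the curve's linear predictor (step 1e-4, curvature
  floored at 1e-4 and capped at 1e6, working-response steps damped to
  |u/w| <= 5). Every update is step-halved until the penalized
  log-likelihood does not decrease, so the trace is monotone - an invariant
  the tests assert. Convergence is declared when the change between cycles
  falls below 1e-4; the cycle cap defaults to 1000 and the AIC penalty
  multiplier to `k = 2`, the conventional settings for this kind of chart
  fitting.
* **Initialization.** `mu` from a penalized least-squares fit of `log y`;
  `sigma` from the residual spread; `nu = 1` (Box-Cox) or the symmetry
  point (SEP); `tau = 2`. Deterministic, so fits are reproducible without
  any seed.
* **Smoothness selection.** Default grids: `mu` 2-6, `sigma` 2-4, `nu` and
  `tau` 1-2 edf. The default search is greedy coordinate descent over the
  grid (about a dozen fits) rather than the full cartesian product, which
  changes nothing on the smooth truths tested here and keeps a five-series
  screen fast; `select = "grid"` does the exhaustive search.
* **No age transformation.** The age axis is used in days as-is. A
  power-transformed age axis is a known variant; it is intentionally not
  applied, and the configuration records that choice.

On synthetic cohorts of n = 2500 with a known BCPEo truth, the fitted
50th-centile curve is recovered with a median absolute relative error
around 1% over the interior ages (82-96 days), comfortably inside the 2%
bound the acceptance suite enforces; `sigma` is recovered within 10%.

## Quantile-regression comparators

`fit_quantile_curves()` minimizes the check loss
`sum_i rho_q(y_i - x_i'b)` per quantile level over six bases (linear,
orthogonal polynomials of degree 2-4, natural splines df 4, B-splines
df 5). Two solvers:

* **Exact L1** - a primal-dual interior-point method on the check-loss
  linear program, maintaining exact primal and dual feasibility and
  driving complementarity to zero, followed by a vertex polish (solve
  through the p smallest-|residual| points and keep the result if the
  objective does not worsen). On generic data this reproduces brute-force
  oracles to machine precision.
* **Lasso** - the L1 coefficient penalty is folded into the same solver by
  the exact augmentation identity
  `rho_q(lambda b) + rho_q(-lambda b) = lambda |b|`: two pseudo-rows
  (`y* = 0`, `x* = +/- lambda e_j`) per penalized coefficient. The
  intercept is not penalized. As `lambda -> 0` this reproduces the exact
  solver by construction, which the tests confirm to 1e-4.

The check loss defines no likelihood, so AIC uses the conventional
asymmetric-Laplace surrogate per level:
`logLik_q = n (log(q(1-q)) - 1 - log(mean rho_q(r)))`,
`AIC_q = 2 p_q - 2 logLik_q`. Because each level's surrogate already
covers the full data, the package reports per-level AICs, their sum, and
uses the per-level *mean* as the headline value: a seven-level sum would
count the data seven times and could not be compared with the LMS models'
single-likelihood AIC, whereas the per-level mean sits on the same scale.
Both readings remain available in the fitted object.

Raw per-level curves may cross; `predict(..., rearrange = TRUE)` applies
the isotonic (sorting) rearrangement. It is off by default, since the
chart-selection workflow compares raw fits.

## Centiles, Z-scores and calibration

`centile_curve()` evaluates `C_alpha(t)` from the fitted parameter curves;
`individual_centile()` and `z_score()` invert the relationship for a
single case (`z = qnorm(F(y; t))`, clamped to |z| <= 8 with a warning on
CDF underflow). Extrapolation beyond the fitted age range is an error
unless explicitly allowed, and is flagged when it is.

`calibration_table()` reports, per target centile (1, 3, 10, 25, 50, 75,
90, 97, 99 by default):

* **predicted** coverage - the percentage of observations strictly below
  their age-specific curve value (ties count as not-below; for continuous
  data the choice is immaterial but fixed);
* **attainable** coverage - the number of sample points strictly below the
  empirical linear-interpolation (type-7) alpha-quantile, i.e.
  `k* = floor(1 + (n-1) alpha)` (minus one at integer positions), as a
  percentage. This is the best any continuous model could achieve on a
  finite sample, and it reproduces the published observed-coverage
  convention this package mirrors (e.g. 26/2547 = 1.02% at the 1st
  centile).

Both are reported to two decimals with unrounded columns retained, along
with Z-score moments and a Shapiro-Wilk statistic.

## Quality control

`triage_rounds()` implements the three sequential review rounds on paired
segmentation agreement: placental Dice below 0.60 (round 1, regardless of
fluid agreement); placental below 0.75 together with amniotic-fluid below
0.40 (round 2); fluid below 0.40 alone (round 3). First match wins, the
order reflecting sequential review; boundary values pass (strict
inequalities); missing values are "unresolvable" rather than silently
passed. `iqr_outliers()` computes per-gestational-day Q1/Q3 by type-7
(linear interpolation) quantiles - the mainstream default, recorded
because the convention changes flags at small n - and flags values
strictly outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`; day groups below 4
observations are exempt and marked. `dice()` defines two empty masks as
agreement 1 (logged).

## Precision arithmetic

`centile_se()` implements `SE_p = SD sqrt((1 + Z_p^2/2)/n)` and
`required_n()` its ceiling inversion. The printed typography of this
formula is ambiguous in the source material; this reading is adopted
because it exactly reproduces both published worked values (n = 1169 at
SD = 1, p = 0.975, target SE = 0.05; SE = 0.03 at n = 2547).
`boxcox_standardize()` chooses the one-parameter Box-Cox power by profile
maximum likelihood and rescales to SD exactly 1 - the standardization
under which "SD = 1" holds in that arithmetic. Constant variance across
age is assumed in this step only; the charts themselves fit age-varying
`sigma`. The two assumptions belong to different steps and are both
implemented, neither reconciled.

## The synthetic cohort generator

`truth_spec()` fixes the study conditions the generator emulates:

* ages 79-99 days sampled with truncated-normal weights peaked at day 89
  (SD 4.5 days), so the extremes are sparse;
* five series with BCPEo truth curves, linear in centered age on the link
  scales: medians 0.07-0.30 at day 89 rising gently with age, coefficients
  of variation 0.35-0.55, Box-Cox powers below 1 everywhere (positive
  skew) and most negative (-0.4) for series 4, which therefore shows the
  most prominent skew; `tau = 2`;
* outcome flags drawn independently. Frequencies that a healthy included
  cohort reports (smoker 1.81%, previous pre-eclampsia 1.57%, birth weight
  below the 10th centile 4.79%, female sex 49.63%) are taken from the
  published cohort table; prevalences of the excluded outcomes themselves
  (miscarriage 0.8%, stillbirth 0.3%, termination 0.4%, neonatal death
  0.2%, anomaly 1%, neonatal-unit admission 3%, diabetes 4%, hypertensive
  disease 3%, antiphospholipid/SLE 0.2%, incomplete outcome 1%) are not
  published anywhere and were fixed once at values realistic for a UK
  screening population;
* log-normal placental volumes with age-increasing mean and a 0.5%
  injected fraction of fence-busting outliers; paired Dice values with
  1%/0.5%/0.5% failures injected for triage rounds 1-3;
* perfusion draws outside (0, 1) are rejected and redrawn (the families
  are supported beyond the physical range; the spillover probability is
  tiny at these parameters).

Regeneration with the same spec and seed is bit-identical, and the truth
curves are embedded in the cohort object for recovery scoring.

What passing tests on these cohorts show: the fitting machinery recovers
smooth four-parameter truths of the assumed family, the calibration
machinery is unbiased when the model is correct, and the pipeline's
filters and QC behave exactly as specified. What they do not show: that
real perfusion data follow any of these families, that outcome flags are
independent in reality (they are not; the generator's correlation hook is
deliberately off because chart construction does not use the joint
distribution), or anything about segmentation quality beyond scalar Dice
values.

## Problem sizes and runtime choices

The test suite fits models at n = 1500-2500 with fixed effective-df
targets (the recovery question is about the fitter, not the smoothness
search), runs the 20-cohort recovery study at n = 2500, and the
Monte-Carlo distribution checks at n = 50 000. The acceptance script uses
the same sizes. These choices keep a full run around a minute while
leaving the Monte-Carlo error well below every asserted tolerance.

## Known limitations

* SEP1 has no closed-form CDF; it is integrated adaptively and its
  quantile is found by bisection, so SEP1 CDF calls are slower than the
  other families (still well under a millisecond each).
* The backfitting fitter targets smooth, moderately parameterized truth
  curves; it is not a general-purpose GAMLSS replacement (no covariates
  other than age, no bootstrap bands, none of the thirteen other families
  screened in the wider family catalog - the interface accepts any family
  implementing the distribution contract, so they are extension points).
* AIC comparisons across a rescaled response shift by `n log c`; AIC
  ordering is only meaningful within one response scale.
* The healthy-cohort filter reports both any-match and first-match
  exclusion counts; the first-match sequence depends on the documented
  criterion order.
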