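---
title: "Generating high-fidelity synthetic time-to-event data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating high-fidelity synthetic time-to-event data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Individual-level survival data can rarely be published alongside the
analyses built on it. `survsynth` constructs a *synthetic replica* of a
time-to-event dataset: a cohort of artificial patients whose covariate
distributions, covariate interrelationships, and conditional survival
experience closely track the source data, while no synthetic record is
tied to any real person. The replica can then accompany code and
publications where the registry extract cannot.

The method has two model layers plus a mechanical reconstruction of the
calendar structure:

1. **Joint covariate distribution** — one regression model per
   covariate, fitted sequentially so that model $m$ conditions on
   covariates $1, \dots, m-1$;
2. **Conditional survival** — a flexible parametric survival model on
   the log cumulative hazard scale, from which survival times are drawn
   by inversion given each synthetic profile;
3. **Calendar reconstruction** — diagnosis dates drawn uniformly within
   each record's diagnosis year, and the source's administrative
   censoring date re-imposed on the synthetic exit dates.

## Sequential conditional covariate models

Covariates are modelled in order of increasing distributional
complexity: continuous covariates first (so their effect can be
imparted on every factor model), then factors by ascending level count.
`order_covariates()` applies this default; an explicit `model_order` in
the schema overrides it, and the bundled `colon_schema()` fixes the
order *age, year, stage, sex, subsite*, which in our experience (and in
the setting the package emulates) recovers survival patterns better
than either pure level-count ordering. Factor covariates with missing
values are first given an explicit `"Missing"` level
(`encode_missing_as_level()`), so missingness patterns are reproduced
like any other group and restored to true `NA`s at the end.

**Factors** are fitted by multinomial logistic regression
(`nnet::multinom`) on all earlier covariates: dummies for earlier
factors, restricted cubic splines (4 knots at the 5/35/65/95 centiles)
for earlier continuous covariates, plus the pairwise interaction
between the two most recent factor predecessors (configurable,
`cov_control(interactions = )`). A tiny ridge penalty
(`decay = 1e-6`) guards against separation in sparse level
combinations. Sampling uses the fitted per-row level probabilities
directly.

**Continuous covariates** use the inverse-normal-rank construction:
the tie-averaged ranks are mapped to normal quantiles,
$z_i = \Phi^{-1}\{(r_i - 0.5)/n\}$ (the simplest member of the
rank-based inverse-normal family), and the original values are
regressed on a restricted cubic spline of $z$ (4 knots at the
5/35/65/95 centiles of $z$) plus any earlier covariates. Because $z$ is
standard normal by construction, simulating $z^* \sim N(0,1)$ and
evaluating the fitted spline reproduces arbitrarily non-normal shapes,
including the left-skewed, bimodal age distributions typical of cancer
registries. A normal residual with the regression's root-mean-square
error is added (without it, sampled values would collapse onto the
fitted curve; switch: `residual_noise`), values are clamped to the
source range, and integer-valued sources (age in whole years) are
rounded back to integers.

## The survival model

The flexible parametric (Royston–Parmar) model expresses the log
cumulative hazard as

$$\log H(t \mid x) = s(\log t;\ \gamma) \;+\; x\beta \;+\;
  \sum_{j \in \text{TDE}} s_j(\log t)\, x_j ,$$

where $s$ is a restricted cubic spline (basis linear beyond the
boundary knots; `rcs_basis()` implements the plus-function
parameterization directly) and the time-dependent-effect (TDE) terms
let chosen covariate effects wane or grow with follow-up time. The
default replication specification (`colon_fpm_spec()`) uses 5 df for
the baseline spline, 3 df per TDE (age and stage), age as a 3-df spline
winsorized at its 2nd/98th percentiles, and two-way interactions of the
age spline with stage, subsite and sex plus stage-by-sex. Baseline
knots sit at the boundary and equally spaced centiles of the
*uncensored* log event times; TDE splines use the 33.3/66.7 centiles.
Time is measured in years (`days / 365.24`), which keeps knots and
coefficients on an interpretable scale.

The log likelihood for subject $i$ with event indicator $d_i$ is
$d_i\{\eta_i + \log (\partial \eta_i / \partial \log t_i) - \log t_i\}
- \exp(\eta_i)$. It is maximized by BFGS with an analytic gradient,
warm-started from a Weibull (df = 1) submodel; design columns are
centered and scaled internally for optimizer stability and mapped back,
so reported coefficients are on the natural scale. Where the time-slope
$\partial\eta/\partial\log t$ becomes non-positive at an event time the
likelihood is replaced by a smooth, steep penalty that pushes the
optimizer back into the valid region. Convergence uses a relative
log-likelihood tolerance of `1e-10` (up to 500 BFGS iterations, with
one automatic restart). With df = 1 and no covariates the model *is*
Weibull, and the test suite verifies coefficient agreement with a
direct Weibull maximum-likelihood fit to $10^{-4}$ and log-likelihood
agreement with an independent spline-hazard implementation
(`flexsurv::flexsurvspline`) for df = 2.

## Generating times, dates, and censoring

A survival time is drawn per synthetic row by solving
$S(t \mid x) = u$ for a uniform $u$: the target is a root of
$\eta(\log t) = \log(-\log u)$, bracketed around the observed log
event-time range (expanded geometrically, hard-capped at $10^4$ times
the largest observed time — capped draws are flagged) and refined
either by Brent's method (`invert_survival_time()`, tolerance
$|S - u| < 10^{-8}$) or, for whole tables, by a vectorized bisection
that resolves all rows simultaneously to the same accuracy
(`generate_times()`). Times convert to days and round *up* to whole
days (minimum 1 day: an exit must differ from diagnosis).

Diagnosis dates are uniform over the days of each record's own
diagnosis year (365 or 366 days — leap years are honoured). Vital
status is first coded dead iff the generated time does not exceed the
source's last observed exit time (the boundary is inclusive; the
convention is ours). Then administrative censoring is re-imposed by
date: any synthetic exit strictly beyond the source's administrative
censoring date is recoded alive at that date. When year-of-diagnosis
randomness pushes a record across the boundary, the date-based recode
wins — the steps are applied in that order deliberately.

## Appraisal

* `compare_covariate_distributions()` tabulates per-level counts,
  percentages and absolute differences (2 dp), including a `"Missing"`
  row, age groups (<45, 45–60, 60–75, >75; left-inclusive bounds) and
  vital status. `max_proportion_difference()` reduces the table to the
  headline fidelity number.
* `km_estimate()` / `km_sup_distance()` compare product-limit curves.
  Comparisons are truncated at the last time with at least 10% of the
  (sub)cohort still at risk (`km_truncation_time()`): beyond that point
  the estimator moves in whole-percent jumps per event and a supremum
  norm measures noise, not fidelity — the same reason published
  survival plots are truncated at small risk sets.
* `rmst()` integrates a KM step function exactly, or a model profile by
  trapezoid; `seed_stability()` regenerates the cohort across seeds
  (model fitting is deterministic given the source, so the fits are
  reused) and compares the 10-year restricted mean survival time to the
  source value.
* `privacy_match_report()` generates a large matched-profile cohort for
  a probe record and reports the share of synthetic diagnosis dates and
  survival times within ±15 days (a 31-day inclusive window), the
  vital-status split and exact-day matches. With the diagnosis year
  fixed, about $31/365 \approx 8.5\%$ of dates must fall in the window
  by chance alone — date matches carry no identifying information. For
  the single shared profile the quantile function is inverted on a
  dense log-time grid (interpolation error orders of magnitude below
  one day). `pattern_frequency_audit()` counts how often rare covariate
  patterns appear at all across replicate synthetic datasets.

## The bundled fixture

`make_colon_fixture()` emulates a historical colon-cancer registry
extract (9,064 diagnoses 1985–1994, administrative censoring at
1995-12-31) so that every stage of the pipeline is testable with known
ground truth and no external data. Design choices, all fixed here and
not revisited:

* age: $0.35\,N(58, 9^2) + 0.65\,N(74, 8^2)$, truncated to [18, 99],
  rounded to whole years — mimics the left-skewed registry age shape;
* diagnosis years uniform over 1985–1994 (the emulated source reports
  no year trend);
* stage marginals 40.91/12.64/32.00% with 14.45% missing completely at
  random; stage depends on age (log-odds +0.08/+0.18 per decade above
  70 for Regional/Distant), with intercepts calibrated by a
  deterministic fixed-point loop so the marginals still hit their
  targets; sex 41.82% male; subsite 35.66/17.69/40.29/6.36%;
* true hazard: Weibull baseline, shape 1.1, rate 0.096 (chosen so
  ~61% of the cohort dies inside the follow-up window), log hazard
  ratios 0.55/1.45 for Regional/Distant, −0.10 for female, 0.35 per
  decade of age above 70, small subsite effects, and an age-by-time
  interaction (the Weibull shape shifts by 0.03 per decade above 70),
  so the truth is mildly non-proportional. The missing-stage group's
  hazard is the mixture induced by blanking at random.

What the fixture does **not** emulate: real registry features such as
calendar-time incidence and survival trends, informative (non-random)
missingness, drop-out censoring before the administrative date, and
covariate measurement error. Passing fixture-based checks therefore
demonstrates that the pipeline recovers *the structures it models* at
registry scale — not that any particular real dataset would be
reproduced equally well.

## Problem sizes used in validation

The test suite runs the full pipeline at the emulated study scale
(9,064 records in and out), checks distributional recovery of a
bimodal covariate at the same size, inversion calibration on $10^4$
draws, date uniformity on $10^6$ draws, seed stability across 10
generation seeds, and likelihood-oracle agreement on batches of small
randomized instances. Matched-profile privacy cohorts use $2\times10^4$
records in the unit tests; the operation comfortably scales to the
$10^6$ used for reporting (a few seconds via grid inversion).

## Known limitations

* All-cause survival only: relative/net survival and conditional life
  expectancy need external population life tables and are out of scope,
  as are competing risks and delayed entry.
* The generator reproduces administrative censoring only; a drop-out
  censoring process is deliberately not modelled.
* Sequential conditional sampling compounds sampling noise along the
  chain: the last-modelled covariate's marginal carries slightly more
  than binomial variability at a given cohort size.
* Fidelity and privacy trade off: richer interaction/TDE structure
  tracks subgroup survival better but moves the replica closer to the
  source; the specification objects make that dial explicit.
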