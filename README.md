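# survsynth

High-fidelity synthetic time-to-event data for open, reproducible
survival research.

Registry-style survival datasets — cancer cohorts with staging,
demographics, diagnosis dates and administratively censored follow-up —
usually cannot be published alongside the analyses built on them.
`survsynth` generates a synthetic replica that preserves the covariate
distributions, their interrelationships and the conditional survival
patterns of a source dataset, while containing no record of any real
individual. It is aimed at biostatisticians and registry analysts who
want to release data-plus-code companions to published survival
analyses.

## The method

1. **Covariate synthesis.** The joint covariate distribution is modelled
   by sequential conditional regressions: model *m* has covariate *m* as
   the outcome and covariates *1..m−1* as predictors, ordered from least
   to most distributional complexity. Factors use multinomial logistic
   regression; continuous covariates use the inverse-normal-rank
   construction — ranks mapped to normal quantiles,
   *z* = Φ⁻¹((r − ½)/n), then the original values regressed on a
   restricted cubic spline of *z* — so arbitrarily non-normal shapes are
   reproduced by simulating *z\** ~ N(0,1) through the fitted spline.

2. **Survival model.** A flexible parametric (Royston–Parmar) model on
   the log cumulative hazard scale,

   log *H*(*t* | *x*) = *s*(log *t*; γ) + *x*β + Σⱼ *s*ⱼ(log *t*) *x*ⱼ,

   with restricted cubic splines of log time (default 5 df),
   time-dependent effects (3 df) and two-way covariate interactions,
   fitted by penalized maximum likelihood with an analytic gradient.

3. **Generation.** For each synthetic profile a uniform *u* is inverted
   through *S*(*t* | *x*) = *u* by root finding on the log-time axis;
   times are rounded up to whole days, diagnosis dates drawn uniformly
   within each record's diagnosis year, and the source's administrative
   censoring date re-imposed (exits beyond it become alive at that
   date).

4. **Appraisal.** Covariate proportion tables, Kaplan–Meier overlap,
   restricted mean survival time across generation seeds, and
   disclosure-risk reports (±15-day date/time window matching against
   rare-profile probes; pattern frequency across replicate datasets).

## Worked example

The package bundles a colon-cancer-like fixture generator with known
ground truth (9,064 patients, diagnoses 1985–1994, administrative
censoring at 1995-12-31, 14.45% missing stage), so the whole pipeline
can be exercised without any external data:

```r
library(survsynth)
src <- make_colon_fixture(n = 9064, seed = 1)
res <- run_pipeline(src, n = 9064, seed = 2)

cmp <- compare_covariate_distributions(src, res$synthetic)
head(cmp[cmp$covariate == "stage", ], 4)
#>  covariate   kind     level source_n source_pct synth_n synth_pct abs_diff
#>      stage factor Localized     3678      40.58    3630     40.05     0.53
#>      stage factor  Regional     1146      12.64    1148     12.67     0.02
#>      stage factor   Distant     2898      31.97    2929     32.31     0.34
#>      stage factor   Missing     1342      14.81    1357     14.97     0.17
max_proportion_difference(cmp, include_vital = FALSE)
#> [1] 0.75
```

Every factor-level proportion (stage, subsite, sex, year of diagnosis)
is reproduced to within 0.75 percentage points here. Survival patterns
carry over as well:

```r
km_src <- km_estimate(src$survival_days / 365.24, src$vital_status == "dead")
km_syn <- km_estimate(res$synthetic$survival_days / 365.24,
                      res$synthetic$vital_status == "dead")
km_sup_distance(km_src, km_syn, 10)   # largest gap between the curves
#> [1] 0.0108
rmst(km_src, 10); rmst(km_syn, 10)    # 10-year restricted mean survival
#> [1] 4.596
#> [1] 4.572
```

And the disclosure-risk audit for the rarest covariate pattern in the
source shows date matches occurring at the rate pure chance dictates
(with the diagnosis year fixed, ~31/365 ≈ 8.5% of uniform dates must
fall inside a ±15-day window):

```r
probe <- make_probe_records(src, 1)
set.seed(3)
privacy_match_report(probe, res$fits, n_synth = 1e5)
#>  n_synth pct_alive pct_dead pct_date_within_window pct_time_within_window
#>   100000     10.04    89.96                   8.47                   1.29
#>  exact_time_matches
#>                  42
```

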