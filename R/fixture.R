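# Colon-cancer-like source data generator with known ground truth, so
# every pipeline stage can be validated without access to registry data.
# All records produced here are synthetic stand-ins; the default
# parameters emulate the published marginal distributions of a historical
# colon cancer cohort (9,064 diagnoses 1985-1994, administratively
# censored 1995-12-31) but the joint model is this package's own choice.

#' Schema of the colon-cancer-like example dataset
#'
#' Age (continuous), year of diagnosis 1985-1994 (calendar-year role),
#' stage, sex and anatomical subsite, with the explicit modelling order
#' age, year, stage, sex, subsite.
#'
#' @return a [covariate_schema()].
#' @export
colon_schema <- function() {
  covariate_schema(
    cov_continuous("age", model_order = 1L),
    cov_categorical("year", as.character(1985:1994), model_order = 2L,
                    year_role = TRUE),
    cov_categorical("stage", c("Localized", "Regional", "Distant"),
                    model_order = 3L),
    cov_categorical("sex", c("Male", "Female"), model_order = 4L),
    cov_categorical("subsite", c("Coecum and Ascending", "Transverse",
                                 "Sigmoid and Descending", "Other and NOS"),
                    model_order = 5L)
  )
}

#' Specification of the colon-like fixture generator
#'
#' Defaults reproduce the example cohort's marginal covariate mix: stage
#' 40.91/12.64/32.00% (Localized/Regional/Distant) with 14.45% missing,
#' subsite 35.66/17.69/40.29/6.36%, sex 41.82% male, years uniform over
#' 1985-1994, and a left-skewed age mixture
#' `0.35 N(58, 9^2) + 0.65 N(74, 8^2)` truncated to [18, 99] and rounded
#' to whole years. Stage depends on age through a multinomial-logit
#' shift (`stage_age_delta` log-odds per decade above 70); intercepts
#' are calibrated so the marginal stage split still hits its targets.
#' Event times follow a Weibull baseline (shape 1.1, rate chosen so that
#' roughly 61% of the cohort dies before the 1995-12-31 administrative
#' censoring date) with log hazard ratios per covariate and a mild
#' age-by-time interaction (age shifts the Weibull shape), so the truth
#' is non-proportional.
#'
#' @param n cohort size.
#' @param age_mix list with `w`, `mean`, `sd` of the two-component
#'   normal mixture for age.
#' @param stage_probs marginal target probabilities (3 observed stages,
#'   renormalized to exclude missingness).
#' @param stage_age_delta log-odds shift per decade of age above 70 for
#'   Regional and Distant (Localized is reference).
#' @param subsite_probs,sex_probs,year_levels marginal settings.
#' @param shape,rate Weibull baseline (time in years).
#' @param loghr named list of log hazard ratios: `stage` (Regional,
#'   Distant), `sex_female`, `age_per_decade` (per decade above 70),
#'   `subsite` (per non-reference level).
#' @param tde_age_shape shift of the Weibull shape per decade of age
#'   above 70 (0 gives proportional hazards).
#' @param missing_stage_rate probability that a record's stage is
#'   blanked (missing completely at random).
#' @param admin_censor_date administrative censoring date.
#' @return a `fixture_spec` list.
#' @export
colon_fixture_spec <- function(n = 9064L,
                               age_mix = list(w = c(0.35, 0.65),
                                              mean = c(58, 74),
                                              sd = c(9, 8)),
                               stage_probs = c(Localized = 0.4091,
                                               Regional = 0.1264,
                                               Distant = 0.3200) / 0.8555,
                               stage_age_delta = c(Regional = 0.08,
                                                   Distant = 0.18),
                               subsite_probs = c(`Coecum and Ascending` = 0.3566,
                                                 Transverse = 0.1769,
                                                 `Sigmoid and Descending` = 0.4029,
                                                 `Other and NOS` = 0.0636),
                               sex_probs = c(Male = 0.4182, Female = 0.5818),
                               year_levels = 1985:1994,
                               shape = 1.1, rate = 0.096,
                               loghr = list(stage = c(Regional = 0.55,
                                                      Distant = 1.45),
                                            sex_female = -0.10,
                                            age_per_decade = 0.35,
                                            subsite = c(Transverse = 0.05,
                                                        `Sigmoid and Descending` = -0.05,
                                                        `Other and NOS` = 0.15)),
                               tde_age_shape = 0.03,
                               missing_stage_rate = 0.1445,
                               admin_censor_date = as.Date("1995-12-31")) {
  if (n < 1L) stop("n must be >= 1")
  stopifnot(shape > 0, rate > 0)
  stage_probs <- stage_probs / sum(stage_probs)
  subsite_probs <- subsite_probs / sum(subsite_probs)
  sex_probs <- sex_probs / sum(sex_probs)
  structure(list(n = as.integer(n), age_mix = age_mix,
                 stage_probs = stage_probs, stage_age_delta = stage_age_delta,
                 subsite_probs = subsite_probs, sex_probs = sex_probs,
                 year_levels = year_levels, shape = shape, rate = rate,
                 loghr = loghr, tde_age_shape = tde_age_shape,
                 missing_stage_rate = missing_stage_rate,
                 admin_censor_date = as.Date(admin_censor_date)),
            class = "fixture_spec")
}

# discrete age distribution on 18..99 implied by the truncated mixture
fixture_age_probs <- function(age_mix) {
  ages <- 18:99
  dens <- rep(0, length(ages))
  for (j in seq_along(age_mix$w)) {
    dens <- dens + age_mix$w[j] *
      (stats::pnorm(ages + 0.5, age_mix$mean[j], age_mix$sd[j]) -
       stats::pnorm(ages - 0.5, age_mix$mean[j], age_mix$sd[j]))
  }
  list(ages = ages, probs = dens / sum(dens))
}

# calibrate stage intercepts so that, averaged over the age distribution,
# marginal stage probabilities hit the targets despite the age dependence
fixture_stage_intercepts <- function(spec) {
  ap <- fixture_age_probs(spec$age_mix)
  agec <- (ap$ages - 70) / 10
  delta <- c(0, spec$stage_age_delta)  # Localized reference
  a <- log(spec$stage_probs / spec$stage_probs[1L])
  for (it in 1:50) {
    L <- outer(rep(1, length(agec)), a) + outer(agec, delta)
    P <- exp(L) / rowSums(exp(L))
    marg <- colSums(P * ap$probs)
    a <- a + log(spec$stage_probs / marg)
    a <- a - a[1L]
  }
  a
}

fixture_stage_probs_given_age <- function(spec, age) {
  a <- fixture_stage_intercepts(spec)
  delta <- c(0, spec$stage_age_delta)
  agec <- (age - 70) / 10
  L <- outer(rep(1, length(agec)), a) + outer(agec, delta)
  P <- exp(L) / rowSums(exp(L))
  colnames(P) <- names(spec$stage_probs)
  P
}

# true log hazard ratio (time-constant part) for fixture rows
fixture_linpred <- function(spec, age, stage, sex, subsite) {
  agec <- (age - 70) / 10
  xb <- spec$loghr$age_per_decade * agec
  xb <- xb + ifelse(sex == "Female", spec$loghr$sex_female, 0)
  st <- spec$loghr$stage
  xb <- xb + ifelse(stage == "Regional", st[["Regional"]],
                    ifelse(stage == "Distant", st[["Distant"]], 0))
  sb <- spec$loghr$subsite
  add <- rep(0, length(subsite))
  for (nm in names(sb)) add[subsite == nm] <- sb[[nm]]
  xb + add
}

#' Analytic survival of the fixture's true model
#'
#' `S(t) = exp(-rate * t^shape(age) * exp(xb))` with
#' `shape(age) = shape + tde_age_shape * (age - 70)/10`, time in years.
#'
#' @param spec a `fixture_spec`.
#' @param t times in years.
#' @param age,stage,sex,subsite scalar covariate values.
#' @return survival probabilities.
#' @export
fixture_true_survival <- function(spec, t, age, stage, sex, subsite) {
  xb <- fixture_linpred(spec, age, stage, sex, subsite)
  sh <- spec$shape + spec$tde_age_shape * (age - 70) / 10
  exp(-spec$rate * t^sh * exp(xb))
}

#' Generate a colon-cancer-like source dataset
#'
#' Draws covariates with the declared age-stage dependence, diagnosis
#' dates uniform within each calendar year, event times from the true
#' Weibull model conditional on covariates (survival days are
#' ceiling-rounded, minimum 1), and applies administrative censoring by
#' date. Uses the current R random stream. The ground truth (the spec)
#' is attached as attribute `truth`.
#'
#' @param spec a [colon_fixture_spec()].
#' @return a valid `tte_dataset` with the [colon_schema()] attached.
#' @export
generate_source_like_colon <- function(spec = colon_fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  n <- spec$n
  ap <- fixture_age_probs(spec$age_mix)
  age <- ap$ages[sample.int(length(ap$ages), n, replace = TRUE, prob = ap$probs)]
  year <- spec$year_levels[sample.int(length(spec$year_levels), n, replace = TRUE)]
  if (any(as.integer(year) > as.integer(format(spec$admin_censor_date, "%Y")))) {
    stop("diagnosis years extend beyond the administrative censoring date")
  }
  sex <- sample(names(spec$sex_probs), n, replace = TRUE, prob = spec$sex_probs)
  P <- fixture_stage_probs_given_age(spec, age)
  u <- stats::runif(n)
  cum <- P
  for (k in 2:ncol(P)) cum[, k] <- cum[, k - 1L] + P[, k]
  stage <- colnames(P)[rowSums(u > cum) + 1L]
  subsite <- sample(names(spec$subsite_probs), n, replace = TRUE,
                    prob = spec$subsite_probs)
  diag_dates <- assign_diagnosis_dates(year)
  if (any(diag_dates > spec$admin_censor_date)) {
    stop("diagnosis dates extend beyond the administrative censoring date")
  }
  xb <- fixture_linpred(spec, age, stage, sex, subsite)
  sh <- spec$shape + spec$tde_age_shape * (age - 70) / 10
  ut <- stats::runif(n)
  t_years <- (-log(ut) / (spec$rate * exp(xb)))^(1 / sh)
  days <- pmax(as.integer(ceiling(t_years * 365.24)), 1L)
  exit <- diag_dates + days
  over <- exit > spec$admin_censor_date
  vital <- ifelse(over, "alive", "dead")
  exit[over] <- spec$admin_censor_date
  days[over] <- as.integer(spec$admin_censor_date - diag_dates[over])
  df <- data.frame(age = as.numeric(age), year = as.character(year),
                   stage = stage, sex = sex, subsite = subsite,
                   diagnosis_date = diag_dates, exit_date = exit,
                   survival_days = days, vital_status = vital,
                   stringsAsFactors = FALSE)
  ds <- tte_dataset(df, colon_schema())
  attr(ds, "truth") <- spec
  ds
}

#' Blank a categorical covariate at random
#'
#' Each row's value is independently set missing with the given
#' probability (missing completely at random).
#'
#' @param ds a `tte_dataset`.
#' @param covariate name of a categorical covariate.
#' @param rate missingness probability in [0, 1].
#' @return the updated dataset.
#' @export
inject_missingness <- function(ds, covariate, rate) {
  if (rate < 0 || rate > 1) stop("rate must be in [0, 1]")
  e <- schema_entry(dataset_schema(ds), covariate)
  if (e$kind != "categorical") stop("inject_missingness needs a categorical covariate")
  hit <- stats::runif(nrow(ds)) < rate
  x <- as.character(ds[[covariate]])
  x[hit] <- NA_character_
  ds[[covariate]] <- factor(x, levels = e$levels)
  ds
}

#' Colon-like fixture with missing stage, in one call
#'
#' Sets the seed, generates the source cohort and blanks stage at the
#' spec's missingness rate.
#'
#' @param n cohort size.
#' @param seed integer seed.
#' @param spec optional [colon_fixture_spec()] (its `n` is overridden).
#' @return a `tte_dataset` with ground truth attached.
#' @export
make_colon_fixture <- function(n = 9064L, seed = 1L, spec = NULL) {
  if (is.null(spec)) spec <- colon_fixture_spec(n = n)
  spec$n <- as.integer(n)
  set.seed(seed)
  ds <- generate_source_like_colon(spec)
  if (spec$missing_stage_rate > 0) {
    ds <- inject_missingness(ds, "stage", spec$missing_stage_rate)
  }
  attr(ds, "truth") <- spec
  ds
}

#' Records with the rarest full covariate patterns
#'
#' Returns the `k` records whose complete covariate tuple (all schema
#' covariates) occurs least often in the dataset, ties broken by row
#' order.
#'
#' @param ds a `tte_dataset`.
#' @param k number of records (1 <= k <= n).
#' @return the selected rows of `ds`, with their pattern frequency in
#'   column `pattern_freq`.
#' @export
make_probe_records <- function(ds, k) {
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (k > nrow(ds)) stop("k exceeds the number of records")
  schema <- dataset_schema(ds)
  cols <- schema_names(schema)
  keys <- do.call(paste, c(lapply(ds[cols], as.character), sep = "\r"))
  freq <- as.integer(table(keys)[keys])
  idx <- order(freq, seq_along(keys))[seq_len(k)]
  out <- as.data.frame(ds)[idx, , drop = FALSE]
  out$pattern_freq <- freq[idx]
  attr(out, "schema") <- schema
  rownames(out) <- NULL
  out
}
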