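# Fidelity and disclosure-risk appraisal of a synthetic dataset against
# its source.

age_group_cut <- function(age, breaks = c(45, 60, 75)) {
  cut(age, breaks = c(-Inf, breaks, Inf), right = FALSE,
      labels = c(paste0("<", breaks[1L]),
                 paste0(breaks[-length(breaks)], "-", breaks[-1L]),
                 paste0(">", breaks[length(breaks)])))
}

#' Compare covariate distributions between source and synthetic data
#'
#' Per-level counts, percentages (reported to 2 decimal places) and
#' absolute percentage-point differences for every categorical
#' covariate, for grouped continuous covariates (age groups <45, 45-60,
#' 60-75, >75 with left-inclusive boundaries), and for vital status.
#' Missing values are tabulated as a "Missing" level. Levels present in
#' only one dataset appear with a zero count. The absolute-difference
#' column is symmetric in the two arguments.
#'
#' @param source,synthetic `tte_dataset`s sharing a schema.
#' @param schema optional schema; defaults to the source's.
#' @return data frame of class `distribution_comparison` with columns
#'   `covariate`, `kind` ("factor", "age_group", "vital_status"),
#'   `level`, `source_n`, `source_pct`, `synth_n`, `synth_pct`,
#'   `abs_diff`.
#' @export
compare_covariate_distributions <- function(source, synthetic, schema = NULL) {
  if (is.null(schema)) schema <- dataset_schema(source)
  rows <- list()
  tab_block <- function(cov, kind, xs, xy) {
    xs <- as.character(xs); xy <- as.character(xy)
    xs[is.na(xs)] <- "Missing"; xy[is.na(xy)] <- "Missing"
    lev <- union(unique(xs), unique(xy))
    e <- schema$entries[[cov]]
    if (!is.null(e) && e$kind == "categorical") {
      lev <- union(e$levels, lev)
    }
    cs <- table(factor(xs, levels = lev))
    cy <- table(factor(xy, levels = lev))
    ps <- 100 * as.numeric(cs) / max(length(xs), 1L)
    py <- 100 * as.numeric(cy) / max(length(xy), 1L)
    data.frame(covariate = cov, kind = kind, level = lev,
               source_n = as.integer(cs), source_pct = round(ps, 2),
               synth_n = as.integer(cy), synth_pct = round(py, 2),
               abs_diff = round(abs(ps - py), 2),
               stringsAsFactors = FALSE)
  }
  for (nm in schema_names(schema)) {
    e <- schema_entry(schema, nm)
    if (e$kind == "categorical") {
      rows[[nm]] <- tab_block(nm, "factor", source[[nm]], synthetic[[nm]])
    } else {
      rows[[nm]] <- tab_block(nm, "age_group",
                              age_group_cut(source[[nm]]),
                              age_group_cut(synthetic[[nm]]))
    }
  }
  rows[["vital_status"]] <- tab_block("vital_status", "vital_status",
                                      source$vital_status, synthetic$vital_status)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("distribution_comparison", "data.frame")
  out
}

#' Maximum absolute factor-level proportion difference
#'
#' Summarizes a [compare_covariate_distributions()] table as the largest
#' absolute percentage-point difference across all factor levels,
#' optionally including the vital-status split. Grouped continuous
#' covariates are always excluded: they are not sampled from direct
#' level probabilities.
#'
#' @param comparison a `distribution_comparison`.
#' @param include_vital logical; also scan the vital-status rows.
#' @return numeric scalar in percentage points.
#' @export
max_proportion_difference <- function(comparison, include_vital = TRUE) {
  kinds <- c("factor", if (include_vital) "vital_status")
  max(comparison$abs_diff[comparison$kind %in% kinds])
}

#' Kaplan-Meier estimate of the survival function
#'
#' Product-limit estimator with tied failures handled simultaneously.
#'
#' @param times non-negative follow-up times (any unit).
#' @param events logical or 0/1 event indicators.
#' @return a `km_curve` list with `time`, `surv` and `n_risk` (sorted by
#'   time; survival starts at 1 and never increases).
#' @export
km_estimate <- function(times, events) {
  if (!length(times)) stop("empty input")
  if (any(times < 0)) stop("times must be non-negative")
  sf <- survival::survfit(survival::Surv(times, as.numeric(events)) ~ 1,
                          conf.type = "none")
  structure(list(time = sf$time, surv = sf$surv, n_risk = sf$n.risk),
            class = "km_curve")
}

# step-function evaluation of a KM curve at arbitrary times
km_surv_at <- function(curve, t) {
  idx <- findInterval(t, curve$time)
  ifelse(idx == 0, 1, curve$surv[pmax(idx, 1L)])
}

#' Supremum distance between two Kaplan-Meier curves
#'
#' Largest absolute difference of the two step functions over the union
#' of their jump times (restricted to an optional horizon).
#'
#' @param a,b `km_curve` objects (on the same time unit).
#' @param horizon optional upper time limit.
#' @return numeric scalar in [0, 1].
#' @export
km_sup_distance <- function(a, b, horizon = Inf) {
  grid <- sort(unique(c(0, a$time, b$time)))
  grid <- grid[grid <= horizon]
  max(abs(km_surv_at(a, grid) - km_surv_at(b, grid)))
}

#' Truncation time for Kaplan-Meier comparisons
#'
#' Last event/censoring time at which at least `min_at_risk_frac` of the
#' initial cohort remains at risk. Survival-curve comparisons are
#' restricted to this window because beyond it the product-limit
#' estimate is dominated by a handful of subjects (the usual convention
#' for truncating published survival plots).
#'
#' @param km a `km_curve`.
#' @param min_at_risk_frac minimum fraction of the cohort at risk.
#' @return time of the last usable estimate.
#' @export
km_truncation_time <- function(km, min_at_risk_frac = 0.10) {
  n0 <- max(km$n_risk)
  ok <- km$time[km$n_risk >= min_at_risk_frac * n0]
  if (!length(ok)) 0 else max(ok)
}

#' Restricted mean survival time
#'
#' Area under the survival curve up to `horizon`. For a `km_curve` the
#' step-function area is computed exactly; for an `fpm_fit` the model
#' survival for a given covariate profile is integrated by the
#' trapezoidal rule on a fine grid.
#'
#' @param x a `km_curve` or `fpm_fit`.
#' @param horizon positive time horizon (same unit as the curve/fit).
#' @param profile covariate row (required for an `fpm_fit`).
#' @param grid_size number of integration points for model-based RMST.
#' @return non-negative scalar.
#' @export
rmst <- function(x, horizon, profile = NULL, grid_size = 2001L) {
  if (horizon <= 0) stop("horizon must be positive")
  UseMethod("rmst")
}

#' @export
rmst.km_curve <- function(x, horizon, profile = NULL, grid_size = 2001L) {
  jumps <- x$time[x$time < horizon]
  pts <- c(0, jumps, horizon)
  s <- c(1, km_surv_at(x, jumps))
  sum(s * diff(pts))
}

#' @export
rmst.fpm_fit <- function(x, horizon, profile = NULL, grid_size = 2001L) {
  if (is.null(profile)) stop("model-based rmst needs a covariate profile")
  t <- seq(horizon / grid_size, horizon, length.out = grid_size)
  s <- predict_survival(x, profile, t)
  s <- c(1, s)
  t <- c(0, t)
  sum((s[-1L] + s[-length(s)]) / 2 * diff(t))
}

#' Stability of a survival metric across generation seeds
#'
#' Fits the synthesis models once (fitting is deterministic given the
#' source) and regenerates a full synthetic dataset per seed, computing
#' the Kaplan-Meier restricted mean survival time for each; the source
#' value is attached as reference.
#'
#' @param source a `tte_dataset`.
#' @param seeds integer vector of at least 2 distinct generation seeds.
#' @param horizon_years RMST horizon in years.
#' @param n synthetic size per seed (default: source size).
#' @param spec,cov_ctl model settings as in [run_pipeline()].
#' @param fits optional prefitted model bundle (from a `synth_result`'s
#'   `fits` element) to reuse.
#' @return data frame with `seed` and `rmst_years`, with the source RMST
#'   in attribute `source_rmst`.
#' @export
seed_stability <- function(source, seeds, horizon_years = 10,
                           n = nrow(source), spec = NULL,
                           cov_ctl = cov_control(), fits = NULL) {
  if (length(seeds) < 2L) stop("need at least 2 seeds")
  if (is.null(fits)) {
    fits <- fit_synthesis_models(source, spec = spec, cov_ctl = cov_ctl)
  }
  src_km <- km_estimate(source$survival_days / 365.24, source$vital_status == "dead")
  ref <- rmst(src_km, horizon_years)
  vals <- vapply(seeds, function(s) {
    synth <- generate_synthetic(fits, n, s)
    km <- km_estimate(synth$survival_days / 365.24, synth$vital_status == "dead")
    rmst(km, horizon_years)
  }, numeric(1))
  structure(data.frame(seed = as.integer(seeds), rmst_years = vals),
            source_rmst = ref)
}

#' Disclosure-risk report for one probe record
#'
#' Generates `n_synth` synthetic individuals forced to the probe's exact
#' covariate profile (survival times from the fitted model, diagnosis
#' dates uniform within the probe's diagnosis year, vital status and
#' censoring reconstructed as in the pipeline) and reports how often
#' their date and time information falls near the probe's: the share of
#' synthetic diagnosis dates and survival times within the +/- window,
#' the synthetic vital-status split, and exact-day survival-time
#' matches. Times for the fixed profile are inverted on a dense
#' log-time grid (interpolation error far below one day).
#'
#' @param probe one-row `tte_dataset` slice (complete covariates).
#' @param fits fitted model bundle (`synth_result$fits`).
#' @param n_synth number of synthetic individuals (>= 1).
#' @param window_days half-width of the matching window in days.
#' @return one-row data frame (class `privacy_report`).
#' @export
privacy_match_report <- function(probe, fits, n_synth = 1e5L,
                                 window_days = 15L) {
  n_synth <- as.integer(n_synth)
  if (n_synth < 1L) stop("n_synth must be >= 1")
  schema <- fits$schema
  prof <- as.data.frame(probe)[1L, schema_names(schema), drop = FALSE]
  for (nm in fits$encoded) {
    v <- as.character(prof[[nm]])
    if (is.na(v)) prof[[nm]] <- fits$missing_label
  }
  for (nm in schema_names(schema)) {
    e <- schema_entry(schema, nm)
    if (e$kind == "categorical") {
      prof[[nm]] <- factor(as.character(prof[[nm]]), levels = e$levels)
      if (is.na(prof[[nm]])) stop("probe has incomplete covariates (", nm, ")")
    }
  }
  parts <- fpm_row_parts(fits$fpm, prof)
  # dense-grid quantile inversion for the single shared profile
  k <- fits$fpm$baseline_knots
  lgrid <- seq(k[1L] - 12, k[length(k)] + log(1e4), length.out = 4001L)
  pr1 <- list(xb = parts$xb[1L], gamma = parts$gamma,
              tde_mult = if (is.null(parts$tde_mult)) NULL else parts$tde_mult[1L, , drop = FALSE])
  eg <- eta_at(list(xb = rep(pr1$xb, length(lgrid)), gamma = pr1$gamma,
                    tde_mult = if (is.null(pr1$tde_mult)) NULL else
                      pr1$tde_mult[rep(1L, length(lgrid)), , drop = FALSE]),
               fits$fpm, lgrid)
  u <- stats::runif(n_synth)
  target <- log(-log(u))
  lt <- stats::approx(eg, lgrid, xout = target, rule = 2)$y
  days <- pmax(as.integer(ceiling(exp(lt) * 365.24)), 1L)
  yearcov <- schema_year_covariate(schema)
  yr <- as.integer(as.character(prof[[yearcov]]))
  dates <- assign_diagnosis_dates(rep(yr, n_synth))
  vital <- code_vital_status(days, fits$censoring$last_exit_time_days)
  cohort <- data.frame(diagnosis_date = dates, raw_time_days = days,
                       vital_status = vital)
  cohort <- apply_admin_censoring(cohort, fits$censoring)
  probe_date <- as.Date(probe$diagnosis_date[1L])
  probe_days <- as.integer(probe$survival_days[1L])
  date_match <- mean(abs(as.integer(cohort$diagnosis_date - probe_date)) <= window_days)
  time_match <- mean(abs(cohort$recorded_time_days - probe_days) <= window_days)
  exact <- sum(cohort$recorded_time_days == probe_days)
  out <- data.frame(
    n_synth = n_synth,
    pct_alive = round(100 * mean(cohort$vital_status == "alive"), 2),
    pct_dead = round(100 * mean(cohort$vital_status == "dead"), 2),
    pct_date_within_window = round(100 * date_match, 2),
    pct_time_within_window = round(100 * time_match, 2),
    exact_time_matches = exact)
  class(out) <- c("privacy_report", "data.frame")
  out
}

#' Frequency of covariate patterns across replicate synthetic datasets
#'
#' Generates `n_datasets` synthetic covariate tables of `n_per_dataset`
#' rows each and records, per probe pattern, the fraction of datasets in
#' which the full pattern occurs at least once.
#'
#' @param patterns data frame of covariate patterns (one per row,
#'   columns = schema covariates).
#' @param cov_models a `covariate_model_set`.
#' @param n_datasets number of replicate datasets (>= 1).
#' @param n_per_dataset rows per replicate.
#' @param cov_ctl a [cov_control()].
#' @param digits rounding applied to continuous covariates before
#'   matching (full patterns include e.g. integer age).
#' @return numeric vector of presence fractions, one per pattern.
#' @export
pattern_frequency_audit <- function(patterns, cov_models, n_datasets,
                                    n_per_dataset, cov_ctl = cov_control(),
                                    digits = 0L) {
  n_datasets <- as.integer(n_datasets)
  if (n_datasets < 1L) stop("n_datasets must be >= 1")
  cols <- cov_models$fit_order
  key <- function(df) {
    parts <- lapply(cols, function(cn) {
      x <- df[[cn]]
      if (is.numeric(x)) format(round(x, digits)) else as.character(x)
    })
    do.call(paste, c(parts, sep = "\r"))
  }
  probe_keys <- key(patterns)
  hits <- numeric(length(probe_keys))
  for (i in seq_len(n_datasets)) {
    tab <- sample_covariates(cov_models, n_per_dataset, cov_ctl)
    kk <- unique(key(tab))
    hits <- hits + as.numeric(probe_keys %in% kk)
  }
  hits / n_datasets
}
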