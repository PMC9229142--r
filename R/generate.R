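# Generation of synthetic survival times by inversion, calendar-date
# reconstruction, and replication of administrative censoring.

# eta pieces that are constant in time for each row of a covariate table.
fpm_row_parts <- function(fit, covariates) {
  bd <- build_design(covariates, fit$spec, layout = fit$layout)
  X <- bd$X
  cf <- fit$coefficients
  nb <- fit$spec$baseline_df
  main_idx <- 1L + nb + seq_len(ncol(X))
  xb <- cf[1L] + if (ncol(X)) drop(X %*% cf[main_idx]) else 0
  tde_x <- NULL
  tde_c <- NULL
  if (length(fit$spec$tde)) {
    # per tde basis column b, the row-specific multiplier sum_a x_a * c_{a,b}
    q <- fit$spec$tde_df
    tde_x <- matrix(0, nrow(covariates), q)
    pos <- 1L + nb + ncol(X)
    for (term in fit$spec$tde) {
      idx <- fit$term_cols[[term]]
      for (a in seq_along(idx)) {
        cc <- cf[pos + seq_len(q)]
        tde_x <- tde_x + outer(X[, idx[a]], cc)
        pos <- pos + q
      }
    }
  }
  gam <- cf[1L + seq_len(nb)]
  list(xb = xb, gamma = gam, tde_mult = tde_x)
}

# eta(lnt) for all rows simultaneously, each row at its own log time.
eta_at <- function(parts, fit, lnt) {
  bb <- rcs_basis(lnt, fit$baseline_knots)
  eta <- parts$xb + drop(bb$basis %*% parts$gamma)
  if (!is.null(parts$tde_mult)) {
    tb <- rcs_basis(lnt, fit$tde_knots)$basis
    eta <- eta + rowSums(tb * parts$tde_mult)
  }
  eta
}

#' Invert the fitted survival function at a uniform draw
#'
#' Solves `S(t | x) = u` for `t` on the log-time axis: the bracket
#' around the observed event-time range is expanded geometrically until
#' the root is enclosed (hard cap at 1e4 times the largest observed
#' time), then refined by Brent's method to `|S(t) - u| < 1e-8`. Larger
#' `u` maps to smaller `t`. If `u` is below the survival probability at
#' the capped horizon, the capped time is returned with a warning and a
#' `capped` attribute.
#'
#' @param fit an `fpm_fit`.
#' @param profile one-row data frame of covariates.
#' @param u uniform value in (0, 1).
#' @return positive time (model time unit, years).
#' @export
invert_survival_time <- function(fit, profile, u) {
  if (length(u) != 1L || !is.finite(u) || u <= 0 || u >= 1) {
    stop("u must be a single value in (0, 1)")
  }
  parts <- fpm_row_parts(fit, profile)
  target <- log(-log(u))
  f <- function(lnt) eta_at(parts, fit, lnt) - target
  k <- fit$baseline_knots
  lo <- k[1L] - 5
  hi <- k[length(k)] + 5
  cap <- k[length(k)] + log(1e4)
  floor_ <- k[1L] - 40
  while (f(lo) > 0 && lo > floor_) lo <- lo - 2
  capped <- FALSE
  while (f(hi) < 0 && hi < cap) hi <- hi + 2
  if (f(hi) < 0) {
    warning("u below survival at the bracket ceiling; returning capped horizon")
    return(structure(exp(cap), capped = TRUE))
  }
  r <- stats::uniroot(f, lower = lo, upper = hi, tol = 1e-12, maxiter = 1000L)
  structure(exp(r$root), capped = capped)
}

# Vectorized inversion: one bisection per binary digit, all rows at once.
invert_times_vec <- function(fit, parts, u) {
  n <- length(u)
  target <- log(-log(u))
  k <- fit$baseline_knots
  lo <- rep(k[1L] - 5, n)
  hi <- rep(k[length(k)] + 5, n)
  cap <- k[length(k)] + log(1e4)
  floor_ <- k[1L] - 40
  # expand brackets where needed (eta is increasing in lnt for valid fits)
  for (it in 1:40) {
    need <- eta_at(parts, fit, lo) > target & lo > floor_
    if (!any(need)) break
    lo[need] <- lo[need] - 2
  }
  capped <- rep(FALSE, n)
  for (it in 1:40) {
    need <- eta_at(parts, fit, hi) < target & hi < cap
    if (!any(need)) break
    hi[need] <- pmin(hi[need] + 2, cap)
  }
  still <- eta_at(parts, fit, hi) < target
  if (any(still)) {
    capped[still] <- TRUE
    warning(sum(still), " draw(s) below survival at the bracket ceiling; capped")
  }
  for (it in 1:52) {
    mid <- (lo + hi) / 2
    below <- eta_at(parts, fit, mid) < target
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
  }
  t <- exp((lo + hi) / 2)
  t[capped] <- exp(cap)
  structure(t, capped = capped)
}

#' Generate synthetic survival times for a covariate table
#'
#' Draws one independent uniform per row (from the current R random
#' stream), inverts the fitted survival function conditional on that
#' row's covariates, converts to days and rounds *up* to a whole day
#' (minimum 1 day).
#'
#' @param fit an `fpm_fit`.
#' @param covariates data frame conforming to the fit's design layout.
#' @return integer vector of day counts, with the uniform draws in
#'   attribute `u` and capping flags in attribute `capped`.
#' @export
generate_times <- function(fit, covariates) {
  parts <- fpm_row_parts(fit, covariates)
  u <- stats::runif(nrow(covariates))
  t_years <- invert_times_vec(fit, parts, u)
  days <- as.integer(ceiling(t_years * 365.24))
  days[days < 1L] <- 1L
  structure(days, u = u, capped = attr(t_years, "capped"))
}

#' Reconstruct diagnosis dates from calendar years
#'
#' Month and day of diagnosis are drawn uniformly over the days of each
#' record's own calendar year (365 or 366 for leap years).
#'
#' @param years integer vector of calendar years.
#' @return vector of `Date` values.
#' @export
assign_diagnosis_dates <- function(years) {
  years <- as.integer(years)
  if (anyNA(years)) stop("invalid year")
  start <- as.Date(paste0(years, "-01-01"))
  ndays <- as.integer(as.Date(paste0(years, "-12-31")) - start) + 1L
  offs <- floor(stats::runif(length(years)) * ndays)
  offs[offs >= ndays] <- ndays[offs >= ndays] - 1L
  start + offs
}

#' Pre-code vital status from the last observed exit time
#'
#' A synthetic subject is coded dead if its generated survival time does
#' not exceed the last observed exit time (in days) of the source data;
#' the boundary is inclusive (time equal to the threshold is dead).
#'
#' @param times_days integer day counts.
#' @param last_exit_days positive threshold in days.
#' @return character vector of "dead"/"alive".
#' @export
code_vital_status <- function(times_days, last_exit_days) {
  if (last_exit_days <= 0) stop("threshold must be positive")
  ifelse(times_days <= last_exit_days, "dead", "alive")
}

#' Apply administrative censoring to a synthetic cohort
#'
#' Exit dates are diagnosis date plus the raw generated time; any exit
#' beyond the administrative censoring date is recoded alive with exit
#' at the censoring date ("exceeds" is strict: a time landing exactly on
#' the censoring date keeps its event status).
#'
#' @param cohort data frame with `diagnosis_date`, `raw_time_days` and
#'   `vital_status` columns.
#' @param censoring a `censoring_info` from [derive_censoring()].
#' @return the cohort with `exit_date`, `recorded_time_days` and updated
#'   `vital_status`.
#' @export
apply_admin_censoring <- function(cohort, censoring) {
  stopifnot(inherits(censoring, "censoring_info"))
  cdate <- censoring$admin_censor_date
  if (any(cohort$diagnosis_date > cdate)) {
    stop("diagnosis date after the administrative censoring date")
  }
  exit <- cohort$diagnosis_date + cohort$raw_time_days
  over <- exit > cdate
  cohort$exit_date <- exit
  cohort$exit_date[over] <- cdate
  cohort$vital_status[over] <- "alive"
  cohort$recorded_time_days <- as.integer(ifelse(over,
    as.integer(cdate - cohort$diagnosis_date), cohort$raw_time_days))
  cohort
}

# Fit stage shared by run_pipeline and seed_stability: sequential covariate
# models + FPM + censoring metadata, all deterministic given the source.
fit_synthesis_models <- function(source, schema = NULL,
                                 cov_ctl = cov_control(),
                                 spec = NULL, missing_label = "Missing") {
  if (is.null(schema)) schema <- dataset_schema(source)
  censoring <- derive_censoring(source)
  ds <- source
  encoded <- character()
  for (nm in schema_names(schema)) {
    e <- schema_entry(dataset_schema(ds), nm)
    if (e$kind == "categorical" && anyNA(ds[[nm]])) {
      ds <- encode_missing_as_level(ds, nm, missing_label)
      encoded <- c(encoded, nm)
    }
  }
  if (is.null(spec)) spec <- colon_fpm_spec()
  cov_models <- fit_covariate_sequence(ds, control = cov_ctl)
  fpm <- fit_fpm(ds, spec)
  list(cov_models = cov_models, fpm = fpm, censoring = censoring,
       schema = dataset_schema(ds), encoded = encoded,
       missing_label = missing_label, cov_ctl = cov_ctl)
}

# Generation stage: everything downstream of the fitted models.
generate_synthetic <- function(fits, n, seed) {
  set.seed(seed)
  covtab <- sample_covariates(fits$cov_models, n, fits$cov_ctl)
  days <- generate_times(fits$fpm, covtab)
  schema <- fits$schema
  yearcov <- schema_year_covariate(schema)
  if (is.null(yearcov)) stop("schema has no calendar-year covariate; cannot reconstruct dates")
  years <- as.integer(as.character(covtab[[yearcov]]))
  diag_dates <- assign_diagnosis_dates(years)
  vital <- code_vital_status(days, fits$censoring$last_exit_time_days)
  cohort <- data.frame(covtab,
                       diagnosis_date = diag_dates,
                       raw_time_days = as.integer(days),
                       vital_status = vital,
                       check.names = FALSE)
  cohort <- apply_admin_censoring(cohort, fits$censoring)
  df <- cohort
  df$survival_days <- df$recorded_time_days
  df$raw_time_days <- NULL
  df$recorded_time_days <- NULL
  df$patient_id <- sprintf("S%06d", seq_len(n))
  synth <- tte_dataset(df, schema)
  for (nm in fits$encoded) synth <- restore_missing(synth, nm, fits$missing_label)
  attr(synth, "u") <- attr(days, "u")
  attr(synth, "capped") <- attr(days, "capped")
  synth
}

#' Run the full synthesis pipeline
#'
#' Executes every stage in order: censoring metadata derivation, missing
#' encoding, sequential covariate model fitting, FPM fitting, covariate
#' sampling, survival-time inversion, date reconstruction, vital-status
#' coding, administrative censoring, and missing restoration. Fully
#' reproducible given `(source, spec, seed)`.
#'
#' @param source a `tte_dataset` with attached schema.
#' @param n number of synthetic records (default: source size).
#' @param seed integer seed for the generation stage.
#' @param spec an [fpm_spec()] for the survival model (default
#'   [colon_fpm_spec()]).
#' @param cov_ctl a [cov_control()].
#' @param missing_label label for missing-encoded factor levels.
#' @return a `synth_result` list: `synthetic` (a `tte_dataset`), the
#'   fitted `cov_models` and `fpm`, the `censoring` info and the seed.
#' @export
run_pipeline <- function(source, n = nrow(source), seed = 1L,
                         spec = NULL, cov_ctl = cov_control(),
                         missing_label = "Missing") {
  n <- as.integer(n)
  if (is.na(n) || n <= 0L) stop("n must be a positive integer")
  fits <- fit_synthesis_models(source, spec = spec, cov_ctl = cov_ctl,
                               missing_label = missing_label)
  synth <- generate_synthetic(fits, n, seed)
  structure(list(synthetic = synth, cov_models = fits$cov_models,
                 fpm = fits$fpm, censoring = fits$censoring,
                 fits = fits, seed = as.integer(seed), source_n = nrow(source)),
            class = "synth_result")
}

#' @export
print.synth_result <- function(x, ...) {
  cat("<synth_result> ", nrow(x$synthetic), " synthetic records (seed ",
      x$seed, ")\n", sep = "")
  cat("  admin censoring date: ", format(x$censoring$admin_censor_date), "\n", sep = "")
  invisible(x)
}
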