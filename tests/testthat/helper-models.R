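# Shared helpers: hand-built model objects with known closed forms, and a
# memoized full-scale fixture pipeline reused by several test files.

# FPM fit object with log H(t) = g0 + g1 * log t (+ one linear covariate
# x with coefficient b): Weibull with shape g1 and rate exp(g0 + b x).
toy_fpm <- function(g0, g1, b = NULL) {
  if (is.null(b)) {
    spec <- fpm_spec(baseline_df = 1L)
    layout <- list(factors = list(), continuous = list())
    term_cols <- list()
    cf <- c(`(Intercept)` = g0, lnt.s1 = g1)
  } else {
    spec <- fpm_spec(baseline_df = 1L, factors = "g")
    layout <- list(factors = list(g = c("a", "b")), continuous = list())
    term_cols <- list(g = 1L)
    cf <- c(`(Intercept)` = g0, lnt.s1 = g1, `g=b` = b)
  }
  structure(list(spec = spec, layout = layout, term_cols = term_cols,
                 baseline_knots = c(log(0.05), log(20)), tde_knots = NULL,
                 coefficients = cf, loglik = NA_real_,
                 convergence = list(converged = TRUE),
                 n = 0L, n_events = 0L, time_unit = "years"),
            class = "fpm_fit")
}

no_covariates <- function(n = 1L) data.frame(row.names = seq_len(n))

# Kaplan-Meier curve of a tte_dataset (time in years), optional row filter.
km_of <- function(ds, rows = NULL) {
  if (!is.null(rows)) {
    ds <- as.data.frame(ds)[rows, ]
  }
  km_estimate(ds$survival_days / 365.24, ds$vital_status == "dead")
}

# Memoized study-scale fixture run: colon-like source of 9,064 records
# (fixture seed 1) pushed through the full pipeline (generation seed 2).
.cache <- new.env(parent = emptyenv())

study_source <- function() {
  if (is.null(.cache$source)) .cache$source <- make_colon_fixture(n = 9064L, seed = 1L)
  .cache$source
}

study_fits <- function() {
  if (is.null(.cache$fits)) {
    .cache$fits <- survsynth:::fit_synthesis_models(study_source())
  }
  .cache$fits
}

study_synthetic <- function() {
  if (is.null(.cache$synthetic)) {
    .cache$synthetic <- survsynth:::generate_synthetic(study_fits(), 9064L, 2L)
  }
  .cache$synthetic
}

# Small fixture for cheap unit tests.
small_source <- function() {
  if (is.null(.cache$small)) .cache$small <- make_colon_fixture(n = 1500L, seed = 4L)
  .cache$small
}

small_fits <- function() {
  if (is.null(.cache$small_fits)) {
    .cache$small_fits <- survsynth:::fit_synthesis_models(
      small_source(), spec = fpm_spec(baseline_df = 3L,
                                      factors = c("stage", "sex", "subsite"),
                                      continuous = list(age = 2L),
                                      tde = "stage", tde_df = 2L))
  }
  .cache$small_fits
}
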