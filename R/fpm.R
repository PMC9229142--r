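#' Winsorize a numeric vector at given percentiles
#'
#' Values below the lower percentile are replaced by it, values above
#' the upper percentile by it; interior values are untouched.
#' Percentiles use the linear-interpolation definition
#' (`quantile(type = 7)`).
#'
#' @param values non-empty numeric vector.
#' @param low_pct,high_pct percentile bounds, `0 <= low < high <= 100`.
#' @return winsorized vector.
#' @export
winsorize <- function(values, low_pct = 2, high_pct = 98) {
  if (!length(values)) stop("empty vector")
  if (!(low_pct >= 0 && low_pct < high_pct && high_pct <= 100)) {
    stop("need 0 <= low_pct < high_pct <= 100")
  }
  q <- stats::quantile(values, c(low_pct, high_pct) / 100, type = 7, names = FALSE)
  pmin(pmax(values, q[1L]), q[2L])
}

#' Specification of a flexible parametric survival model
#'
#' Describes the log-cumulative-hazard model
#' `log H(t|x) = s(log t; gamma) + x beta + sum_j s_j(log t) x_j`,
#' where `s` is a restricted cubic spline of log time with `baseline_df`
#' basis columns, continuous covariates enter as restricted cubic
#' splines, and the covariates named in `tde` get time-dependent effects
#' through interactions with a second log-time spline of `tde_df`
#' columns.
#'
#' @param baseline_df basis columns of the baseline log-time spline.
#' @param factors character vector of categorical covariate names
#'   (reference-coded dummies).
#' @param continuous named list mapping continuous covariate names to
#'   their spline degrees of freedom (basis columns).
#' @param interactions list of length-2 character vectors; each pair of
#'   terms contributes all products of their columns.
#' @param tde character vector of terms with time-dependent effects;
#'   each must also appear as a main effect.
#' @param tde_df basis columns of the time-dependent-effect spline.
#' @param winsor percentile bounds applied to every continuous covariate
#'   before the spline basis is built (stabilizes fitting in sparse
#'   tails).
#' @return an `fpm_spec` object.
#' @export
fpm_spec <- function(baseline_df = 5L, factors = character(),
                     continuous = list(), interactions = list(),
                     tde = character(), tde_df = 3L,
                     winsor = c(2, 98)) {
  baseline_df <- as.integer(baseline_df)
  if (baseline_df < 1L) stop("baseline_df must be >= 1")
  main <- c(factors, names(continuous))
  if (!all(tde %in% main)) stop("every tde term must also be a main effect")
  for (p in interactions) {
    if (length(p) != 2L || !all(p %in% main)) {
      stop("interactions must be pairs of main-effect terms")
    }
  }
  structure(list(baseline_df = baseline_df, factors = factors,
                 continuous = continuous, interactions = interactions,
                 tde = tde, tde_df = as.integer(tde_df), winsor = winsor),
            class = "fpm_spec")
}

#' Model specification used for the colon-cancer-style replication
#'
#' Baseline spline with 5 df; stage, sex and anatomical subsite as
#' factors; age as a 3-df restricted cubic spline (winsorized at the
#' 2nd/98th percentiles); two-way interactions between the age spline
#' and stage/subsite/sex plus stage-by-sex; time-dependent effects
#' (3 df) for age and stage.
#'
#' @param stage_levels levels of the stage factor as present in the data
#'   (after missing-encoding).
#' @param age_df spline df for age.
#' @return an `fpm_spec`.
#' @export
colon_fpm_spec <- function(stage_levels = NULL, age_df = 3L) {
  fpm_spec(baseline_df = 5L,
           factors = c("stage", "sex", "subsite"),
           continuous = list(age = as.integer(age_df)),
           interactions = list(c("age", "stage"), c("age", "subsite"),
                               c("age", "sex"), c("stage", "sex")),
           tde = c("age", "stage"), tde_df = 3L)
}

# ---- design construction --------------------------------------------------

#' Build the covariate design matrix for an FPM specification
#'
#' On the first call (no `layout`) the factor level sets, winsorizing
#' bounds and continuous-covariate spline knots are frozen from the
#' supplied data; passing the returned `layout` back rebuilds an
#' identical column layout for new (e.g. synthetic) rows, reusing the
#' source-fitted knots and bounds. Unseen factor levels are an error.
#'
#' @param covariates data frame of covariate values.
#' @param spec an [fpm_spec()].
#' @param layout optional layout from a previous call.
#' @return list with `X` (design matrix, no intercept), `layout`, and
#'   `term_cols` (map from term name to column indices).
#' @export
build_design <- function(covariates, spec, layout = NULL) {
  freeze <- is.null(layout)
  if (freeze) {
    layout <- list(factors = list(), continuous = list())
    for (f in spec$factors) {
      x <- covariates[[f]]
      if (is.null(x)) stop("covariate not found: ", f)
      layout$factors[[f]] <- levels(as.factor(x))
    }
    for (cn in names(spec$continuous)) {
      x <- as.numeric(covariates[[cn]])
      if (is.null(covariates[[cn]])) stop("covariate not found: ", cn)
      q <- stats::quantile(x, spec$winsor / 100, type = 7, names = FALSE)
      xw <- pmin(pmax(x, q[1L]), q[2L])
      df <- spec$continuous[[cn]]
      kn <- centile_knots(xw, seq(5, 95, length.out = df + 1L))
      layout$continuous[[cn]] <- list(bounds = q, knots = kn)
    }
  }
  n <- nrow(covariates)
  cols <- list()
  term_cols <- list()
  add <- function(name, M) {
    start <- sum(vapply(cols, ncol, integer(1)))
    cols[[length(cols) + 1L]] <<- M
    term_cols[[name]] <<- start + seq_len(ncol(M))
  }
  blocks <- list()
  for (f in spec$factors) {
    lev <- layout$factors[[f]]
    x <- as.character(covariates[[f]])
    bad <- setdiff(unique(x[!is.na(x)]), lev)
    if (length(bad)) stop("unseen level(s) in ", f, ": ", paste(bad, collapse = ", "))
    M <- vapply(lev[-1L], function(lv) as.numeric(x == lv), numeric(n))
    M <- matrix(M, nrow = n, dimnames = list(NULL, paste0(f, "=", lev[-1L])))
    blocks[[f]] <- M
    add(f, M)
  }
  for (cn in names(spec$continuous)) {
    li <- layout$continuous[[cn]]
    x <- as.numeric(covariates[[cn]])
    xw <- pmin(pmax(x, li$bounds[1L]), li$bounds[2L])
    B <- rcs_basis(xw, li$knots)$basis
    colnames(B) <- paste0(cn, ".s", seq_len(ncol(B)))
    blocks[[cn]] <- B
    add(cn, B)
  }
  for (p in spec$interactions) {
    A <- blocks[[p[1L]]]; Bm <- blocks[[p[2L]]]
    M <- matrix(0, n, ncol(A) * ncol(Bm))
    nmv <- character(ncol(A) * ncol(Bm))
    k <- 0L
    for (i in seq_len(ncol(A))) for (j in seq_len(ncol(Bm))) {
      k <- k + 1L
      M[, k] <- A[, i] * Bm[, j]
      nmv[k] <- paste0(colnames(A)[i], ":", colnames(Bm)[j])
    }
    colnames(M) <- nmv
    add(paste(p, collapse = ":"), M)
  }
  X <- if (length(cols)) do.call(cbind, cols) else matrix(numeric(0), n, 0)
  list(X = X, layout = layout, term_cols = term_cols)
}

# ---- likelihood -----------------------------------------------------------

#' Log likelihood of the log-cumulative-hazard spline model
#'
#' For `eta_i = design_i . params` and its log-time derivative
#' `etap_i = deriv_i . params`, each subject contributes
#' `d_i * (eta_i + log(etap_i) - log(t_i)) - exp(eta_i)`
#' (the log hazard at the event time for events, minus the cumulative
#' hazard for everyone). A large smooth penalty replaces `-Inf` when the
#' time-slope `etap` is non-positive at an event time, keeping
#' quasi-Newton optimization stable.
#'
#' @param params coefficient vector.
#' @param times positive event/censoring times.
#' @param events logical or 0/1 event indicators.
#' @param design matrix whose rows evaluate all model columns (including
#'   the intercept column of ones) at each subject's log time.
#' @param deriv matrix of derivatives of `design` with respect to log
#'   time (zero for time-constant columns).
#' @return scalar log likelihood (penalized when invalid).
#' @export
fpm_loglik <- function(params, times, events, design, deriv) {
  if (any(times <= 0)) stop("all times must be positive")
  events <- as.logical(events)
  eta <- drop(design %*% params)
  etap <- drop(deriv %*% params)
  H <- exp(eta)
  ed <- etap[events]
  pen <- 0
  eps <- 1e-12
  bad <- ed <= eps
  if (any(bad)) {
    pen <- 1e6 * sum((eps - ed[bad])^2) + 1e4 * sum(eps - ed[bad])
    ed[bad] <- eps
  }
  ll <- sum(eta[events] + log(ed) - log(times[events])) - sum(H)
  ll - pen
}

fpm_loglik_grad <- function(params, times, events, design, deriv) {
  events <- as.logical(events)
  eta <- drop(design %*% params)
  etap <- drop(deriv %*% params)
  H <- exp(eta)
  ed <- etap[events]
  eps <- 1e-12
  bad <- ed <= eps
  w <- numeric(length(ed))
  w[!bad] <- 1 / ed[!bad]
  g <- colSums(design[events, , drop = FALSE]) -
    colSums(design * H) +
    drop(crossprod(deriv[events, , drop = FALSE], w))
  if (any(bad)) {
    # gradient of the feasibility penalty: pushes the time-slope positive
    Db <- deriv[events, , drop = FALSE][bad, , drop = FALSE]
    g <- g + drop(crossprod(Db, 2e6 * (eps - ed[bad]) + 1e4))
  }
  g
}

# Assemble the full time-by-covariate design (and its log-time derivative)
# for given log times, covariate design X, and tde column blocks.
assemble_fpm_design <- function(lnt, X, term_cols, spec, bknots, tknots) {
  bb <- rcs_basis(lnt, bknots)
  n <- length(lnt)
  D <- cbind(`(Intercept)` = rep(1, n), bb$basis, X)
  Dp <- cbind(0, bb$deriv, matrix(0, n, ncol(X)))
  colnames(D) <- c("(Intercept)", paste0("lnt.s", seq_len(ncol(bb$basis))), colnames(X))
  tde_cols <- list()
  if (length(spec$tde)) {
    tb <- rcs_basis(lnt, tknots)
    for (term in spec$tde) {
      idx <- term_cols[[term]]
      Xt <- X[, idx, drop = FALSE]
      for (a in seq_len(ncol(Xt))) for (b in seq_len(ncol(tb$basis))) {
        nm <- paste0(colnames(Xt)[a], "#t", b)
        D <- cbind(D, Xt[, a] * tb$basis[, b])
        Dp <- cbind(Dp, Xt[, a] * tb$deriv[, b])
        colnames(D)[ncol(D)] <- nm
      }
    }
  }
  colnames(Dp) <- colnames(D)
  list(D = D, Dp = Dp)
}

# ---- fitting --------------------------------------------------------------

#' Fit a flexible parametric survival model
#'
#' Maximizes the log-cumulative-hazard spline likelihood by quasi-Newton
#' (BFGS) iteration with an analytic gradient. Baseline knots are placed
#' at the boundary and equally spaced centiles of the *uncensored* log
#' event times; time-dependent-effect splines get interior knots at the
#' 33.3/66.7 centiles. Design columns are centered and scaled internally
#' for optimizer stability and estimates mapped back, so reported
#' coefficients are on the natural scale. Start values come from a
#' Weibull (df = 1) submodel.
#'
#' @param data a `tte_dataset`, or a plain data frame of covariates when
#'   `time` and `event` are given explicitly.
#' @param spec an [fpm_spec()].
#' @param time optional numeric vector of follow-up times in years
#'   (defaults to `survival_days / 365.24` of a `tte_dataset`).
#' @param event optional logical event indicator (defaults to
#'   `vital_status == "dead"`).
#' @param control list of optimizer settings (`maxit`, `reltol`).
#' @return an `fpm_fit` with coefficients, knots, frozen design layout,
#'   log likelihood, convergence record and (co)variance estimates.
#' @export
fit_fpm <- function(data, spec, time = NULL, event = NULL,
                    control = list(maxit = 500L, reltol = 1e-10)) {
  if (inherits(data, "tte_dataset")) {
    if (is.null(time)) time <- data$survival_days / 365.24
    if (is.null(event)) event <- data$vital_status == "dead"
  }
  if (is.null(time) || is.null(event)) stop("need time and event")
  event <- as.logical(event)
  if (any(time <= 0)) stop("all times must be positive; day counts must be >= 1")
  if (!any(event)) stop("no events in the data; cannot fit a survival model")
  covdf <- as.data.frame(data)
  bd <- build_design(covdf, spec, layout = NULL)
  X <- bd$X
  lnt <- log(time)
  le <- lnt[event]
  bknots <- rcs_knots(le, spec$baseline_df)
  tknots <- if (length(spec$tde)) rcs_knots(le, spec$tde_df) else NULL
  ad <- assemble_fpm_design(lnt, X, bd$term_cols, spec, bknots, tknots)
  D <- ad$D; Dp <- ad$Dp
  P <- ncol(D)
  # center/scale all non-intercept columns
  ctr <- c(0, colMeans(D[, -1L, drop = FALSE]))
  scl <- c(1, apply(D[, -1L, drop = FALSE], 2, stats::sd))
  scl[scl == 0 | !is.finite(scl)] <- 1
  Ds <- sweep(sweep(D, 2, ctr, "-"), 2, scl, "/")
  Ds[, 1L] <- 1
  Dps <- sweep(Dp, 2, scl, "/")
  # Weibull warm start: log H = a*lnt - a*log(b)
  sr <- survival::survreg(survival::Surv(time, event) ~ 1, dist = "weibull")
  a <- 1 / sr$scale
  g0 <- -a * unname(stats::coef(sr)[1L])
  beta0 <- numeric(P)
  names(beta0) <- colnames(D)
  beta0[1L] <- g0
  beta0[2L] <- a    # first baseline column is lnt
  th0 <- beta0 * scl
  th0[1L] <- beta0[1L] + sum(beta0[-1L] * ctr[-1L])
  nll <- function(th) -fpm_loglik(th, time, event, Ds, Dps)
  gr <- function(th) -fpm_loglik_grad(th, time, event, Ds, Dps)
  opt <- stats::optim(th0, nll, gr, method = "BFGS",
                      control = list(maxit = control$maxit,
                                     reltol = control$reltol))
  if (opt$convergence != 0) {
    opt2 <- stats::optim(opt$par, nll, gr, method = "BFGS",
                         control = list(maxit = control$maxit,
                                        reltol = control$reltol))
    if (opt2$value <= opt$value) opt <- opt2
  }
  th <- opt$par
  # map back to the natural scale
  coefs <- th / scl
  coefs[1L] <- th[1L] - sum(th[-1L] * ctr[-1L] / scl[-1L])
  names(coefs) <- colnames(D)
  vcov_nat <- se <- NULL
  H <- tryCatch(stats::optimHess(th, nll, gr), error = function(e) NULL)
  if (!is.null(H)) {
    Vs <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(Vs)) {
      J <- diag(1 / scl)
      J[1L, ] <- -ctr / scl
      J[1L, 1L] <- 1
      vcov_nat <- J %*% Vs %*% t(J)
      dimnames(vcov_nat) <- list(names(coefs), names(coefs))
      se <- sqrt(pmax(diag(vcov_nat), 0))
    }
  }
  etap <- drop(Dps %*% th)
  fit <- structure(list(
    spec = spec, layout = bd$layout, term_cols = bd$term_cols,
    baseline_knots = bknots, tde_knots = tknots,
    coefficients = coefs, loglik = -opt$value,
    convergence = list(converged = opt$convergence == 0,
                       counts = opt$counts,
                       min_event_time_slope = min(etap[event])),
    vcov = vcov_nat, se = se,
    n = length(time), n_events = sum(event),
    time_unit = "years"), class = "fpm_fit")
  fit
}

#' @export
print.fpm_fit <- function(x, ...) {
  cat("<fpm_fit> log cumulative hazard spline model\n")
  cat(sprintf("  n = %d (%d events), baseline df = %d, %d parameters\n",
              x$n, x$n_events, x$spec$baseline_df, length(x$coefficients)))
  cat(sprintf("  log-likelihood %.3f, converged: %s\n", x$loglik,
              x$convergence$converged))
  invisible(x)
}

# Linear predictor eta (and slope) for one covariate profile over log times.
fpm_eta <- function(fit, profile, lnt) {
  bd <- build_design(profile, fit$spec, layout = fit$layout)
  Xrow <- bd$X
  cf <- fit$coefficients
  nb <- fit$spec$baseline_df
  bb <- rcs_basis(lnt, fit$baseline_knots)
  eta <- cf[1L] + drop(bb$basis %*% cf[1L + seq_len(nb)])
  etap <- drop(bb$deriv %*% cf[1L + seq_len(nb)])
  main_idx <- 1L + nb + seq_len(ncol(Xrow))
  if (ncol(Xrow)) eta <- eta + sum(Xrow[1L, ] * cf[main_idx])
  if (length(fit$spec$tde)) {
    tb <- rcs_basis(lnt, fit$tde_knots)
    pos <- 1L + nb + ncol(Xrow)
    for (term in fit$spec$tde) {
      idx <- fit$term_cols[[term]]
      xv <- Xrow[1L, idx]
      for (a in seq_along(idx)) {
        cc <- cf[pos + seq_len(fit$spec$tde_df)]
        eta <- eta + xv[a] * drop(tb$basis %*% cc)
        etap <- etap + xv[a] * drop(tb$deriv %*% cc)
        pos <- pos + fit$spec$tde_df
      }
    }
  }
  list(eta = eta, etap = etap)
}

#' Predicted survival probability
#'
#' `S(t | x) = exp(-exp(eta(log t, x)))`, monotone non-increasing in `t`
#' for any valid fit.
#'
#' @param fit an `fpm_fit`.
#' @param profile one-row data frame of covariate values.
#' @param t positive times (in the model's time unit, years).
#' @return survival probabilities in (0, 1].
#' @export
predict_survival <- function(fit, profile, t) {
  if (any(t <= 0)) stop("t must be positive")
  stopifnot(nrow(profile) == 1L)
  e <- fpm_eta(fit, profile, log(t))
  exp(-exp(e$eta))
}

#' Predicted hazard rate
#'
#' `h(t | x) = exp(eta) * (d eta / d log t) / t`. Errors if the model's
#' time-slope is non-positive at any requested time (the fit is invalid
#' there).
#'
#' @inheritParams predict_survival
#' @return non-negative hazard values.
#' @export
predict_hazard <- function(fit, profile, t) {
  if (any(t <= 0)) stop("t must be positive")
  stopifnot(nrow(profile) == 1L)
  e <- fpm_eta(fit, profile, log(t))
  if (any(e$etap <= 0)) stop("non-positive time-slope at requested time(s)")
  exp(e$eta) * e$etap / t
}
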