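#' Inverse-normal-rank transformation
#'
#' Maps a numeric vector to standard-normal quantiles of its tie-averaged
#' ranks, `z_i = qnorm((r_i - 0.5) / n)`. The transform is order
#' preserving and yields an approximately standard-normal intermediate
#' variable regardless of the shape of the input distribution.
#'
#' @param values numeric vector (finite).
#' @return numeric vector of the same length on the z scale.
#' @examples
#' inverse_normal_rank(c(5, 1, 9))
#' @export
inverse_normal_rank <- function(values) {
  if (!length(values)) stop("empty input")
  if (any(!is.finite(values))) stop("non-finite values in input")
  r <- rank(values, ties.method = "average")
  stats::qnorm((r - 0.5) / length(values))
}

#' Default modelling order for the sequential conditional models
#'
#' Continuous covariates come first (so their effect can be imparted on
#' every factor model), then categorical covariates in ascending order
#' of level count (least to most distributional complexity). An explicit
#' `model_order` in the schema overrides the heuristic for that
#' covariate: explicitly ordered covariates are placed first, sorted by
#' their order value; the rest follow in heuristic order.
#'
#' @param schema a [covariate_schema()].
#' @return character vector of covariate names in modelling order.
#' @export
order_covariates <- function(schema) {
  stopifnot(inherits(schema, "covariate_schema"))
  ent <- schema$entries
  ord <- vapply(ent, `[[`, integer(1), "model_order")
  explicit <- names(ent)[!is.na(ord)]
  if (anyDuplicated(ord[!is.na(ord)])) stop("duplicate explicit model_order values")
  explicit <- explicit[order(ord[explicit])]
  rest <- setdiff(names(ent), explicit)
  kinds <- vapply(ent[rest], `[[`, character(1), "kind")
  cont <- rest[kinds == "continuous"]
  cats <- rest[kinds == "categorical"]
  nlev <- vapply(ent[cats], function(e) length(e$levels), integer(1))
  cats <- cats[order(nlev, seq_along(cats))]
  c(explicit, cont, cats)
}

#' Control settings for covariate model fitting and sampling
#'
#' @param z_knot_centiles centiles (of the rank-normal z values) at which
#'   restricted-cubic-spline knots are placed in continuous-covariate
#'   models.
#' @param prior_knot_centiles centiles at which knots are placed when a
#'   continuous covariate enters a later model as a predictor.
#' @param residual_noise logical; add a normal residual (sd = residual
#'   RMSE of the z-spline regression) when simulating continuous values.
#'   Without it sampled values collapse onto the fitted curve.
#' @param interactions logical; include the pairwise interaction between
#'   the two most recent categorical predecessors in each factor model.
#' @param decay small ridge penalty passed to [nnet::multinom()] to guard
#'   against separation in sparse level combinations.
#' @param maxit maximum multinomial fitting iterations.
#' @param round_integers logical; round simulated continuous values to
#'   integers when the source variable is integer-valued (e.g. age in
#'   whole years).
#' @return list of class `cov_control`.
#' @export
cov_control <- function(z_knot_centiles = c(5, 35, 65, 95),
                        prior_knot_centiles = c(5, 35, 65, 95),
                        residual_noise = TRUE,
                        interactions = TRUE,
                        decay = 1e-6,
                        maxit = 500L,
                        round_integers = TRUE) {
  structure(list(z_knot_centiles = z_knot_centiles,
                 prior_knot_centiles = prior_knot_centiles,
                 residual_noise = isTRUE(residual_noise),
                 interactions = isTRUE(interactions),
                 decay = decay, maxit = as.integer(maxit),
                 round_integers = isTRUE(round_integers)),
            class = "cov_control")
}

# ---- predictor layout -----------------------------------------------------
# A prior_spec freezes, at fit time, exactly how earlier covariates enter a
# model: dummy columns for categoricals (reference = first level), an RCS
# basis with source-data knots for continuous, and optionally the product
# columns for one categorical x categorical interaction. The same spec is
# replayed on synthetic rows so fit and generation share one layout.

make_prior_spec <- function(data, priors, schema_like, control) {
  terms <- list()
  for (p in priors) {
    x <- data[[p]]
    if (is.factor(x)) {
      terms[[p]] <- list(name = p, kind = "categorical", levels = levels(x))
    } else {
      kn <- centile_knots(x, control$prior_knot_centiles)
      if (length(kn) < 2L) {
        terms[[p]] <- list(name = p, kind = "linear")
      } else {
        terms[[p]] <- list(name = p, kind = "continuous", knots = kn)
      }
    }
  }
  inter <- NULL
  if (control$interactions) {
    cats <- names(terms)[vapply(terms, function(t) t$kind == "categorical", logical(1))]
    if (length(cats) >= 2L) inter <- utils::tail(cats, 2L)
  }
  list(terms = terms, interaction = inter)
}

build_prior_matrix <- function(prior_spec, data) {
  n <- nrow(data)
  cols <- list()
  for (t in prior_spec$terms) {
    x <- data[[t$name]]
    if (t$kind == "categorical") {
      x <- as.character(x)
      bad <- setdiff(unique(x), t$levels)
      if (length(bad)) stop("unseen level(s) in ", t$name, ": ", paste(bad, collapse = ", "))
      for (lv in t$levels[-1L]) {
        cols[[paste0(t$name, "=", lv)]] <- as.numeric(x == lv)
      }
    } else if (t$kind == "continuous") {
      B <- rcs_basis(as.numeric(x), t$knots)$basis
      for (j in seq_len(ncol(B))) cols[[paste0(t$name, ".s", j)]] <- B[, j]
    } else {
      cols[[t$name]] <- as.numeric(x)
    }
  }
  if (!is.null(prior_spec$interaction)) {
    a <- prior_spec$terms[[prior_spec$interaction[1L]]]
    b <- prior_spec$terms[[prior_spec$interaction[2L]]]
    xa <- as.character(data[[a$name]]); xb <- as.character(data[[b$name]])
    for (la in a$levels[-1L]) for (lb in b$levels[-1L]) {
      cols[[paste0(a$name, "=", la, ":", b$name, "=", lb)]] <-
        as.numeric(xa == la & xb == lb)
    }
  }
  if (!length(cols)) {
    return(matrix(numeric(0), nrow = n, ncol = 0))
  }
  do.call(cbind, cols)
}

# ---- fitting --------------------------------------------------------------

#' Fit the sequential conditional covariate models
#'
#' Fits one regression model per covariate, in modelling order, with all
#' earlier covariates as predictors (the first model is marginal).
#' Categorical covariates use multinomial logistic regression;
#' continuous covariates use a linear regression of the original values
#' on a restricted cubic spline of their inverse-normal-rank transform
#' (plus any prior covariates), so non-normal shapes are captured.
#'
#' @param ds a `tte_dataset` whose categorical covariates have already
#'   been missing-encoded where needed (see [encode_missing_as_level()]).
#' @param schema optional schema; defaults to the dataset's.
#' @param control a [cov_control()].
#' @param order optional explicit modelling order; defaults to
#'   [order_covariates()].
#' @return a `covariate_model_set` with one fitted model per covariate
#'   and a per-model convergence record.
#' @export
fit_covariate_sequence <- function(ds, schema = NULL, control = cov_control(),
                                   order = NULL) {
  if (is.null(schema)) schema <- dataset_schema(ds)
  if (is.null(order)) order <- order_covariates(schema)
  stopifnot(all(order %in% schema_names(schema)))
  models <- list()
  for (m in seq_along(order)) {
    nm <- order[m]
    e <- schema_entry(schema, nm)
    priors <- order[seq_len(m - 1L)]
    pspec <- make_prior_spec(ds, priors, schema, control)
    PM <- build_prior_matrix(pspec, ds)
    if (e$kind == "continuous") {
      models[[nm]] <- fit_rank_normal_model(ds[[nm]], PM, pspec, control, nm)
    } else {
      y <- ds[[nm]]
      if (anyNA(y)) {
        stop("covariate '", nm, "' has missing values; encode them as a level first")
      }
      models[[nm]] <- fit_multinomial_model(y, PM, pspec, control, nm)
    }
  }
  structure(list(models = models, fit_order = order, schema = schema),
            class = "covariate_model_set")
}

fit_rank_normal_model <- function(x, PM, pspec, control, name) {
  x <- as.numeric(x)
  if (anyNA(x)) stop("continuous covariate '", name, "' has missing values")
  z <- inverse_normal_rank(x)
  zk <- centile_knots(z, control$z_knot_centiles)
  ZB <- rcs_basis(z, zk)$basis
  colnames(ZB) <- paste0("z.s", seq_len(ncol(ZB)))
  X <- cbind(`(Intercept)` = 1, PM, ZB)
  fit <- stats::lm.fit(X, x)
  coefs <- fit$coefficients
  if (anyNA(coefs)) coefs[is.na(coefs)] <- 0
  dfres <- max(length(x) - sum(!is.na(fit$coefficients)), 1L)
  sigma <- sqrt(sum(fit$residuals^2) / dfres)
  structure(list(type = "rank_normal", name = name,
                 prior_spec = pspec, z_knots = zk,
                 coefficients = coefs, residual_sd = sigma,
                 range = range(x),
                 integer_valued = all(x == round(x)),
                 converged = TRUE),
            class = "rank_normal_model")
}

fit_multinomial_model <- function(y, PM, pspec, control, name) {
  y <- as.factor(y)
  lev0 <- levels(y)
  tab <- table(y)
  if (any(tab == 0L)) {
    stop("covariate '", name, "' has level(s) observed zero times (",
         paste(names(tab)[tab == 0L], collapse = ", "),
         "); remove them from the schema before fitting")
  }
  if (length(lev0) == 1L) {
    return(structure(list(type = "degenerate", name = name, levels = lev0,
                          prior_spec = pspec, converged = TRUE),
                     class = "multinomial_model"))
  }
  dat <- data.frame(.y = y, check.names = FALSE)
  if (ncol(PM) > 0) dat <- cbind(dat, as.data.frame(PM, check.names = FALSE))
  fml <- if (ncol(PM) > 0) stats::as.formula(paste0(".y ~ `", paste(colnames(PM), collapse = "` + `"), "`")) else .y ~ 1
  fit <- nnet::multinom(fml, data = dat, trace = FALSE,
                        maxit = control$maxit, decay = control$decay,
                        MaxNWts = 100000)
  B <- stats::coef(fit)
  if (is.null(dim(B))) B <- matrix(B, nrow = 1L, dimnames = list(levels(y)[2L], names(B)))
  # strip backticks that multinom adds around non-syntactic names
  colnames(B) <- gsub("^`|`$", "", colnames(B))
  if (!all(is.finite(B))) stop("non-finite coefficients fitting covariate '", name, "'")
  structure(list(type = "multinomial", name = name, levels = levels(y),
                 prior_spec = pspec, coefficients = B,
                 converged = fit$convergence == 0),
            class = "multinomial_model")
}

# Per-row level probabilities from a fitted multinomial model.
multinomial_probs <- function(model, data) {
  if (model$type == "degenerate") {
    P <- matrix(1, nrow(data), 1L, dimnames = list(NULL, model$levels))
    return(P)
  }
  PM <- build_prior_matrix(model$prior_spec, data)
  B <- model$coefficients
  X <- cbind(`(Intercept)` = rep(1, nrow(data)), PM)
  miss <- setdiff(colnames(B), colnames(X))
  if (length(miss)) stop("predictor layout mismatch: missing ", paste(miss, collapse = ", "))
  L <- X[, colnames(B), drop = FALSE] %*% t(B)
  E <- exp(cbind(0, L))
  P <- E / rowSums(E)
  colnames(P) <- model$levels
  P
}

# ---- sampling -------------------------------------------------------------

#' Sample synthetic covariate profiles from fitted conditional models
#'
#' Covariates are generated sequentially in the fit order: categorical
#' values are drawn from each row's conditional level probabilities;
#' continuous values are generated by drawing `z* ~ N(0,1)`, evaluating
#' the stored z-spline regression given earlier covariates, and adding a
#' normal residual of the stored residual sd. Uses the current R random
#' stream, so results are reproducible under `set.seed()`.
#'
#' @param models a `covariate_model_set` from [fit_covariate_sequence()].
#' @param n number of profiles to generate (positive).
#' @param control the [cov_control()] used at fit time (residual noise
#'   and rounding switches are honoured).
#' @return data frame of `n` synthetic covariate rows (factors carry the
#'   fitted level sets).
#' @export
sample_covariates <- function(models, n, control = cov_control()) {
  stopifnot(inherits(models, "covariate_model_set"))
  n <- as.integer(n)
  if (is.na(n) || n <= 0L) stop("n must be a positive integer")
  out <- data.frame(row.names = seq_len(n))
  for (nm in models$fit_order) {
    mod <- models$models[[nm]]
    if (inherits(mod, "rank_normal_model")) {
      z <- stats::rnorm(n)
      ZB <- rcs_basis(z, mod$z_knots)$basis
      colnames(ZB) <- paste0("z.s", seq_len(ncol(ZB)))
      PM <- build_prior_matrix(mod$prior_spec, out)
      X <- cbind(`(Intercept)` = rep(1, n), PM, ZB)
      mu <- drop(X[, names(mod$coefficients), drop = FALSE] %*% mod$coefficients)
      x <- mu + if (control$residual_noise) stats::rnorm(n, 0, mod$residual_sd) else 0
      x <- pmin(pmax(x, mod$range[1L]), mod$range[2L])
      if (control$round_integers && mod$integer_valued) x <- round(x)
      out[[nm]] <- x
    } else {
      u <- stats::runif(n)
      P <- multinomial_probs(mod, out)
      cum <- P
      K <- ncol(P)
      if (K > 1L) for (k in 2:K) cum[, k] <- cum[, k - 1L] + P[, k]
      idx <- rowSums(u > cum) + 1L
      idx[idx > K] <- K
      out[[nm]] <- factor(mod$levels[idx], levels = mod$levels)
    }
  }
  out
}
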