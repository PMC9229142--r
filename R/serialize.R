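# Structured-text (JSON) serialization of fitted model bundles, so that
# fitting and generation can run as separate invocations: models are
# stored with named coefficients, knots and layout and restored in the
# same order they were fitted.

matrix_to_list <- function(M) {
  list(values = as.numeric(M), nrow = nrow(M), ncol = ncol(M),
       rownames = rownames(M), colnames = colnames(M))
}

list_to_matrix <- function(l) {
  M <- matrix(l$values, nrow = l$nrow, ncol = l$ncol)
  rownames(M) <- l$rownames
  colnames(M) <- l$colnames
  M
}

#' Serialize a fitted covariate model set to JSON
#'
#' @param models a `covariate_model_set`.
#' @param path output file path.
#' @export
write_covariate_models <- function(models, path) {
  stopifnot(inherits(models, "covariate_model_set"))
  enc <- lapply(models$models, function(m) {
    out <- unclass(m)
    if (!is.null(out$coefficients)) {
      if (is.matrix(out$coefficients)) {
        out$coefficients <- matrix_to_list(out$coefficients)
        out$coef_is_matrix <- TRUE
      } else {
        # named vectors must go out as objects, not anonymous arrays
        out$coefficients <- as.list(out$coefficients)
      }
    }
    out
  })
  sch <- lapply(models$schema$entries, unclass)
  jsonlite::write_json(list(kind = "covariate_model_set",
                            fit_order = models$fit_order,
                            schema = sch, models = enc),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Restore a covariate model set written by [write_covariate_models()]
#'
#' @param path JSON file path.
#' @return a `covariate_model_set`.
#' @export
read_covariate_models <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE)
  stopifnot(identical(j$kind, "covariate_model_set"))
  fix_pspec <- function(ps) {
    ps$terms <- lapply(ps$terms, function(t) t)
    if (!is.null(ps$interaction) && !length(ps$interaction)) ps$interaction <- NULL
    ps
  }
  models <- lapply(j$models, function(m) {
    if (isTRUE(m$coef_is_matrix)) m$coefficients <- list_to_matrix(m$coefficients)
    m$coef_is_matrix <- NULL
    m$prior_spec <- fix_pspec(m$prior_spec)
    cls <- if (m$type == "rank_normal") "rank_normal_model" else "multinomial_model"
    if (m$type == "rank_normal") m$coefficients <- unlist(m$coefficients)
    structure(m, class = cls)
  })
  entries <- lapply(j$schema, function(e) {
    structure(list(name = e$name, kind = e$kind,
                   levels = as.character(unlist(e$levels)),
                   model_order = if (is.null(e$model_order)) NA_integer_ else as.integer(e$model_order),
                   year_role = isTRUE(e$year_role)), class = "covariate_def")
  })
  schema <- covariate_schema(entries)
  structure(list(models = models, fit_order = as.character(j$fit_order),
                 schema = schema), class = "covariate_model_set")
}

#' Serialize a fitted flexible parametric survival model to JSON
#'
#' Stores the specification, frozen design layout, knots and named
#' coefficients; the (co)variance matrix is not preserved.
#'
#' @param fit an `fpm_fit`.
#' @param path output file path.
#' @export
write_fpm <- function(fit, path) {
  stopifnot(inherits(fit, "fpm_fit"))
  out <- list(kind = "fpm_fit",
              spec = unclass(fit$spec),
              layout = fit$layout,
              term_cols = fit$term_cols,
              baseline_knots = fit$baseline_knots,
              tde_knots = fit$tde_knots,
              coefficients = as.list(fit$coefficients),
              loglik = fit$loglik,
              convergence = fit$convergence[c("converged")],
              n = fit$n, n_events = fit$n_events,
              time_unit = fit$time_unit)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Restore a survival model written by [write_fpm()]
#'
#' @param path JSON file path.
#' @return an `fpm_fit` (without variance estimates).
#' @export
read_fpm <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE)
  stopifnot(identical(j$kind, "fpm_fit"))
  spec <- j$spec
  spec$continuous <- as.list(spec$continuous)
  spec$interactions <- lapply(j$spec$interactions, unlist)
  spec$factors <- as.character(unlist(spec$factors))
  spec$tde <- as.character(unlist(spec$tde))
  class(spec) <- "fpm_spec"
  layout <- j$layout
  layout$factors <- lapply(layout$factors, function(x) as.character(unlist(x)))
  layout$continuous <- lapply(layout$continuous, function(l) {
    list(bounds = as.numeric(unlist(l$bounds)), knots = as.numeric(unlist(l$knots)))
  })
  cf <- unlist(j$coefficients)
  structure(list(spec = spec, layout = layout,
                 term_cols = lapply(j$term_cols, function(x) as.integer(unlist(x))),
                 baseline_knots = as.numeric(unlist(j$baseline_knots)),
                 tde_knots = if (is.null(j$tde_knots)) NULL else as.numeric(unlist(j$tde_knots)),
                 coefficients = cf, loglik = j$loglik,
                 convergence = list(converged = isTRUE(j$convergence$converged)),
                 vcov = NULL, se = NULL,
                 n = j$n, n_events = j$n_events,
                 time_unit = j$time_unit), class = "fpm_fit")
}
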