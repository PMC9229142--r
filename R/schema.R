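#' Declare a covariate for a time-to-event schema
#'
#' @param name column name in the data.
#' @param levels character vector of factor levels (categorical only);
#'   the first level is the modelling reference.
#' @param model_order optional positive integer fixing this covariate's
#'   position in the sequential conditional modelling order; `NA` lets
#'   [order_covariates()] apply its default heuristic.
#' @param year_role logical; `TRUE` marks this covariate as the calendar
#'   year of diagnosis, used to reconstruct diagnosis dates. At most one
#'   covariate in a schema may carry the role.
#' @return a `covariate_def` object.
#' @export
cov_categorical <- function(name, levels, model_order = NA_integer_, year_role = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  levels <- as.character(levels)
  if (length(levels) < 1L) stop("categorical covariate needs at least one level")
  structure(list(name = name, kind = "categorical", levels = levels,
                 model_order = as.integer(model_order), year_role = isTRUE(year_role)),
            class = "covariate_def")
}

#' @rdname cov_categorical
#' @export
cov_continuous <- function(name, model_order = NA_integer_) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  structure(list(name = name, kind = "continuous", levels = character(),
                 model_order = as.integer(model_order), year_role = FALSE),
            class = "covariate_def")
}

#' Covariate schema for a time-to-event dataset
#'
#' Collects [cov_categorical()] / [cov_continuous()] declarations into an
#' ordered schema describing every covariate that the synthesis pipeline
#' must model.
#'
#' @param ... `covariate_def` objects.
#' @return a `covariate_schema` object.
#' @examples
#' covariate_schema(
#'   cov_continuous("age"),
#'   cov_categorical("sex", c("Male", "Female"))
#' )
#' @export
covariate_schema <- function(...) {
  entries <- list(...)
  if (length(entries) == 1L && is.list(entries[[1L]]) &&
      !inherits(entries[[1L]], "covariate_def")) {
    entries <- entries[[1L]]
  }
  if (!length(entries)) stop("schema needs at least one covariate")
  ok <- vapply(entries, inherits, logical(1), "covariate_def")
  if (!all(ok)) stop("all schema entries must be covariate_def objects")
  nms <- vapply(entries, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("covariate names must be unique")
  yr <- vapply(entries, `[[`, logical(1), "year_role")
  if (sum(yr) > 1L) stop("at most one covariate may have the calendar-year role")
  names(entries) <- nms
  structure(list(entries = entries), class = "covariate_schema")
}

schema_names <- function(schema) names(schema$entries)

schema_entry <- function(schema, name) {
  e <- schema$entries[[name]]
  if (is.null(e)) stop("unknown covariate: ", name)
  e
}

schema_year_covariate <- function(schema) {
  yr <- vapply(schema$entries, `[[`, logical(1), "year_role")
  if (!any(yr)) return(NULL)
  names(schema$entries)[yr][1L]
}

#' @export
print.covariate_schema <- function(x, ...) {
  cat("<covariate_schema> ", length(x$entries), " covariates\n", sep = "")
  for (e in x$entries) {
    cat(sprintf("  %-12s %-11s %s%s\n", e$name, e$kind,
                if (e$kind == "categorical") paste0("[", paste(e$levels, collapse = ", "), "]") else "",
                if (e$year_role) "  (calendar year)" else ""))
  }
  invisible(x)
}

# ---- date parsing ---------------------------------------------------------

# Accepts ISO-8601 (YYYY-MM-DD) and day-first (DD/MM/YYYY).
parse_dates <- function(x, what = "date") {
  if (inherits(x, "Date")) return(x)
  x <- as.character(x)
  out <- as.Date(rep(NA_integer_, length(x)), origin = "1970-01-01")
  iso <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  dmy <- grepl("^\\d{1,2}/\\d{1,2}/\\d{4}$", x)
  out[iso] <- as.Date(x[iso], format = "%Y-%m-%d")
  out[dmy] <- as.Date(x[dmy], format = "%d/%m/%Y")
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad)) {
    stop(sprintf("cannot parse %s '%s' in row %d", what, x[bad[1L]], bad[1L]))
  }
  out
}

# ---- dataset construction -------------------------------------------------

#' Construct and validate a time-to-event dataset
#'
#' A `tte_dataset` is a data frame holding one row per patient with the
#' schema covariates plus `diagnosis_date`, `exit_date`, `survival_days`,
#' `vital_status` ("dead"/"alive") and `patient_id`. Validation enforces
#' the date contract `exit_date = diagnosis_date + survival_days`,
#' non-negative survival times, and that categorical values lie within
#' their declared level sets.
#'
#' @param df data frame of records. Either `survival_days` or `exit_date`
#'   may be omitted; the missing one is derived.
#' @param schema a [covariate_schema()].
#' @return a `tte_dataset` (data frame subclass with the schema attached).
#' @export
tte_dataset <- function(df, schema) {
  stopifnot(inherits(schema, "covariate_schema"))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (nm in schema_names(schema)) {
    if (!nm %in% names(df)) stop("missing required covariate column: ", nm)
    e <- schema_entry(schema, nm)
    if (e$kind == "categorical") {
      vals <- as.character(df[[nm]])
      vals[!is.na(vals) & vals == ""] <- NA_character_   # CSV empty field
      extra <- setdiff(unique(vals[!is.na(vals)]), e$levels)
      if (length(extra)) {
        stop(sprintf("covariate '%s' has values outside its declared levels: %s",
                     nm, paste(extra, collapse = ", ")))
      }
      df[[nm]] <- factor(vals, levels = e$levels)
    } else {
      df[[nm]] <- as.numeric(df[[nm]])
    }
  }
  if (!"diagnosis_date" %in% names(df)) stop("missing required column: diagnosis_date")
  if (!"vital_status" %in% names(df)) stop("missing required column: vital_status")
  if (!("survival_days" %in% names(df)) && !("exit_date" %in% names(df))) {
    stop("need either survival_days or exit_date")
  }
  df$diagnosis_date <- parse_dates(df$diagnosis_date, "diagnosis_date")
  if ("exit_date" %in% names(df)) df$exit_date <- parse_dates(df$exit_date, "exit_date")
  if (!"survival_days" %in% names(df)) {
    df$survival_days <- as.integer(df$exit_date - df$diagnosis_date)
  }
  df$survival_days <- as.integer(round(as.numeric(df$survival_days)))
  if (anyNA(df$survival_days)) stop("missing survival time")
  if (any(df$survival_days < 0L)) {
    stop("negative survival time in row ", which(df$survival_days < 0L)[1L])
  }
  derived_exit <- df$diagnosis_date + df$survival_days
  if (!"exit_date" %in% names(df)) {
    df$exit_date <- derived_exit
  } else if (any(df$exit_date != derived_exit)) {
    stop("exit_date and diagnosis_date + survival_days disagree in row ",
         which(df$exit_date != derived_exit)[1L])
  }
  vs <- tolower(as.character(df$vital_status))
  if (!all(vs %in% c("dead", "alive"))) stop("vital_status must be 'dead' or 'alive'")
  df$vital_status <- vs
  if (!"patient_id" %in% names(df)) {
    df$patient_id <- sprintf("P%06d", seq_len(nrow(df)))
  }
  df$patient_id <- as.character(df$patient_id)
  cols <- c("patient_id", schema_names(schema),
            "diagnosis_date", "exit_date", "survival_days", "vital_status")
  df <- df[, cols]
  attr(df, "schema") <- schema
  class(df) <- c("tte_dataset", "data.frame")
  df
}

dataset_schema <- function(ds) {
  s <- attr(ds, "schema")
  if (is.null(s)) stop("dataset has no attached schema")
  s
}

#' Read a time-to-event dataset from a delimited text file
#'
#' Reads a comma-separated file (header row, UTF-8) containing all schema
#' covariates plus `diagnosis_date`, `vital_status`, and at least one of
#' `survival_days` / `exit_date`, then validates it via [tte_dataset()].
#' Dates may be ISO-8601 (`YYYY-MM-DD`) or day-first (`DD/MM/YYYY`).
#'
#' @param path file path of a CSV table.
#' @param schema a [covariate_schema()].
#' @return a validated `tte_dataset`.
#' @export
load_dataset <- function(path, schema) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  tte_dataset(df, schema)
}

#' Write a time-to-event dataset to CSV
#'
#' Dates are serialized as ISO-8601 so that [load_dataset()] reproduces
#' the dataset value-for-value.
#'
#' @param ds a `tte_dataset`.
#' @param path output file path.
#' @export
write_dataset <- function(ds, path) {
  out <- as.data.frame(ds)
  out$diagnosis_date <- format(out$diagnosis_date, "%Y-%m-%d")
  out$exit_date <- format(out$exit_date, "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

# ---- censoring metadata ---------------------------------------------------

#' Derive the administrative censoring metadata from a dataset
#'
#' The administrative censoring date is the last observed exit date in
#' the source data; the last observed exit *time* (in days) is the
#' threshold later used to pre-code synthetic vital status. If an
#' explicit `admin_censor_date` is supplied, it is used instead (see
#' [truncate_followup()] to clamp records beyond it).
#'
#' @param ds a non-empty `tte_dataset`.
#' @param admin_censor_date optional `Date` overriding the derived date.
#' @return a `censoring_info` list with `admin_censor_date` and
#'   `last_exit_time_days`.
#' @export
derive_censoring <- function(ds, admin_censor_date = NULL) {
  if (nrow(ds) == 0L) stop("cannot derive censoring from an empty dataset")
  date <- if (is.null(admin_censor_date)) max(ds$exit_date) else as.Date(admin_censor_date)
  structure(list(admin_censor_date = date,
                 last_exit_time_days = max(ds$survival_days)),
            class = "censoring_info")
}

#' Clamp follow-up beyond an administrative censoring date
#'
#' Records whose exit date exceeds the censoring date are reassigned to
#' exit at the censoring date and recoded alive.
#'
#' @param ds a `tte_dataset`.
#' @param censoring a `censoring_info` from [derive_censoring()].
#' @return the clamped `tte_dataset`.
#' @export
truncate_followup <- function(ds, censoring) {
  stopifnot(inherits(censoring, "censoring_info"))
  over <- ds$exit_date > censoring$admin_censor_date
  if (any(over)) {
    ds$exit_date[over] <- censoring$admin_censor_date
    ds$survival_days[over] <- as.integer(censoring$admin_censor_date - ds$diagnosis_date[over])
    ds$vital_status[over] <- "alive"
  }
  ds
}

# ---- missing-data factor levels ------------------------------------------

#' Encode missing categorical values as an explicit factor level
#'
#' Absent values of a categorical covariate become their own level so
#' that missingness patterns are modelled and reproduced like any other
#' group. Invertible by [restore_missing()]. A covariate without absent
#' values is returned unchanged (the level is not added).
#'
#' @param ds a `tte_dataset`.
#' @param covariate name of a categorical covariate.
#' @param label level label for the missing group.
#' @return the updated `tte_dataset` (schema level set extended).
#' @export
encode_missing_as_level <- function(ds, covariate, label = "Missing") {
  schema <- dataset_schema(ds)
  e <- schema_entry(schema, covariate)
  if (e$kind != "categorical") {
    stop("encode_missing_as_level only supports categorical covariates")
  }
  x <- ds[[covariate]]
  if (!anyNA(x)) return(ds)
  if (label %in% levels(x)) stop("label '", label, "' already a level of ", covariate)
  v <- as.character(x)
  v[is.na(v)] <- label
  newlev <- c(e$levels, label)
  ds[[covariate]] <- factor(v, levels = newlev)
  schema$entries[[covariate]]$levels <- newlev
  attr(ds, "schema") <- schema
  ds
}

#' Restore an encoded missing level to true missing values
#'
#' All rows at the given level become `NA` and the level is removed from
#' the schema. Restoring twice errors because the label is gone.
#'
#' @inheritParams encode_missing_as_level
#' @return the updated `tte_dataset`.
#' @export
restore_missing <- function(ds, covariate, label = "Missing") {
  schema <- dataset_schema(ds)
  e <- schema_entry(schema, covariate)
  if (!label %in% e$levels) stop("label '", label, "' is not a level of ", covariate)
  v <- as.character(ds[[covariate]])
  v[v == label] <- NA_character_
  newlev <- setdiff(e$levels, label)
  ds[[covariate]] <- factor(v, levels = newlev)
  schema$entries[[covariate]]$levels <- newlev
  attr(ds, "schema") <- schema
  ds
}
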