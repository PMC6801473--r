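#' Read a daily analysis series from CSV
#'
#' Expects ISO-8601 dates in a `date` column, one row per day with no gaps
#' or duplicates, and numeric weather/pollutant/YLL columns. Errors name the
#' offending column or date; nothing is imputed.
#'
#' @param path CSV path.
#' @param required columns that must be present besides `date`.
#' @return validated data frame with `date` as `Date`.
#' @export
read_daily_series <- function(path,
                              required = c("temp", "humidity", "holiday")) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"date" %in% names(x)) stop("missing 'date' column", call. = FALSE)
  miss <- setdiff(required, names(x))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  d <- as.Date(x$date, format = "%Y-%m-%d")
  if (anyNA(d))
    stop("unparseable date at row(s): ",
         paste(utils::head(which(is.na(d)), 5L), collapse = ", "),
         call. = FALSE)
  dup <- duplicated(d)
  if (any(dup))
    stop("duplicated date: ", format(d[dup][1L]), call. = FALSE)
  if (length(d) > 1L && any(diff(as.integer(d)) != 1L)) {
    g <- which(diff(as.integer(d)) != 1L)[1L]
    stop(sprintf("date gap between %s and %s", format(d[g]),
                 format(d[g + 1L])), call. = FALSE)
  }
  for (cn in setdiff(names(x), "date")) {
    v <- suppressWarnings(as.numeric(x[[cn]]))
    if (anyNA(v) && !anyNA(x[[cn]]))
      stop(sprintf("non-numeric value in column '%s' at row %d", cn,
                   which(is.na(v))[1L]), call. = FALSE)
    x[[cn]] <- v
  }
  x$date <- d
  x
}

#' Write a daily series to CSV (ISO dates, one row per day)
#'
#' @param x daily series data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_daily_series <- function(x, path) {
  x$date <- format(as.Date(x$date), "%Y-%m-%d")
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Read a long-format period life table
#'
#' Columns `year, sex, age, ex` (expected remaining life years); `ex` must
#' be positive.
#'
#' @param path CSV path.
#' @return life table data frame.
#' @export
read_life_table <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("year", "sex", "age", "ex")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("life table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(x$ex <= 0))
    stop("life table has non-positive remaining life years", call. = FALSE)
  class(x) <- c("life_table", "data.frame")
  x
}

#' Read individual death records
#'
#' Columns `date, age, sex, icd10`; dates ISO-8601.
#'
#' @param path CSV path.
#' @return data frame of death records.
#' @export
read_deaths <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "age", "sex", "icd10")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("deaths file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  x$date <- as.Date(x$date, format = "%Y-%m-%d")
  if (anyNA(x$date)) stop("unparseable death date", call. = FALSE)
  x
}

#' Serialize a fitted model to JSON
#'
#' Stores coefficients, covariance, column layout, the temperature
#' cross-basis specification and the observed temperature series -- enough
#' to recompute any percentile-contrast effect with [read_fit_json()].
#'
#' @param fit a [yll_dlnm()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  spec <- fit$temp_cb_spec
  payload <- list(
    package_version = as.character(utils::packageVersion("tempyll")),
    response = fit$response,
    coefficients = unname(fit$coefficients),
    coef_names = names(fit$coefficients),
    vcov = unname(fit$vcov),
    sigma = fit$sigma,
    df_residual = fit$df.residual,
    n_used = fit$n_used,
    layout = fit$layout,
    temp = fit$temp,
    dates = format(fit$dates, "%Y-%m-%d"),
    temp_cb_spec = list(
      max_lag = spec$max_lag,
      var = unclass(spec$var_spec),
      lag = unclass(spec$lag_spec)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

rebuild_basis_spec <- function(s) {
  spec <- basis_spec(s$family, degree = s$degree,
                     df = s$df, knots = unlist(s$knots),
                     Boundary.knots = unlist(s$Boundary.knots),
                     intercept = isTRUE(s$intercept),
                     transform = s$transform %||% "identity")
  if (is.null(spec$knots)) spec$knots <- numeric(0)
  spec
}

#' Rebuild a fitted-model object from JSON
#'
#' Returns a `"yll_dlnm"` object sufficient for the effect functions
#' (contrasts, curves, summaries); per-day fitted values and residuals are
#' not stored.
#'
#' @param path JSON written by [write_fit_json()].
#' @return a `"yll_dlnm"` object.
#' @export
read_fit_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- crossbasis_spec(rebuild_basis_spec(p$temp_cb_spec$var),
                          rebuild_basis_spec(p$temp_cb_spec$lag),
                          p$temp_cb_spec$max_lag)
  V <- matrix(unlist(p$vcov), length(p$coefficients),
              length(p$coefficients))
  structure(list(
    coefficients = stats::setNames(p$coefficients, p$coef_names),
    vcov = V,
    sigma = p$sigma,
    df.residual = p$df_residual,
    n_used = p$n_used,
    layout = lapply(p$layout, as.integer),
    temp_cb_spec = spec,
    pollutant_cb_specs = list(),
    temp = p$temp,
    dates = as.Date(p$dates),
    response = p$response,
    call = quote(read_fit_json())
  ), class = "yll_dlnm")
}

#' Write a simulation truth surface sidecar
#'
#' Records the representation, coefficients/spec (cross-basis surfaces) and
#' reference temperature as JSON next to a simulated series.
#'
#' @param truth a `"truth_surface"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  payload <- list(kind = truth$kind, reference = truth$reference,
                  max_lag = truth$max_lag)
  if (truth$kind == "crossbasis") {
    payload$theta <- truth$theta
    payload$spec <- list(max_lag = truth$spec$max_lag,
                         var = unclass(truth$spec$var_spec),
                         lag = unclass(truth$spec$lag_spec))
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
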