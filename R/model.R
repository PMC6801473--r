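#' Fit the Gaussian distributed-lag non-linear regression for daily YLL
#'
#' Fits, by ordinary least squares, the time-series model
#'
#' `E(YLL_t) = CB(temperature) + CB(pollutants) + NS(time, df/yr x years)
#'  + NS(humidity, 3) + DOW + Holiday + intercept`
#'
#' where `CB(temperature)` is a cross-basis of a quadratic B-spline over
#' daily mean temperature (knots equally spaced across the temperature
#' range) with a natural cubic spline over `log(lag + 1)` (knots equally
#' spaced on the log-lag scale) up to `max_lag` days, and each pollutant
#' cross-basis pairs a natural cubic spline in concentration with indicator
#' strata on lags 0-1. Daily YLL is approximately Gaussian, so the identity
#' link / least-squares fit applies and lag-specific effects add exactly to
#' cumulative effects. Rows without a complete temperature lag history (the
#' first `max_lag` days) are dropped, not imputed.
#'
#' @param data a daily series data frame with columns `date` (consecutive
#'   `Date`s), `temp`, `humidity`, `holiday` (0/1), the pollutant columns
#'   named in `pollutants`, and the response column named in `response`.
#' @param response name of the YLL column to model (default `"all"`).
#' @param pollutants character vector of pollutant column names to adjust
#'   for; `character(0)` fits the unadjusted model.
#' @param max_lag maximum temperature lag in days (default 30).
#' @param temp_df,lag_df dimension of the temperature and lag bases
#'   (defaults 5 and 5: 3 equally spaced interior knots each).
#' @param temp_knots,temp_boundary optional explicit interior/boundary knots
#'   for the temperature basis (defaults: equally spaced over the data
#'   range).
#' @param pollutant_df natural-cubic dimension for each pollutant (default 3).
#' @param pollutant_max_lag pollutant lag window (default 1, i.e. lags 0-1).
#' @param df_per_year seasonal/trend spline dimension per year (default 7).
#' @param humidity_df relative-humidity spline dimension (default 3).
#' @return an object of class `"yll_dlnm"` with components `coefficients`,
#'   `vcov`, `sigma`, `df.residual`, `n_used`, `layout` (named column-index
#'   blocks), `temp_cb_spec`, `pollutant_cb_specs`, `temp` (full observed
#'   series, used for percentile contrasts), `dates`, `fitted.values`,
#'   `residuals`, `response`, `call`.
#' @seealso [lag_effect()], [cumulative_effect()], [effect_curve()],
#'   [run_sensitivity()]
#' @examples
#' sim <- simulate_daily_series(sim_config(seed = 1))
#' fit <- yll_dlnm(sim, pollutants = character(0))
#' summary(fit)
#' @export
yll_dlnm <- function(data, response = "all",
                     pollutants = intersect(c("pm10", "no2", "so2", "co", "o3"),
                                            names(data)),
                     max_lag = 30L, temp_df = 5L, lag_df = 5L,
                     temp_knots = NULL, temp_boundary = NULL,
                     pollutant_df = 3L, pollutant_max_lag = 1L,
                     df_per_year = 7L, humidity_df = 3L) {
  cl <- match.call()
  required <- c("date", "temp", "humidity", "holiday", response, pollutants)
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols))
    stop("data lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  dates <- as.Date(data$date)
  check_covariates(data, c("temp", "humidity", response, pollutants), dates)

  X <- build_design(data, pollutants = pollutants, max_lag = max_lag,
                    temp_df = temp_df, lag_df = lag_df,
                    temp_knots = temp_knots, temp_boundary = temp_boundary,
                    pollutant_df = pollutant_df,
                    pollutant_max_lag = pollutant_max_lag,
                    df_per_year = df_per_year, humidity_df = humidity_df)
  keep <- attr(X, "valid")
  layout <- attr(X, "layout")
  y <- data[[response]][keep]
  Xk <- X[keep, , drop = FALSE]
  n <- nrow(Xk); p <- ncol(Xk)
  if (n <= p)
    stop(sprintf("n = %d rows with full lag history but %d parameters", n, p),
         call. = FALSE)
  fit <- stats::lm.fit(Xk, y)
  if (fit$rank < p) {
    bad <- colnames(Xk)[is.na(fit$coefficients)]
    blocks <- vapply(bad, function(cn)
      names(layout)[vapply(layout, function(ix)
        cn %in% colnames(X)[ix], logical(1))][1L], character(1))
    stop("design is rank deficient; collinear column(s): ",
         paste(unique(paste0(bad, " [", blocks, "]")), collapse = ", "),
         call. = FALSE)
  }
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / (n - p)
  R <- qr.R(fit$qr)
  # columns may be pivoted; undo the permutation
  piv <- fit$qr$pivot
  XtXinv <- chol2inv(R)[order(piv), order(piv), drop = FALSE]
  V <- sigma2 * XtXinv
  V <- (V + t(V)) / 2
  dimnames(V) <- list(colnames(Xk), colnames(Xk))

  structure(list(
    coefficients = fit$coefficients,
    vcov = V,
    sigma = sqrt(sigma2),
    df.residual = n - p,
    n_used = n,
    layout = layout,
    temp_cb_spec = attr(X, "temp_cb_spec"),
    pollutant_cb_specs = attr(X, "pollutant_cb_specs"),
    temp = data$temp,
    dates = dates,
    fitted.values = fit$fitted.values,
    residuals = fit$residuals,
    response = response,
    design = Xk,
    call = cl
  ), class = "yll_dlnm")
}

check_covariates <- function(data, cols, dates) {
  if (length(dates) > 1L && any(diff(as.integer(dates)) != 1L)) {
    gap <- which(diff(as.integer(dates)) != 1L)[1L]
    stop(sprintf("dates must be consecutive; gap or disorder after %s",
                 format(dates[gap])), call. = FALSE)
  }
  for (cn in cols) {
    v <- data[[cn]]
    if (!is.numeric(v))
      stop(sprintf("column '%s' is not numeric", cn), call. = FALSE)
    if (anyNA(v))
      stop(sprintf("missing values in '%s' on %s", cn,
                   paste(format(utils::head(dates[is.na(v)], 5L)),
                         collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

#' Assemble the regression design matrix
#'
#' Concatenates the temperature cross-basis, one cross-basis per pollutant,
#' the long-term-trend spline, the humidity spline, six day-of-week
#' indicators (Sunday is the reference; temperature contrasts are invariant
#' to this choice), the holiday indicator and the intercept. Rows without a
#' complete temperature lag history are flagged invalid.
#'
#' @inheritParams yll_dlnm
#' @return design matrix with attributes `valid` (row mask), `layout`
#'   (named list of column-index blocks), `temp_cb_spec`,
#'   `pollutant_cb_specs`.
#' @export
build_design <- function(data, pollutants = character(0), max_lag = 30L,
                         temp_df = 5L, lag_df = 5L, temp_knots = NULL,
                         temp_boundary = NULL, pollutant_df = 3L,
                         pollutant_max_lag = 1L, df_per_year = 7L,
                         humidity_df = 3L) {
  dates <- as.Date(data$date)
  n <- nrow(data)

  cb_spec <- temp_crossbasis_spec(max_lag = max_lag, var_df = temp_df,
                                  lag_df = lag_df, var_knots = temp_knots,
                                  var_boundary = temp_boundary)
  CBt <- build_crossbasis(data$temp, cb_spec)
  valid <- attr(CBt, "valid")

  blocks <- list(temp = unclass(CBt))
  pol_specs <- list()
  for (pol in pollutants) {
    ps <- pollutant_crossbasis_spec(max_lag = pollutant_max_lag,
                                    var_df = pollutant_df)
    CBp <- build_crossbasis(data[[pol]], ps)
    valid <- valid & attr(CBp, "valid")
    pol_specs[[pol]] <- attr(CBp, "spec")
    blocks[[pol]] <- unclass(CBp)
  }

  blocks$time <- unclass(time_trend_basis(dates, df_per_year))
  blocks$humidity <- unclass(natural_cubic_basis(data$humidity,
                                                 df = humidity_df))
  wday <- as.POSIXlt(dates)$wday
  DOW <- outer(wday, 1:6, `==`) * 1
  colnames(DOW) <- paste0("dow", 1:6)
  blocks$dow <- DOW
  blocks$holiday <- matrix(as.numeric(data$holiday), ncol = 1,
                           dimnames = list(NULL, "holiday"))
  blocks$intercept <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))

  for (b in names(blocks))
    colnames(blocks[[b]]) <- paste0(b, ".", colnames(blocks[[b]]))
  X <- do.call(cbind, blocks)
  sizes <- vapply(blocks, ncol, integer(1))
  ends <- cumsum(sizes)
  layout <- stats::setNames(
    lapply(seq_along(sizes), function(i) (ends[i] - sizes[i] + 1L):ends[i]),
    names(sizes))
  structure(X, valid = valid, layout = layout,
            temp_cb_spec = attr(CBt, "spec"),
            pollutant_cb_specs = pol_specs)
}

#' @export
print.yll_dlnm <- function(x, ...) {
  cat("Gaussian DLNM for daily years of life lost\n")
  cat(sprintf("  response: %s   days used: %d (%d dropped for lag history)\n",
              x$response, x$n_used, length(x$temp) - x$n_used))
  cat("  temperature cross-basis:",
      x$temp_cb_spec$var_spec$df, "x", x$temp_cb_spec$lag_spec$df,
      "up to lag", x$temp_cb_spec$max_lag, "days\n")
  pols <- names(x$pollutant_cb_specs)
  cat("  pollutants:", if (length(pols)) paste(pols, collapse = ", ")
      else "(none)", "\n")
  cat("  residual SD:", format(x$sigma, digits = 4), "years/day on",
      x$df.residual, "df\n")
  invisible(x)
}

#' @export
summary.yll_dlnm <- function(object, ...) {
  pct <- temperature_percentiles(object$temp, c(0.01, 0.25, 0.75, 0.99))
  L <- object$temp_cb_spec$max_lag
  cold <- cumulative_effect(object, target = pct[[1L]], ref = pct[[2L]],
                            lag_max = L)
  heat <- cumulative_effect(object, target = pct[[4L]], ref = pct[[3L]],
                            lag_max = L)
  out <- list(fit = object, percentiles = pct, cold = cold, heat = heat)
  class(out) <- "summary.yll_dlnm"
  out
}

#' @export
print.summary.yll_dlnm <- function(x, ...) {
  print(x$fit)
  p <- x$percentiles
  cat(sprintf("\nTemperature percentiles (degC): 1st %.2f, 25th %.2f, 75th %.2f, 99th %.2f\n",
              p[[1L]], p[[2L]], p[[3L]], p[[4L]]))
  L <- x$fit$temp_cb_spec$max_lag
  cat(sprintf("Cumulative cold effect (25th -> 1st, lag 0-%d): %s years\n",
              L, format_effect(x$cold)))
  cat(sprintf("Cumulative heat effect (75th -> 99th, lag 0-%d): %s years\n",
              L, format_effect(x$heat)))
  invisible(x)
}

#' @export
coef.yll_dlnm <- function(object, block = NULL, ...) {
  if (is.null(block)) return(object$coefficients)
  object$coefficients[object$layout[[block]]]
}

#' @export
vcov.yll_dlnm <- function(object, block = NULL, ...) {
  if (is.null(block)) return(object$vcov)
  ix <- object$layout[[block]]
  object$vcov[ix, ix, drop = FALSE]
}

#' @export
residuals.yll_dlnm <- function(object, ...) object$residuals

#' @export
fitted.yll_dlnm <- function(object, ...) object$fitted.values

#' Simulate response series from a fitted model
#'
#' Draws Gaussian responses around the fitted values with the estimated
#' residual standard deviation (parametric bootstrap of the outcome over the
#' days actually used in the fit).
#'
#' @param object a fitted [yll_dlnm()] model.
#' @param nsim number of simulated series.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return data frame with `nsim` columns, one simulated response per column.
#' @export
simulate.yll_dlnm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- object$n_used
  out <- as.data.frame(matrix(
    stats::rnorm(n * nsim, mean = rep(object$fitted.values, nsim),
                 sd = object$sigma), n, nsim))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Predicted temperature effects from a fitted model
#'
#' The `predict` method returns percentile-contrast effect curves (the
#' quantities plotted and tabulated in this analysis) rather than per-day
#' fitted values, which are available via `fitted()`.
#'
#' @param object a fitted [yll_dlnm()] model.
#' @param contrast `"cold"` (25th to 1st temperature percentile) or `"heat"`
#'   (75th to 99th).
#' @param cumulative if `TRUE`, effects cumulated over lag windows
#'   `0-0 ... 0-max_lag`; otherwise single-day lag effects.
#' @param ... unused.
#' @return an effect-curve data frame; see [effect_curve()].
#' @export
predict.yll_dlnm <- function(object, contrast = c("cold", "heat"),
                             cumulative = FALSE, ...) {
  effect_curve(object, contrast = match.arg(contrast),
               cumulative = cumulative)
}
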