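#' Empirical temperature percentiles
#'
#' Quantiles by linear interpolation between order statistics
#' (`stats::quantile` type 7), computed on the full observed series
#' including the initial days dropped from the regression. Cold effects
#' contrast the 25th against the 1st percentile; heat effects the 75th
#' against the 99th.
#'
#' @param x temperature series.
#' @param probs probabilities strictly inside (0, 1).
#' @return named numeric vector of percentile values.
#' @export
temperature_percentiles <- function(x, probs) {
  if (!length(x)) stop("empty series", call. = FALSE)
  if (any(probs <= 0 | probs >= 1))
    stop("probs must lie strictly inside (0, 1)", call. = FALSE)
  stats::quantile(x, probs = probs, type = 7, na.rm = FALSE, names = TRUE)
}

contrast_temps <- function(fit, contrast) {
  p <- if (contrast == "cold") c(0.25, 0.01) else c(0.75, 0.99)
  q <- temperature_percentiles(fit$temp, p)
  list(ref = q[[1L]], target = q[[2L]])
}

effect_from_contrast <- function(fit, v) {
  ix <- fit$layout$temp
  beta <- fit$coefficients[ix]
  V <- fit$vcov[ix, ix, drop = FALSE]
  est <- drop(v %*% beta)
  sd <- sqrt(pmax(0, drop(v %*% V %*% v)))
  ci_low <- est - 1.96 * sd
  ci_high <- est + 1.96 * sd
  data.frame(estimate = est, ci_low = ci_low, ci_high = ci_high,
             significant = ci_low > 0 | ci_high < 0)
}

#' Single-day lag effect of a temperature contrast
#'
#' The modelled YLL difference (years) between `target` and `ref`
#' temperature at one lag day, with delta-method 95% confidence interval:
#' with contrast vector `v = (R(target) - R(ref)) (x) C(lag)` over the
#' temperature block, the estimate is `v' beta` and its variance
#' `v' Sigma v`.
#'
#' @param fit a fitted [yll_dlnm()] model.
#' @param target,ref temperatures (degC); values outside the observed range
#'   are clamped to the basis boundary with a warning.
#' @param lag lag day in `0:max_lag`.
#' @return one-row data frame: `contrast`, `lag`, `estimate`, `ci_low`,
#'   `ci_high`, `significant` (95% CI excludes 0).
#' @export
lag_effect <- function(fit, target, ref, lag) {
  spec <- fit$temp_cb_spec
  v <- crossbasis_contrast(spec, target, ref, lag)
  out <- effect_from_contrast(fit, drop(v))
  cbind(data.frame(target = target, ref = ref, lag = lag), out)
}

#' Cumulative effect of a temperature contrast over a lag window
#'
#' Sums the single-lag contrast vectors over lags `0..lag_max` before
#' applying the delta method, so the estimate equals the sum of single-lag
#' estimates exactly (identity link) while the variance correctly accounts
#' for the covariance between lags (it is not the sum of single-lag
#' variances).
#'
#' @inheritParams lag_effect
#' @param lag_max upper end of the lag window `0..lag_max`.
#' @return one-row data frame as in [lag_effect()], with `lag_max` in place
#'   of `lag`.
#' @export
cumulative_effect <- function(fit, target, ref, lag_max) {
  spec <- fit$temp_cb_spec
  if (lag_max > spec$max_lag)
    stop(sprintf("lag_max = %d exceeds max_lag = %d", lag_max, spec$max_lag),
         call. = FALSE)
  v <- colSums(crossbasis_contrast(spec, target, ref, 0:lag_max))
  out <- effect_from_contrast(fit, v)
  cbind(data.frame(target = target, ref = ref, lag_max = lag_max), out)
}

#' Full lag-effect curve for a cold or heat contrast
#'
#' Computes the effect at every lag (or every cumulative window
#' `0-0 ... 0-max_lag`) for the conventional percentile contrasts: cold is
#' the change from the 25th to the 1st percentile of the observed
#' temperature, heat from the 75th to the 99th.
#'
#' @param fit a fitted [yll_dlnm()] model.
#' @param contrast `"cold"`, `"heat"`, or a numeric `c(target, ref)` pair in
#'   degC.
#' @param cumulative cumulate over lag windows instead of single days.
#' @return data frame of class `"yll_effect_curve"`, one row per lag (or
#'   window), with columns `lag`, `estimate`, `ci_low`, `ci_high`,
#'   `significant`; attributes `contrast`, `cumulative`, `target`, `ref`.
#' @export
effect_curve <- function(fit, contrast = c("cold", "heat"),
                         cumulative = FALSE) {
  if (is.numeric(contrast)) {
    stopifnot(length(contrast) == 2L)
    target <- contrast[1L]; ref <- contrast[2L]
    label <- "custom"
  } else {
    label <- match.arg(contrast)
    ct <- contrast_temps(fit, label)
    target <- ct$target; ref <- ct$ref
  }
  L <- fit$temp_cb_spec$max_lag
  rows <- lapply(0:L, function(l)
    if (cumulative) cumulative_effect(fit, target, ref, l)[-(1:3)]
    else lag_effect(fit, target, ref, l)[-(1:3)])
  out <- cbind(data.frame(lag = 0:L), do.call(rbind, rows))
  structure(out, contrast = label, cumulative = cumulative,
            target = target, ref = ref,
            class = c("yll_effect_curve", "data.frame"))
}

format_effect <- function(e) {
  sprintf("%.2f (%.2f, %.2f)", e$estimate, e$ci_low, e$ci_high)
}

en_dash <- "\u2013"

format_runs_single <- function(runs) {
  if (!nrow(runs)) return("-")
  lab <- ifelse(runs$from == runs$to,
                paste0("Lag ", runs$from),
                paste0("Lag ", runs$from, en_dash, runs$to))
  lab[-1L] <- sub("^Lag", "lag", lab[-1L])
  paste(lab, collapse = ", ")
}

format_runs_cumulative <- function(runs) {
  if (!nrow(runs)) return("-")
  lab <- ifelse(runs$from == runs$to,
                paste0("Lag 0", en_dash, runs$from),
                paste0("Lag 0", en_dash, runs$from, " to ", runs$to))
  lab[-1L] <- sub("^Lag", "lag", lab[-1L])
  paste(lab, collapse = ", ")
}

significant_runs <- function(lags, significant) {
  sig <- which(significant)
  if (!length(sig)) return(data.frame(from = integer(0), to = integer(0)))
  brk <- c(0L, which(diff(sig) != 1L), length(sig))
  data.frame(from = lags[sig[brk[-length(brk)] + 1L]],
             to = lags[sig[brk[-1L]]])
}

#' Summarize an effect curve into significant-duration and strongest-effect
#' form
#'
#' Reduces a lag-effect curve to the three quantities conventionally
#' tabulated: the maximal runs of consecutive significant lags (formatted
#' "Lag a-b", joined by commas; cumulative curves as "Lag 0-a to b", meaning
#' windows 0-a through 0-b are all significant), the lag (or window) with
#' the largest estimate among significant lags (ties broken toward the
#' smaller lag), and that largest effect with its 95% CI. All three are "-"
#' when no lag is significant.
#'
#' @param curve a [effect_curve()] result.
#' @return list with `significant_duration`, `strongest_lag` (integer or
#'   `NA`), `strongest_label`, `highest_yll` (formatted string), and
#'   `highest` (one-row data frame or `NULL`).
#' @export
summarize_curve <- function(curve) {
  cumulative <- isTRUE(attr(curve, "cumulative"))
  runs <- significant_runs(curve$lag, curve$significant)
  duration <- if (cumulative) format_runs_cumulative(runs)
              else format_runs_single(runs)
  if (!nrow(runs)) {
    return(list(significant_duration = "-", strongest_lag = NA_integer_,
                strongest_label = "-", highest_yll = "-", highest = NULL))
  }
  sig <- curve[curve$significant, , drop = FALSE]
  best <- sig[order(-sig$estimate, sig$lag)[1L], , drop = FALSE]
  label <- if (cumulative) paste0("Lag 0", en_dash, best$lag)
           else paste0("Lag ", best$lag)
  list(significant_duration = duration,
       strongest_lag = best$lag,
       strongest_label = label,
       highest_yll = format_effect(best),
       highest = best)
}

#' Cold/heat summary table across response strata
#'
#' Fits the model for each requested stratum and emits one row per stratum
#' per contrast in the shape of the conventional summary tables: significant
#' duration, strongest lag, and the highest YLL effect with 95% CI.
#'
#' @param data daily series data frame.
#' @param strata response column names to analyse.
#' @param cumulative single-day lag effects (`FALSE`) or cumulative windows
#'   (`TRUE`).
#' @param ... passed to [yll_dlnm()].
#' @return data frame with columns `stratum`, `contrast`,
#'   `significant_duration`, `strongest`, `highest_yll`.
#' @export
effect_table <- function(data, strata = "all", cumulative = FALSE, ...) {
  rows <- list()
  for (s in strata) {
    fit <- yll_dlnm(data, response = s, ...)
    for (ct in c("cold", "heat")) {
      sm <- summarize_curve(effect_curve(fit, ct, cumulative = cumulative))
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = s, contrast = ct,
        significant_duration = sm$significant_duration,
        strongest = sm$strongest_label,
        highest_yll = sm$highest_yll,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Sensitivity analysis over modelling choices
#'
#' Refits the model over a grid of maximum lag (15-30 days), trend df per
#' year (6-10), humidity df (3-5) and pollutant adjustment (all configured
#' pollutants vs none), reporting the cumulative cold and heat effects for
#' each configuration. A failed fit is recorded in its row and the run
#' continues.
#'
#' @param data daily series data frame.
#' @param response YLL column to model.
#' @param grid data frame with any of the columns `max_lag`, `df_per_year`,
#'   `humidity_df`, `pollutants` (logical: adjust or not); defaults to the
#'   full one-at-a-time grid around the base configuration.
#' @param pollutants pollutant columns used when `pollutants = TRUE`.
#' @param ... further arguments to [yll_dlnm()].
#' @return data frame: one row per configuration with the settings, the
#'   cumulative cold and heat estimates and CIs, and an `error` column
#'   (`NA` on success).
#' @export
run_sensitivity <- function(data, response = "all", grid = NULL,
                            pollutants = intersect(c("pm10", "no2", "so2",
                                                     "co", "o3"),
                                                   names(data)), ...) {
  if (is.null(grid)) {
    base <- data.frame(max_lag = 30L, df_per_year = 7L, humidity_df = 3L,
                       pollutants = TRUE)
    grid <- rbind(
      base,
      data.frame(max_lag = 15:30, df_per_year = 7L, humidity_df = 3L,
                 pollutants = TRUE),
      data.frame(max_lag = 30L, df_per_year = 6:10, humidity_df = 3L,
                 pollutants = TRUE),
      data.frame(max_lag = 30L, df_per_year = 7L, humidity_df = 3:5,
                 pollutants = TRUE),
      data.frame(max_lag = 30L, df_per_year = 7L, humidity_df = 3L,
                 pollutants = FALSE))
    grid <- unique(grid)
  }
  defaults <- list(max_lag = 30L, df_per_year = 7L, humidity_df = 3L,
                   pollutants = TRUE)
  for (cn in names(defaults))
    if (is.null(grid[[cn]])) grid[[cn]] <- defaults[[cn]]

  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    res <- data.frame(config = i, max_lag = g$max_lag,
                      df_per_year = g$df_per_year,
                      humidity_df = g$humidity_df,
                      pollutants = g$pollutants,
                      cold_est = NA_real_, cold_lo = NA_real_,
                      cold_hi = NA_real_, heat_est = NA_real_,
                      heat_lo = NA_real_, heat_hi = NA_real_,
                      error = NA_character_, stringsAsFactors = FALSE)
    got <- tryCatch({
      fit <- yll_dlnm(data, response = response,
                      pollutants = if (g$pollutants) pollutants
                                   else character(0),
                      max_lag = g$max_lag, df_per_year = g$df_per_year,
                      humidity_df = g$humidity_df, ...)
      ctc <- contrast_temps(fit, "cold")
      cth <- contrast_temps(fit, "heat")
      cold <- cumulative_effect(fit, ctc$target, ctc$ref, g$max_lag)
      heat <- cumulative_effect(fit, cth$target, cth$ref, g$max_lag)
      res$cold_est <- cold$estimate; res$cold_lo <- cold$ci_low
      res$cold_hi <- cold$ci_high
      res$heat_est <- heat$estimate; res$heat_lo <- heat$ci_low
      res$heat_hi <- heat$ci_high
      res
    }, error = function(e) {
      res$error <- conditionMessage(e)
      res
    })
    out[[i]] <- got
  }
  do.call(rbind, out)
}
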