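#' Exposure-lag-response truth surfaces for simulation
#'
#' A truth surface is the known additive YLL contribution `f(temperature,
#' lag)` a simulated series is generated from, so that downstream estimates
#' can be checked against it. Two representations are supported:
#'
#' * `truth_crossbasis()` -- coefficients on the same cross-basis family the
#'   model fits (quadratic B-spline in temperature by natural cubic spline
#'   in log-lag, with fixed boundary knots). Data generated from such a
#'   surface come from a submodel of the fitted regression, so least-squares
#'   recovery is exactly unbiased.
#' * `truth_closed_form()` -- an arbitrary bivariate function, for
#'   misspecification experiments.
#'
#' `truth_null()` is the zero surface. Surfaces are treated as contrasts:
#' only differences `f(target, l) - f(ref, l)` matter (any lag-wise offset
#' is absorbed by the model intercept), and [true_effect()] evaluates those
#' differences.
#'
#' @param theta coefficient vector, length `var_df * lag_df`, laid out
#'   var-major like the cross-basis columns.
#' @param spec a resolved [crossbasis_spec()].
#' @param reference reference temperature (degC) at which the surface is
#'   centred to zero.
#' @return an object of class `"truth_surface"`.
#' @name truth_surface
NULL

#' @rdname truth_surface
#' @export
truth_crossbasis <- function(theta, spec, reference = 11.4) {
  stopifnot(inherits(spec, "crossbasis_spec"))
  vdf <- spec$var_spec$df; ldf <- spec$lag_spec$df
  if (is.null(vdf) || is.null(ldf))
    stop("crossbasis spec must be resolved", call. = FALSE)
  if (length(theta) != vdf * ldf)
    stop(sprintf("theta has length %d; expected %d x %d = %d",
                 length(theta), vdf, ldf, vdf * ldf), call. = FALSE)
  structure(list(kind = "crossbasis", theta = theta, spec = spec,
                 reference = reference, max_lag = spec$max_lag),
            class = "truth_surface")
}

#' @rdname truth_surface
#' @param f function of (temperature, lag) vectors returning YLL
#'   contributions in years.
#' @param max_lag largest lag (days) at which the surface is non-zero.
#' @export
truth_closed_form <- function(f, max_lag = 30L, reference = 11.4) {
  stopifnot(is.function(f))
  structure(list(kind = "closed_form", f = f, reference = reference,
                 max_lag = as.integer(max_lag)),
            class = "truth_surface")
}

#' @rdname truth_surface
#' @export
truth_null <- function(max_lag = 30L) {
  truth_closed_form(function(temp, lag) rep(0, length(temp)),
                    max_lag = max_lag)
}

#' Evaluate a truth surface
#'
#' Returns the centred contribution `f(temp, lag) - f(reference, lag)`.
#'
#' @param truth a `"truth_surface"`.
#' @param temp,lag equal-length vectors (lags in days).
#' @return numeric vector of YLL contributions (years).
#' @export
evaluate_truth <- function(truth, temp, lag) {
  stopifnot(inherits(truth, "truth_surface"))
  if (truth$kind == "closed_form")
    return(truth$f(temp, lag) - truth$f(rep(truth$reference, length(lag)), lag))
  spec <- truth$spec
  raw <- function(x, l) {
    R <- unclass(eval_basis(spec$var_spec, x))
    C <- unclass(eval_basis(spec$lag_spec, l))
    Theta <- matrix(truth$theta, spec$var_spec$df, spec$lag_spec$df,
                    byrow = TRUE)
    rowSums((R %*% Theta) * C)
  }
  raw(temp, lag) - raw(rep(truth$reference, length(lag)), lag)
}

#' True effect of a temperature contrast under a truth surface
#'
#' The quantity the fitted model's [lag_effect()]/[cumulative_effect()]
#' estimates target: `f(target, l) - f(ref, l)` per lag, or its sum over a
#' lag window.
#'
#' @param truth a `"truth_surface"`.
#' @param target,ref temperatures (degC).
#' @param lags lag days (default `0:max_lag`).
#' @param cumulative sum over `lags` instead of returning per-lag values.
#' @return numeric vector (per lag) or single number (cumulative).
#' @export
true_effect <- function(truth, target, ref, lags = 0:truth$max_lag,
                        cumulative = FALSE) {
  per_lag <- evaluate_truth(truth, rep(target, length(lags)), lags) -
    evaluate_truth(truth, rep(ref, length(lags)), lags)
  if (cumulative) sum(per_lag) else per_lag
}

#' Default simulation truth: delayed cold effect, prompt heat effect
#'
#' Projects a closed-form surface with a cold effect confined to lags 5-20
#' (YLL rising linearly below 5 degC, smooth sine-squared lag profile) and a
#' heat effect at lags 0-2 (rising above 20 degC) onto the model's own
#' cross-basis family with fixed temperature boundary knots (-20, 38 degC),
#' so the generating model is nested in the fitted one. Amplitudes are
#' scaled so the cumulative cold and heat contrasts are of the order
#' reported for a temperate semi-arid city (roughly 150-250 and 60-90 YLL
#' years respectively).
#'
#' @param cold_amp YLL years per degC below 5 degC, total across lags.
#' @param heat_amp YLL years per degC above 20 degC, total across lags.
#' @param max_lag maximum lag of the surface (days).
#' @param var_boundary temperature boundary knots for the basis.
#' @return a cross-basis `"truth_surface"`; attribute `"closed_form"` holds
#'   the pre-projection surface.
#' @export
truth_default <- function(cold_amp = 15, heat_amp = 10, max_lag = 30L,
                          var_boundary = c(-20, 38)) {
  w_cold_raw <- function(l) ifelse(l >= 5 & l <= 20, sin((l - 5) / 15 * pi)^2, 0)
  cold_norm <- sum(w_cold_raw(0:max_lag))  # lag profile integrates to 1
  w_cold <- function(l) w_cold_raw(l) / cold_norm
  w_heat <- function(l) ifelse(l %in% 0:2, c(0.5, 0.3, 0.2)[l + 1L], 0)
  g <- function(temp, lag)
    cold_amp * pmax(0, 5 - temp) * w_cold(lag) +
    heat_amp * pmax(0, temp - 20) * w_heat(lag)
  closed <- truth_closed_form(g, max_lag = max_lag)
  spec <- resolve_crossbasis_spec(
    temp_crossbasis_spec(max_lag = max_lag, var_boundary = var_boundary),
    var_boundary)
  # least-squares projection of g onto the cross-basis function space
  xg <- seq(var_boundary[1L], var_boundary[2L], length.out = 80)
  lg <- 0:max_lag
  R <- unclass(eval_basis(spec$var_spec, xg))
  C <- unclass(eval_basis(spec$lag_spec, lg))
  X <- matrix(0, length(xg) * length(lg), ncol(R) * ncol(C))
  yv <- numeric(length(xg) * length(lg))
  row <- 1L
  for (i in seq_along(xg)) for (m in seq_along(lg)) {
    X[row, ] <- as.vector(t(outer(R[i, ], C[m, ])))  # var-major layout
    yv[row] <- g(xg[i], lg[m])
    row <- row + 1L
  }
  theta <- stats::lm.fit(X, yv)$coefficients
  theta[is.na(theta)] <- 0
  out <- truth_crossbasis(theta, spec)
  attr(out, "closed_form") <- closed
  out
}
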