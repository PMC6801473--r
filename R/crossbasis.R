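#' Cross-basis specification
#'
#' Pairs a basis over the exposure values with a basis over lag days. The
#' temperature term uses a quadratic B-spline over temperature (knots equally
#' spaced across the temperature range) crossed with a natural cubic spline
#' over `log(lag + 1)` (knots equally spaced on the log scale, intercept
#' included) up to a maximum lag of 30 days; pollutant terms use a natural
#' cubic spline over concentration crossed with unconstrained indicator
#' strata on lags 0 and 1.
#'
#' @param var_spec [basis_spec()] for the exposure dimension.
#' @param lag_spec [basis_spec()] for the lag dimension (evaluated at lags
#'   `0:max_lag`; a `log1p` transform puts its knots on the log-lag scale).
#' @param max_lag maximum lag in days (>= 0).
#' @return an object of class `"crossbasis_spec"`.
#' @export
crossbasis_spec <- function(var_spec, lag_spec, max_lag) {
  stopifnot(inherits(var_spec, "basis_spec"), inherits(lag_spec, "basis_spec"))
  max_lag <- as.integer(max_lag)
  if (max_lag < 0L) stop("max_lag must be >= 0", call. = FALSE)
  structure(list(var_spec = var_spec, lag_spec = lag_spec, max_lag = max_lag),
            class = "crossbasis_spec")
}

# Default temperature cross-basis: quadratic B-spline x natural cubic on
# log(lag + 1). var_df = 5 (3 equally spaced interior knots), lag_df = 5
# (3 interior knots on the log scale, intercept included).
temp_crossbasis_spec <- function(max_lag = 30L, var_df = 5L, lag_df = 5L,
                                 var_knots = NULL, var_boundary = NULL) {
  if (max_lag > 0L) {
    lag_spec <- basis_spec("natural_cubic", df = lag_df, intercept = TRUE,
                           transform = "log1p",
                           Boundary.knots = c(0, log1p(max_lag)))
    lag_spec <- resolve_basis_spec(lag_spec, c(0, max_lag))
  } else {
    lag_spec <- resolve_basis_spec(
      basis_spec("linear_strata", knots = 0), 0)
  }
  var_spec <- basis_spec("bspline", degree = 2L,
                         df = if (is.null(var_knots)) var_df else NULL,
                         knots = var_knots, Boundary.knots = var_boundary)
  crossbasis_spec(var_spec, lag_spec, max_lag)
}

# Default pollutant cross-basis: natural cubic in concentration (df = 3),
# indicator strata over lags {0, 1}.
pollutant_crossbasis_spec <- function(max_lag = 1L, var_df = 3L) {
  lag_spec <- resolve_basis_spec(
    basis_spec("linear_strata", knots = 0:max_lag), 0:max_lag)
  crossbasis_spec(basis_spec("natural_cubic", df = var_df), lag_spec, max_lag)
}

resolve_crossbasis_spec <- function(spec, x) {
  spec$var_spec <- resolve_basis_spec(spec$var_spec, x)
  if (is.null(spec$lag_spec$knots) || spec$lag_spec$family != "linear_strata")
    spec$lag_spec <- resolve_basis_spec(spec$lag_spec, 0:spec$max_lag)
  spec
}

#' Build a cross-basis matrix from a daily exposure series
#'
#' Entry `(t, (j-1)*lag_df + k)` is `sum_{l=0}^{L} R_j(x[t-l]) * C_k(l)`
#' where `R` is the exposure basis and `C` the lag basis. The first
#' `max_lag` rows lack a complete lag history and are set to `NA` and
#' flagged invalid.
#'
#' @param x daily exposure series (length > `max_lag`).
#' @param spec a [crossbasis_spec()]; unresolved dimensions are resolved on
#'   `x` (boundary knots at the data range).
#' @return matrix with attributes `spec` (resolved) and `valid` (logical row
#'   mask); class `"crossbasis"`.
#' @export
build_crossbasis <- function(x, spec) {
  stopifnot(inherits(spec, "crossbasis_spec"))
  n <- length(x)
  L <- spec$max_lag
  if (n <= L)
    stop(sprintf("series length %d must exceed max_lag = %d", n, L),
         call. = FALSE)
  spec <- resolve_crossbasis_spec(spec, x)
  R <- unclass(eval_basis(spec$var_spec, x))
  C <- unclass(eval_basis(spec$lag_spec, 0:L))
  vdf <- ncol(R); ldf <- ncol(C)
  CB <- matrix(0, n, vdf * ldf)
  for (j in seq_len(vdf)) for (k in seq_len(ldf)) {
    col <- numeric(n)
    for (l in 0:L) {
      ck <- C[l + 1L, k]
      if (ck != 0) col[(l + 1L):n] <- col[(l + 1L):n] +
          R[seq_len(n - l), j] * ck
    }
    CB[, (j - 1L) * ldf + k] <- col
  }
  valid <- seq_len(n) > L
  CB[!valid, ] <- NA_real_
  colnames(CB) <- paste0("v", rep(seq_len(vdf), each = ldf),
                         ".l", rep(seq_len(ldf), vdf))
  structure(CB, spec = spec, valid = valid,
            class = c("crossbasis", "matrix"))
}

# Contrast rows over the cross-basis columns for target vs reference
# exposure at given single lags: (R(target) - R(ref)) (x) C(lag).
# Returns a matrix with one row per lag.
crossbasis_contrast <- function(spec, target, ref, lags) {
  if (any(lags < 0L | lags > spec$max_lag))
    stop(sprintf("lag out of range [0, %d]", spec$max_lag), call. = FALSE)
  dR <- unclass(eval_basis(spec$var_spec, target)) -
    unclass(eval_basis(spec$var_spec, ref))
  C <- unclass(eval_basis(spec$lag_spec, lags))
  vdf <- length(dR); ldf <- ncol(C)
  out <- matrix(0, length(lags), vdf * ldf)
  for (j in seq_len(vdf))
    out[, (j - 1L) * ldf + seq_len(ldf)] <- dR[j] * C
  out
}
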