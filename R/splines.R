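#' Spline basis specification
#'
#' Describes one of the three basis families used throughout the package:
#' natural cubic splines (linear beyond the boundary knots), B-splines of
#' arbitrary degree, and indicator strata (used for the short pollutant lag
#' dimension). A spec can be given either explicit knots or a target number
#' of basis columns (`df`), in which case interior knots are placed at
#' equally spaced values across the covariate range when the spec is
#' resolved against data -- equal spacing, not quantiles, is the convention
#' here because the exposure dimension of the cross-basis uses equally
#' spaced temperature knots.
#'
#' Column counts: natural cubic gives `length(knots) + 1 + intercept`
#' columns; a degree-`d` B-spline gives `length(knots) + d + intercept`;
#' strata give one indicator column per stratum value.
#'
#' @param family one of `"natural_cubic"`, `"bspline"`, `"linear_strata"`.
#' @param degree polynomial degree (B-splines only; natural cubic is always
#'   cubic; ignored for strata).
#' @param df target number of basis columns; mutually exclusive with
#'   explicit `knots`.
#' @param knots interior knot positions (or stratum values for
#'   `linear_strata`), strictly increasing.
#' @param Boundary.knots length-2 numeric; defaults to the data range when
#'   the spec is resolved.
#' @param intercept logical; include the full (partition-of-unity /
#'   constant-capable) basis rather than dropping one column.
#' @param transform `"identity"` or `"log1p"`; the basis is built on the
#'   transformed scale (used for lag bases with knots equally spaced on
#'   `log(lag + 1)`).
#' @return an object of class `"basis_spec"`.
#' @export
basis_spec <- function(family = c("natural_cubic", "bspline", "linear_strata"),
                       degree = NULL, df = NULL, knots = NULL,
                       Boundary.knots = NULL, intercept = FALSE,
                       transform = c("identity", "log1p")) {
  family <- match.arg(family)
  transform <- match.arg(transform)
  if (family == "bspline") {
    if (is.null(degree)) degree <- 2L
    if (degree < 1L) stop("bspline degree must be >= 1", call. = FALSE)
  } else if (family == "natural_cubic") {
    degree <- 3L
  }
  if (!is.null(knots) && is.unsorted(knots, strictly = TRUE))
    stop("knots must be strictly increasing", call. = FALSE)
  if (!is.null(Boundary.knots)) {
    if (length(Boundary.knots) != 2L || diff(Boundary.knots) <= 0)
      stop("Boundary.knots must be two increasing values", call. = FALSE)
    if (!is.null(knots) && family != "linear_strata" &&
        (any(knots <= Boundary.knots[1L]) || any(knots >= Boundary.knots[2L])))
      stop("interior knots must lie strictly inside the boundary knots",
           call. = FALSE)
  }
  structure(list(family = family, degree = as.integer(degree %||% 0L),
                 df = df, knots = knots, Boundary.knots = Boundary.knots,
                 intercept = isTRUE(intercept), transform = transform),
            class = "basis_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Resolve a basis spec against data
#'
#' Fills in boundary knots (data range on the transformed scale) and, when
#' the spec was given as a `df`, places the implied number of interior knots
#' at equally spaced values between the boundary knots.
#'
#' @param spec a [basis_spec()].
#' @param x covariate values (untransformed scale).
#' @return the spec with `knots` and `Boundary.knots` concrete.
#' @export
resolve_basis_spec <- function(spec, x) {
  stopifnot(inherits(spec, "basis_spec"))
  if (spec$family == "linear_strata") {
    if (is.null(spec$knots)) spec$knots <- sort(unique(x))
    spec$df <- length(spec$knots)
    return(spec)
  }
  xt <- apply_transform(x, spec$transform)
  if (is.null(spec$Boundary.knots)) {
    spec$Boundary.knots <- range(xt, na.rm = TRUE)
    if (diff(spec$Boundary.knots) <= 0)
      stop("cannot set boundary knots: covariate is constant", call. = FALSE)
  }
  if (is.null(spec$knots)) {
    if (is.null(spec$df))
      stop("basis_spec needs either df or explicit knots", call. = FALSE)
    n_int <- spec$df - spec$intercept -
      if (spec$family == "natural_cubic") 1L else spec$degree
    if (n_int < 0L)
      stop(sprintf("df = %d is too small for a %s basis", spec$df,
                   spec$family), call. = FALSE)
    bk <- spec$Boundary.knots
    spec$knots <- if (n_int > 0L)
      seq(bk[1L], bk[2L], length.out = n_int + 2L)[-c(1L, n_int + 2L)]
    else numeric(0)
  }
  spec$df <- basis_ncol(spec)
  spec
}

apply_transform <- function(x, transform) {
  switch(transform, identity = x, log1p = {
    if (any(x < 0, na.rm = TRUE))
      stop("log1p transform requires non-negative values", call. = FALSE)
    log1p(x)
  })
}

basis_ncol <- function(spec) {
  switch(spec$family,
         natural_cubic = length(spec$knots) + 1L + spec$intercept,
         bspline       = length(spec$knots) + spec$degree + spec$intercept,
         linear_strata = length(spec$knots))
}

# Cox-de Boor recursion on a padded, non-decreasing knot vector. Returns the
# full (intercept-inclusive) design with length(tk) - degree - 1 columns.
# x must already be clamped into [min(tk), max(tk)].
cox_de_boor <- function(x, tk, degree) {
  n <- length(x)
  nb <- length(tk) - 1L
  B <- matrix(0, n, nb)
  for (j in seq_len(nb))
    if (tk[j] < tk[j + 1L]) B[, j] <- as.numeric(x >= tk[j] & x < tk[j + 1L])
  # right-continuity at the upper boundary: fold x == max(tk) into the last
  # non-degenerate span so the partition of unity holds on the closed interval
  rb <- tk[length(tk)]
  last <- max(which(tk < rb))
  B[x == rb, last] <- 1
  if (degree > 0L) for (d in seq_len(degree)) {
    nb2 <- nb - d
    Bn <- matrix(0, n, nb2)
    for (j in seq_len(nb2)) {
      d1 <- tk[j + d] - tk[j]
      d2 <- tk[j + d + 1L] - tk[j + 1L]
      if (d1 > 0) Bn[, j] <- Bn[, j] + (x - tk[j]) / d1 * B[, j]
      if (d2 > 0) Bn[, j] <- Bn[, j] + (tk[j + d + 1L] - x) / d2 * B[, j + 1L]
    }
    B <- Bn
  }
  B
}

# Weight matrix taking a degree-(d-1) basis on tk to the derivative of the
# degree-d basis on tk:  B'_{j,d} = d * (B_{j,d-1}/D1 - B_{j+1,d-1}/D2).
deriv_weights <- function(tk, degree) {
  K  <- length(tk) - degree - 1L          # columns of the degree-d basis
  Kl <- K + 1L                            # columns of the degree-(d-1) basis
  W <- matrix(0, Kl, K)
  for (j in seq_len(K)) {
    d1 <- tk[j + degree] - tk[j]
    d2 <- tk[j + degree + 1L] - tk[j + 1L]
    if (d1 > 0) W[j, j] <- W[j, j] + degree / d1
    if (d2 > 0) W[j + 1L, j] <- W[j + 1L, j] - degree / d2
  }
  W
}

# Exact m-th derivative design of the degree-`degree` B-spline basis at x.
bspline_deriv_design <- function(x, tk, degree, m) {
  if (m == 0L) return(cox_de_boor(x, tk, degree))
  B <- cox_de_boor(x, tk, degree - m)
  for (d in (degree - m + 1L):degree) B <- B %*% deriv_weights(tk, d)
  B
}

pad_knots <- function(spec) {
  c(rep(spec$Boundary.knots[1L], spec$degree + 1L), spec$knots,
    rep(spec$Boundary.knots[2L], spec$degree + 1L))
}

# Null-space projector enforcing zero second derivative at both boundary
# knots: the natural-spline transform of the cubic B-spline basis. Depends
# only on the knots, so fit-time and prediction-time evaluations agree.
natural_constraint_Z <- function(spec) {
  tk <- pad_knots(spec)
  C2 <- bspline_deriv_design(spec$Boundary.knots, tk, 3L, 2L)
  qr.Q(qr(t(C2)), complete = TRUE)[, -(1:2), drop = FALSE]
}

clamp_to_boundary <- function(xt, bk, what) {
  # tolerance absorbs floating-point overshoot (e.g. log1p of an integer lag
  # reproducing the boundary knot inexactly) without a spurious warning
  eps <- 1e-8 * max(1, abs(bk[2L] - bk[1L]))
  out <- xt < bk[1L] - eps | xt > bk[2L] + eps
  if (any(out, na.rm = TRUE))
    warning(sprintf(
      "%d %s value(s) outside the boundary knots [%g, %g]; clamped",
      sum(out, na.rm = TRUE), what, bk[1L], bk[2L]), call. = FALSE)
  pmin(pmax(xt, bk[1L]), bk[2L])
}

#' Evaluate a resolved basis specification
#'
#' Values outside the boundary knots are clamped to them with a warning
#' (this arises when prediction contrasts sit at the extremes of the data);
#' within the boundary the natural cubic family is cubic between knots with
#' zero second derivative at and beyond the boundary knots, and the B-spline
#' family satisfies the partition of unity (when intercept-inclusive).
#'
#' @param spec a resolved [basis_spec()] (see [resolve_basis_spec()]).
#' @param x values at which to evaluate (untransformed scale).
#' @return numeric matrix, one row per value, `spec$df` columns; attribute
#'   `"spec"` carries the spec. Class `"basis_matrix"`.
#' @export
eval_basis <- function(spec, x) {
  stopifnot(inherits(spec, "basis_spec"))
  if (spec$family == "linear_strata") {
    M <- outer(x, spec$knots, `==`) * 1
    colnames(M) <- paste0("s", spec$knots)
    return(structure(M, spec = spec, class = c("basis_matrix", "matrix")))
  }
  if (is.null(spec$Boundary.knots))
    stop("spec is unresolved; call resolve_basis_spec() first", call. = FALSE)
  xt <- apply_transform(x, spec$transform)
  xt <- clamp_to_boundary(xt, spec$Boundary.knots, spec$family)
  M <- if (spec$family == "bspline") {
    B <- cox_de_boor(xt, pad_knots(spec), spec$degree)
    if (spec$intercept) B else B[, -1L, drop = FALSE]
  } else {
    cubic_spec <- spec; cubic_spec$degree <- 3L
    B <- cox_de_boor(xt, pad_knots(cubic_spec), 3L)
    N <- B %*% natural_constraint_Z(cubic_spec)
    if (spec$intercept) N else N[, -1L, drop = FALSE]
  }
  colnames(M) <- paste0("b", seq_len(ncol(M)))
  structure(M, spec = spec, class = c("basis_matrix", "matrix"))
}

#' Natural cubic spline basis
#'
#' Convenience wrapper: resolves a natural-cubic [basis_spec()] on `x` and
#' evaluates it. With `df` given, interior knots are equally spaced across
#' the range of `x`.
#'
#' @inheritParams basis_spec
#' @param x covariate values.
#' @return a `"basis_matrix"` with the resolved spec attached.
#' @export
natural_cubic_basis <- function(x, df = NULL, knots = NULL,
                                Boundary.knots = NULL, intercept = FALSE) {
  spec <- basis_spec("natural_cubic", df = df, knots = knots,
                     Boundary.knots = Boundary.knots, intercept = intercept)
  eval_basis(resolve_basis_spec(spec, x), x)
}

#' B-spline basis
#'
#' Cox-de Boor B-spline basis of the given degree; the temperature dimension
#' of the cross-basis uses degree 2 (quadratic) with equally spaced interior
#' knots.
#'
#' @inheritParams natural_cubic_basis
#' @param degree polynomial degree (default 2).
#' @return a `"basis_matrix"` with the resolved spec attached.
#' @export
bspline_basis <- function(x, degree = 2L, df = NULL, knots = NULL,
                          Boundary.knots = NULL, intercept = FALSE) {
  spec <- basis_spec("bspline", degree = degree, df = df, knots = knots,
                     Boundary.knots = Boundary.knots, intercept = intercept)
  eval_basis(resolve_basis_spec(spec, x), x)
}

#' Long-term-trend basis over a daily calendar
#'
#' Natural cubic spline on the day index with `df_per_year` columns per year
#' of data (the seasonal/trend adjustment term of the regression; 7 per year
#' over a 4-year series gives 28 columns), knots equally spaced over the
#' index range. No intercept column (the model supplies its own).
#'
#' @param dates consecutive `Date` vector.
#' @param df_per_year integer >= 1.
#' @return a `"basis_matrix"`.
#' @export
time_trend_basis <- function(dates, df_per_year = 7L) {
  if (df_per_year < 1L) stop("df_per_year must be >= 1", call. = FALSE)
  n <- length(dates)
  if (n > 1L && any(diff(as.integer(as.Date(dates))) != 1L))
    stop("dates must be consecutive days", call. = FALSE)
  n_years <- max(1L, round(n / 365.25))
  natural_cubic_basis(seq_len(n), df = as.integer(df_per_year * n_years))
}
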