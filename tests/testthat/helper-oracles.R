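# Independent oracles used across the suite. These deliberately avoid the
# package's own vectorized code paths.

# Brute-force cross-basis: naive double loop over (t, l).
naive_crossbasis <- function(x, spec) {
  spec <- tempyll:::resolve_crossbasis_spec(spec, x)
  R <- unclass(eval_basis(spec$var_spec, x))
  C <- unclass(eval_basis(spec$lag_spec, 0:spec$max_lag))
  n <- length(x)
  L <- spec$max_lag
  out <- matrix(NA_real_, n, ncol(R) * ncol(C))
  for (t in seq_len(n)) {
    if (t <= L) next
    for (j in seq_len(ncol(R))) for (k in seq_len(ncol(C))) {
      s <- 0
      for (l in 0:L) s <- s + R[t - l, j] * C[l + 1L, k]
      out[t, (j - 1L) * ncol(C) + k] <- s
    }
  }
  out
}

# Naive scalar Cox-de Boor recursion, straight from the definition.
naive_bspline_one <- function(x, j, tk, d) {
  if (d == 0L) return(as.numeric(x >= tk[j] && x < tk[j + 1L]))
  w1 <- if (tk[j + d] > tk[j])
    (x - tk[j]) / (tk[j + d] - tk[j]) * naive_bspline_one(x, j, tk, d - 1L)
  else 0
  w2 <- if (tk[j + d + 1L] > tk[j + 1L])
    (tk[j + d + 1L] - x) / (tk[j + d + 1L] - tk[j + 1L]) *
      naive_bspline_one(x, j + 1L, tk, d - 1L)
  else 0
  w1 + w2
}

# Truncated-power natural cubic spline basis (all knots = boundary +
# interior): span{1, x, d_i(x) - d_(K-1)(x)} with
# d_i(x) = ((x - k_i)_+^3 - (x - k_K)_+^3) / (k_K - k_i).
truncated_power_natural <- function(x, all_knots) {
  K <- length(all_knots)
  dk <- function(i) {
    (pmax(0, x - all_knots[i])^3 - pmax(0, x - all_knots[K])^3) /
      (all_knots[K] - all_knots[i])
  }
  cols <- list(rep(1, length(x)), x)
  for (i in seq_len(K - 2L)) cols[[length(cols) + 1L]] <- dk(i) - dk(K - 1L)
  do.call(cbind, cols)
}

# Do two bases span the same column space? Project each onto the other.
same_column_space <- function(A, B, tol = 1e-8) {
  res1 <- qr.resid(qr(A), B)
  res2 <- qr.resid(qr(B), A)
  max(abs(res1)) < tol && max(abs(res2)) < tol
}

# Small, fast simulated dataset + fit for effect-level tests.
small_sim_fit <- function(seed = 7L, n_days = 400L, max_lag = 10L,
                          truth = NULL) {
  if (is.null(truth)) truth <- truth_default(max_lag = max_lag)
  cfg <- sim_config(n_days = n_days, seed = seed, truth = truth,
                    yll_noise_sd = 40)
  sim <- simulate_daily_series(cfg)
  fit <- yll_dlnm(sim, pollutants = character(0), max_lag = max_lag)
  list(sim = sim, fit = fit, truth = truth)
}

# Multivariate normal draws via the Cholesky factor.
mvn_draws <- function(n, mean, V) {
  Lc <- chol(V + diag(1e-12, nrow(V)))
  matrix(rnorm(n * length(mean)), n) %*% Lc +
    matrix(mean, n, length(mean), byrow = TRUE)
}

# Random cross-basis specification for oracle comparisons.
random_cb_spec <- function(max_lag) {
  var_spec <- if (runif(1) < 0.5)
    basis_spec("bspline", degree = sample(1:3, 1), df = sample(3:6, 1))
  else basis_spec("natural_cubic", df = sample(2:5, 1))
  lag_spec <- if (max_lag == 0L) {
    basis_spec("linear_strata", knots = 0)
  } else if (runif(1) < 0.5) {
    basis_spec("natural_cubic", df = max(2L, min(sample(2:4, 1), max_lag)),
               intercept = TRUE,
               transform = if (runif(1) < 0.5) "log1p" else "identity")
  } else {
    basis_spec("linear_strata", knots = 0:max_lag)
  }
  crossbasis_spec(var_spec, lag_spec, max_lag)
}
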