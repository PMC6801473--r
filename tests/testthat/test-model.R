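test_that("design matrix has the documented layout and masking", {
  sim <- simulate_daily_series(sim_config(seed = 3))
  X <- build_design(sim, pollutants = c("pm10", "o3"))
  layout <- attr(X, "layout")
  expect_named(layout, c("temp", "pm10", "o3", "time", "humidity", "dow",
                         "holiday", "intercept"))
  expect_length(layout$temp, 25)        # 5 x 5 cross-basis
  expect_length(layout$pm10, 6)         # 3 x 2 cross-basis
  expect_length(layout$time, 28)        # 7 df/year x 4 years
  expect_length(layout$humidity, 3)
  expect_length(layout$dow, 6)
  expect_equal(sum(attr(X, "valid")), 1461 - 30)
  # dummy coding: at most one DOW indicator per row
  expect_true(all(rowSums(X[, layout$dow]) %in% c(0, 1)))
})

test_that("the fit runs without pollutant adjustment", {
  sim <- simulate_daily_series(sim_config(n_days = 400, seed = 4))
  fit <- yll_dlnm(sim, pollutants = character(0), max_lag = 10)
  expect_false(any(grepl("pm10|no2|so2|co|o3", names(fit$layout))))
  expect_equal(fit$n_used, 390)
})

test_that("noiseless data generated from the design are recovered exactly", {
  sim <- simulate_daily_series(sim_config(n_days = 500, seed = 5))
  X <- build_design(sim, pollutants = "pm10", max_lag = 10)
  keep <- attr(X, "valid")
  set.seed(6)
  beta <- rnorm(ncol(X), 0, 2)
  sim$all <- NA_real_
  sim$all[keep] <- drop(X[keep, ] %*% beta)
  sim$all[!keep] <- 0
  fit <- yll_dlnm(sim, pollutants = "pm10", max_lag = 10)
  expect_lt(max(abs(fit$coefficients - beta)), 1e-8)
  expect_lt(fit$sigma, 1e-8)
})

test_that("intercept-only regression gives the closed-form mean and variance", {
  set.seed(7)
  y <- rnorm(50, 10, 2)
  X <- matrix(1, 50, 1, dimnames = list(NULL, "(Intercept)"))
  fit <- stats::lm.fit(X, y)
  # closed form check of the same estimator yll_dlnm uses
  s2 <- sum(fit$residuals^2) / (50 - 1)
  expect_equal(unname(fit$coefficients), mean(y))
  expect_equal(s2 / 50, s2 * chol2inv(qr.R(fit$qr))[1, 1])
})

test_that("coefficient covariance agrees with a nonparametric bootstrap", {
  set.seed(8)
  n <- 300
  x <- rnorm(n)
  X <- cbind(1, x, x^2)
  beta <- c(2, 1, -0.5)
  y <- drop(X %*% beta) + rnorm(n, 0, 1.5)
  fit <- stats::lm.fit(X, y)
  V <- sum(fit$residuals^2) / (n - 3) * chol2inv(qr.R(fit$qr))
  B <- 2000
  boots <- matrix(0, B, 3)
  for (b in seq_len(B)) {
    ix <- sample.int(n, replace = TRUE)
    boots[b, ] <- stats::lm.fit(X[ix, , drop = FALSE], y[ix])$coefficients
  }
  Vb <- stats::cov(boots)
  # diagonal agreement within Monte-Carlo error (relative scale)
  expect_lt(max(abs(diag(Vb) - diag(V)) / diag(V)), 0.2)
})

test_that("temperature contrasts are invariant to the DOW reference category", {
  sim <- simulate_daily_series(sim_config(n_days = 400, seed = 9))
  fit1 <- yll_dlnm(sim, pollutants = character(0), max_lag = 10)
  # recode day-of-week: rotating the calendar start shifts the reference day
  sim2 <- sim
  sim2$date <- sim2$date + 2L
  fit2 <- yll_dlnm(sim2, pollutants = character(0), max_lag = 10)
  e1 <- cumulative_effect(fit1, -5, 5, 10)
  e2 <- cumulative_effect(fit2, -5, 5, 10)
  expect_equal(e1$estimate, e2$estimate, tolerance = 1e-8)
  expect_equal(e1$ci_low, e2$ci_low, tolerance = 1e-6)
})

test_that("missing covariate values are reported with their dates", {
  sim <- simulate_daily_series(sim_config(n_days = 400, seed = 10))
  sim$humidity[100] <- NA
  expect_error(yll_dlnm(sim, pollutants = character(0), max_lag = 10),
               "missing values in 'humidity'")
  sim2 <- simulate_daily_series(sim_config(n_days = 400, seed = 10))
  sim2 <- sim2[-50, ]
  expect_error(yll_dlnm(sim2, pollutants = character(0), max_lag = 10),
               "consecutive")
})

test_that("rank-deficient designs are rejected with the collinear block named", {
  sim <- simulate_daily_series(sim_config(n_days = 400, seed = 11))
  sim$pm10 <- 2 * sim$o3   # perfectly collinear pollutant pair
  expect_error(yll_dlnm(sim, pollutants = c("pm10", "o3"), max_lag = 10),
               "rank deficient")
})

test_that("equivalent natural-spline parameterizations leave fitted values unchanged", {
  skip_if_not_installed("splines")
  sim <- simulate_daily_series(sim_config(n_days = 400, seed = 12))
  fit <- yll_dlnm(sim, pollutants = character(0), max_lag = 10)
  # refit replacing the humidity block with the reference parameterization
  X <- fit$design
  hix <- fit$layout$humidity
  hum <- sim$humidity[(10 + 1):400]
  kn <- fit$call  # not needed; rebuild spec from data range
  spec <- resolve_basis_spec(basis_spec("natural_cubic", df = 3),
                             sim$humidity)
  alt <- splines::ns(hum, knots = spec$knots,
                     Boundary.knots = spec$Boundary.knots)
  X2 <- X
  X2[, hix] <- alt
  f1 <- stats::lm.fit(X, sim$all[11:400])$fitted.values
  f2 <- stats::lm.fit(X2, sim$all[11:400])$fitted.values
  expect_equal(f1, f2, tolerance = 1e-8)
})

test_that("simulate() draws reproduce the fitted model's moments", {
  sm <- small_sim_fit(seed = 13)
  draws <- simulate(sm$fit, nsim = 5, seed = 99)
  expect_equal(dim(draws), c(sm$fit$n_used, 5L))
  expect_equal(mean(as.matrix(draws)), mean(fitted(sm$fit)),
               tolerance = 0.02)
})
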