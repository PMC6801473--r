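test_that("percentiles follow the linear-interpolation quantile rule", {
  expect_equal(unname(temperature_percentiles(1:100, 0.25)), 25.75)
  expect_equal(unname(temperature_percentiles(rep(4.2, 50),
                                              c(0.01, 0.25, 0.75, 0.99))),
               rep(4.2, 4))
  expect_error(temperature_percentiles(1:10, c(0, 0.5)), "inside")
  expect_error(temperature_percentiles(numeric(0), 0.5), "empty")
})

test_that("a null contrast has zero estimate and zero-width CI", {
  sm <- small_sim_fit()
  e <- lag_effect(sm$fit, 10, 10, 3)
  expect_equal(e$estimate, 0)
  expect_equal(e$ci_low, 0)
  expect_equal(e$ci_high, 0)
  expect_false(e$significant)
})

test_that("lag effects are antisymmetric in target and reference", {
  sm <- small_sim_fit()
  for (l in c(0, 4, 10)) {
    e1 <- lag_effect(sm$fit, -4, 18, l)
    e2 <- lag_effect(sm$fit, 18, -4, l)
    expect_equal(e1$estimate, -e2$estimate, tolerance = 1e-12)
    expect_equal(e1$ci_low, -e2$ci_high, tolerance = 1e-12)
  }
})

test_that("cumulative estimates equal the sum of single-lag estimates exactly", {
  sm <- small_sim_fit()
  fit <- sm$fit
  singles <- vapply(0:10, function(l)
    lag_effect(fit, -5, 5, l)$estimate, numeric(1))
  for (L in c(0, 3, 10)) {
    ce <- cumulative_effect(fit, -5, 5, L)
    expect_lt(abs(ce$estimate - sum(singles[1:(L + 1)])), 1e-10)
  }
  e0 <- cumulative_effect(fit, -5, 5, 0)
  l0 <- lag_effect(fit, -5, 5, 0)
  expect_equal(e0$estimate, l0$estimate)
  expect_equal(e0$ci_low, l0$ci_low)
  expect_error(cumulative_effect(fit, -5, 5, 11), "exceeds max_lag")
})

test_that("cumulative variance uses the summed contrast, not summed variances", {
  sm <- small_sim_fit()
  fit <- sm$fit
  ce <- cumulative_effect(fit, -5, 5, 10)
  sd_cum <- (ce$ci_high - ce$estimate) / 1.96
  var_sum <- sum(vapply(0:10, function(l) {
    e <- lag_effect(fit, -5, 5, l)
    ((e$ci_high - e$estimate) / 1.96)^2
  }, numeric(1)))
  # with positively correlated lag estimates these must differ
  expect_gt(abs(sd_cum^2 - var_sum) / var_sum, 0.01)
})

test_that("delta-method CIs match a multivariate-normal sampling oracle", {
  set.seed(61)
  sm <- small_sim_fit(seed = 62)
  fit <- sm$fit
  ix <- fit$layout$temp
  draws <- mvn_draws(10000, fit$coefficients[ix],
                     fit$vcov[ix, ix, drop = FALSE])
  spec <- fit$temp_cb_spec
  v <- colSums(tempyll:::crossbasis_contrast(spec, -5, 5, 0:10))
  samp <- drop(draws %*% v)
  ce <- cumulative_effect(fit, -5, 5, 10)
  sd_delta <- (ce$ci_high - ce$estimate) / 1.96
  # sampling error of an SD over 10,000 normal draws is about 0.7%
  expect_equal(sd(samp), sd_delta, tolerance = 0.03)
  expect_lt(abs(mean(samp) - ce$estimate), 4 * sd_delta / 100)
  expect_lt(abs(unname(quantile(samp, 0.025)) - ce$ci_low), 0.1 * sd_delta)
  expect_lt(abs(unname(quantile(samp, 0.975)) - ce$ci_high), 0.1 * sd_delta)
})

test_that("effect curves carry the percentile contrasts they were built from", {
  sm <- small_sim_fit(seed = 63)
  p <- temperature_percentiles(sm$fit$temp, c(0.01, 0.25, 0.75, 0.99))
  cold <- effect_curve(sm$fit, "cold")
  expect_equal(attr(cold, "target"), p[[1]])
  expect_equal(attr(cold, "ref"), p[[2]])
  heat <- effect_curve(sm$fit, "heat", cumulative = TRUE)
  expect_equal(attr(heat, "target"), p[[4]])
  expect_equal(attr(heat, "ref"), p[[3]])
  expect_equal(nrow(cold), 11)
  expect_true(all(cold$ci_low <= cold$estimate &
                    cold$estimate <= cold$ci_high))
})

test_that("summaries reproduce the tabulated significance strings", {
  mk <- function(sig, est = NULL, cumulative = FALSE) {
    n <- length(sig)
    if (is.null(est)) est <- rep(1, n)
    curve <- data.frame(lag = 0:(n - 1), estimate = est,
                        ci_low = ifelse(sig, est - 0.1, est - 10),
                        ci_high = ifelse(sig, est + 0.1, est + 10),
                        significant = sig)
    structure(curve, cumulative = cumulative,
              class = c("yll_effect_curve", "data.frame"))
  }
  sig <- rep(FALSE, 31); sig[6:13] <- TRUE
  est <- rep(0.5, 31); est[8] <- 3
  s <- summarize_curve(mk(sig, est))
  expect_equal(s$significant_duration, "Lag 5\u201312")
  expect_equal(s$strongest_lag, 7)
  expect_equal(s$strongest_label, "Lag 7")

  two <- rep(FALSE, 31); two[6:15] <- TRUE; two[24:30] <- TRUE
  s2 <- summarize_curve(mk(two))
  expect_equal(s2$significant_duration,
               "Lag 5\u201314, lag 23\u201329")

  none <- summarize_curve(mk(rep(FALSE, 31)))
  expect_equal(none$significant_duration, "-")
  expect_equal(none$strongest_label, "-")
  expect_equal(none$highest_yll, "-")

  one <- rep(FALSE, 31); one[2] <- TRUE
  expect_equal(summarize_curve(mk(one))$significant_duration, "Lag 1")

  cum <- rep(FALSE, 31); cum[10:31] <- TRUE
  sc <- summarize_curve(mk(cum, cumulative = TRUE))
  expect_equal(sc$significant_duration, "Lag 0\u20139 to 30")
  expect_equal(sc$strongest_label, "Lag 0\u20139")

  cum1 <- rep(FALSE, 31); cum1[31] <- TRUE
  expect_equal(summarize_curve(mk(cum1, cumulative = TRUE))$significant_duration,
               "Lag 0\u201330")
})

test_that("strongest effect ties break toward the smaller lag", {
  sig <- rep(TRUE, 5)
  curve <- structure(
    data.frame(lag = 0:4, estimate = c(1, 2, 2, 1, 0.5),
               ci_low = 0.1, ci_high = 3, significant = sig),
    cumulative = FALSE, class = c("yll_effect_curve", "data.frame"))
  expect_equal(summarize_curve(curve)$strongest_lag, 1)
})

test_that("a size-1 sensitivity grid reproduces the base analysis", {
  sm <- small_sim_fit(seed = 64)
  grid <- data.frame(max_lag = 10L, df_per_year = 7L, humidity_df = 3L,
                     pollutants = FALSE)
  sens <- run_sensitivity(sm$sim, grid = grid)
  ctc <- tempyll:::contrast_temps(sm$fit, "cold")
  base <- cumulative_effect(sm$fit, ctc$target, ctc$ref, 10)
  expect_true(is.na(sens$error[1]))
  expect_equal(sens$cold_est[1], base$estimate, tolerance = 1e-10)
  expect_equal(sens$cold_lo[1], base$ci_low, tolerance = 1e-10)
})

test_that("sensitivity rows record failures without stopping the run", {
  sm <- small_sim_fit(seed = 65)
  grid <- data.frame(max_lag = c(10L, 399L), df_per_year = 7L,
                     humidity_df = 3L, pollutants = FALSE)
  sens <- run_sensitivity(sm$sim, grid = grid)
  expect_true(is.na(sens$error[1]))
  expect_false(is.na(sens$error[2]))
  expect_true(is.na(sens$cold_est[2]))
})

test_that("cold estimates are stable across the lag-window sensitivity grid", {
  # truth confined to lags <= 10, so widening the window only adds
  # variance; the cumulative cold contrast itself must not drift
  tr <- truth_default(max_lag = 10)
  cfg <- sim_config(seed = 66, truth = tr, yll_noise_sd = 40)
  sim <- simulate_daily_series(cfg)
  grid <- data.frame(max_lag = c(15L, 20L, 30L), df_per_year = 7L,
                     humidity_df = 3L, pollutants = FALSE)
  sens <- run_sensitivity(sim, grid = grid)
  expect_true(all(is.na(sens$error)))
  # every window detects the positive cold effect, and the estimates agree
  # with each other within the sampling uncertainty of the widest window
  expect_true(all(sens$cold_lo > 0))
  half_max <- max((sens$cold_hi - sens$cold_lo) / 2)
  expect_lt(max(sens$cold_est) - min(sens$cold_est), half_max)
})

test_that("removing pollutants leaves effects unchanged when they have no influence", {
  cfg <- sim_config(seed = 67, yll_noise_sd = 40)  # pollutant effects zero
  sim <- simulate_daily_series(cfg)
  grid <- data.frame(max_lag = 30L, df_per_year = 7L, humidity_df = 3L,
                     pollutants = c(TRUE, FALSE))
  sens <- run_sensitivity(sim, grid = grid)
  expect_true(all(is.na(sens$error)))
  # the two estimates agree within the width of either CI
  half <- (sens$cold_hi[1] - sens$cold_lo[1]) / 2
  expect_lt(abs(sens$cold_est[1] - sens$cold_est[2]), half)
})
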