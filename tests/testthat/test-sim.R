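test_that("invalid configuration fields are named in the error", {
  expect_error(sim_config(temp_ar1 = 1.2), "temp_ar1")
  expect_error(sim_config(yll_noise_sd = -1), "yll_noise_sd")
  expect_error(sim_config(n_days = 10), "n_days")
  expect_error(sim_config(deaths_per_day_mean = -2), "deaths_per_day_mean")
})

test_that("the generator is deterministic given the seed", {
  a <- simulate_daily_series(sim_config(seed = 33, n_days = 200))
  b <- simulate_daily_series(sim_config(seed = 33, n_days = 200))
  expect_identical(a, b)
  c <- simulate_daily_series(sim_config(seed = 34, n_days = 200))
  expect_false(identical(a$temp, c$temp))
})

test_that("degenerate weather settings give a constant series at the mean", {
  cfg <- sim_config(temp_amplitude = 0, temp_noise_sd = 0, seed = 1,
                    n_days = 100)
  w <- generate_weather(cfg)
  expect_equal(w$temp, rep(cfg$temp_mean, 100))
  expect_true(all(w$humidity >= 0 & w$humidity <= 100))
})

test_that("weather moments match the calibrated climate", {
  cfg <- sim_config(seed = 44)
  w <- generate_weather(cfg)
  # SE of the mean of the AR(1) noise component, plus a small allowance for
  # the seasonal cosine not covering an exact whole number of cycles
  n <- nrow(w)
  sd_stat <- cfg$temp_noise_sd / sqrt(1 - cfg$temp_ar1^2)
  se_mean <- sd_stat * sqrt((1 + cfg$temp_ar1) / (1 - cfg$temp_ar1)) / sqrt(n)
  expect_lt(abs(mean(w$temp) - cfg$temp_mean), 3 * se_mean + 0.1)
  expect_lt(min(w$temp), 0)
  expect_gt(max(w$temp), 25)
  expect_equal(sd(w$temp), 9.4, tolerance = 0.15)
})

test_that("pollutants are positive with the configured temperature coupling", {
  cfg <- sim_config(seed = 45, n_days = 1461)
  w <- generate_weather(cfg)
  p <- generate_pollutants(cfg, w)
  for (pol in c("pm10", "no2", "so2", "co", "o3"))
    expect_true(all(p[[pol]] > 0))
  expect_lt(cor(w$temp, p$pm10), -0.1)
  expect_lt(cor(w$temp, p$co), -0.2)
  expect_gt(cor(w$temp, p$o3), 0.3)
})

test_that("zero coupling decouples pollutants from temperature", {
  cfg <- sim_config(seed = 46, n_days = 1461)
  w <- generate_weather(cfg)
  p <- generate_pollutants(cfg, w, coupling = c(pm10 = 0, no2 = 0, so2 = 0,
                                                co = 0, o3 = 0))
  for (pol in c("pm10", "o3"))
    expect_lt(abs(cor(w$temp, p[[pol]])), 3 / sqrt(nrow(w)) * 2)
})

test_that("null truth with zero noise gives a constant YLL series", {
  cfg <- sim_config(seed = 47, n_days = 100, truth = truth_null(max_lag = 5),
                    yll_noise_sd = 0)
  w <- generate_weather(cfg)
  y <- generate_yll_series(cfg, w)
  expect_equal(y$all, rep(cfg$yll_baseline, 100))
})

test_that("null truth YLL is Gaussian i.i.d. around the baseline", {
  cfg <- sim_config(seed = 48, truth = truth_null())
  sim <- simulate_daily_series(cfg)
  z <- sim$all
  n <- length(z)
  expect_lt(abs(mean(z) - cfg$yll_baseline), 3 * cfg$yll_noise_sd / sqrt(n))
  skew <- mean((z - mean(z))^3) / sd(z)^3
  kurt <- mean((z - mean(z))^4) / sd(z)^4
  expect_lt(abs(skew), 3 * sqrt(6 / n))
  expect_lt(abs(kurt - 3), 3 * sqrt(24 / n))
  # no temperature signal: lagged correlations stay at noise level
  expect_lt(abs(cor(z[31:n], sim$temp[31:n])), 4 / sqrt(n))
})

test_that("a cold effect confined to lags 10-20 shows up in the lagged cross-correlation", {
  w_cold <- function(l) ifelse(l >= 10 & l <= 20, 1 / 11, 0)
  tr <- truth_closed_form(function(temp, lag)
    20 * pmax(0, 5 - temp) * w_cold(lag), max_lag = 30)
  cfg <- sim_config(seed = 49, truth = tr, yll_noise_sd = 20)
  sim <- simulate_daily_series(cfg)
  cold <- pmax(0, 5 - sim$temp)
  n <- nrow(sim)
  xcor <- vapply(0:30, function(l)
    cor(sim$all[(l + 1):n], cold[1:(n - l)]), numeric(1))
  expect_gt(mean(xcor[11:21]), mean(xcor[1:6]) + 0.05)
  expect_gt(which.max(xcor) - 1, 9)
  expect_lt(which.max(xcor) - 1, 21)
})

test_that("the recorded truth contrast is what the effects module must recover", {
  sim <- simulate_daily_series(sim_config(seed = 50))
  tr <- attr(sim, "truth")
  p <- temperature_percentiles(sim$temp, c(0.01, 0.25))
  target <- true_effect(tr, p[[1]], p[[2]], cumulative = TRUE)
  # identical to summing the per-lag truth
  expect_equal(sum(true_effect(tr, p[[1]], p[[2]])), target,
               tolerance = 1e-12)
  expect_gt(target, 50)   # a detectable cold effect by design
})

test_that("stratum shares keep the generated series internally consistent", {
  sim <- simulate_daily_series(sim_config(seed = 51, n_days = 200))
  expect_equal(sim$male + sim$female, sim$all, tolerance = 1e-9)
  expect_equal(sim$nonacc_lt65 + sim$nonacc_ge65, sim$all,
               tolerance = 1e-9)
})

test_that("Poisson death counts have the configured mean", {
  cfg <- sim_config(seed = 52, n_days = 400, deaths_per_day_mean = 25)
  rec <- generate_death_records(cfg)
  calendar <- cfg$start_date + 0:399
  counts <- table(factor(format(rec$deaths$date), levels = format(calendar)))
  m <- mean(as.numeric(counts))
  expect_lt(abs(m - 25), 3 * sqrt(25 / 400))
  cfg0 <- sim_config(seed = 53, n_days = 100, deaths_per_day_mean = 0)
  expect_equal(nrow(generate_death_records(cfg0)$deaths), 0L)
})

test_that("life tables are positive and strictly decreasing in age", {
  lt <- make_life_table()
  expect_true(all(lt$ex > 0))
  for (yr in unique(lt$year)) for (sx in unique(lt$sex)) {
    ex <- lt$ex[lt$year == yr & lt$sex == sx][order(
      lt$age[lt$year == yr & lt$sex == sx])]
    expect_true(all(diff(ex) < 0))
  }
})
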