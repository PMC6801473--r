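#' Simulation configuration
#'
#' Bundles and validates the parameters of the synthetic registry-style data
#' generator. Defaults emulate a 4-year (1461-day) daily series from a
#' temperate, semi-arid northern city: strongly seasonal mean temperature
#' (annual mean 11.4 degC, overall SD about 9.4 degC, winter minima near
#' -12 degC and summer maxima near 30 degC), approximately Gaussian daily
#' YLL with mean 420 years/day, and combustion pollutants anti-correlated
#' with temperature (ozone positively correlated).
#'
#' Temperature is a seasonal cosine (peak in mid-July by default) plus AR(1)
#' noise; with amplitude 12 degC (SD 12/sqrt(2) = 8.5) and stationary noise
#' SD 2.9/sqrt(1 - 0.7^2) = 4.1 the overall SD is about 9.4 degC. The
#' residual YLL noise SD (60 years/day) is below the overall daily-YLL SD of
#' about 129 because much of that spread is seasonal/temperature signal; the
#' split is a modelling choice, as registry analyses do not report residual
#' variance.
#'
#' @param n_days series length in days (default 1461; must be at least
#'   `2 * max_lag + 1` of the truth surface).
#' @param seed integer seed; all generator randomness derives from it.
#' @param start_date first calendar day.
#' @param temp_mean annual mean temperature, degC.
#' @param temp_amplitude seasonal cosine amplitude, degC.
#' @param temp_ar1 AR(1) coefficient of the temperature noise, in `[0, 1)`.
#' @param temp_noise_sd AR(1) innovation SD, degC (> 0 unless 0 for
#'   degenerate tests).
#' @param peak_doy day of year of the seasonal temperature peak (default
#'   196, mid-July).
#' @param humidity_mean,humidity_sd relative-humidity marginal moments (%).
#' @param yll_baseline baseline daily YLL, years/day.
#' @param yll_noise_sd residual daily YLL SD, years.
#' @param trend_slope linear trend in YLL, years/day per day (lies in the
#'   model's trend-spline space).
#' @param truth a `"truth_surface"` (default [truth_default()]).
#' @param pollutant_effects named vector of linear lag-0 YLL effects per
#'   unit concentration (default all zero).
#' @param deaths_per_day_mean Poisson mean of daily death counts for the
#'   record-level generator.
#' @param holiday_dates `Date` vector flagged as holidays (default: Jan 1-3
#'   and Oct 1-3 each year, a stylized holiday calendar).
#' @return validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_days = 1461L, seed = NULL,
                       start_date = as.Date("2014-01-01"),
                       temp_mean = 11.4, temp_amplitude = 12,
                       temp_ar1 = 0.7, temp_noise_sd = 2.9,
                       peak_doy = 196L,
                       humidity_mean = 51.5, humidity_sd = 15.1,
                       yll_baseline = 420, yll_noise_sd = 60,
                       trend_slope = 0,
                       truth = truth_default(),
                       pollutant_effects = NULL,
                       deaths_per_day_mean = 25,
                       holiday_dates = NULL) {
  cfg <- list(n_days = as.integer(n_days), seed = seed,
              start_date = as.Date(start_date),
              temp_mean = temp_mean, temp_amplitude = temp_amplitude,
              temp_ar1 = temp_ar1, temp_noise_sd = temp_noise_sd,
              peak_doy = as.integer(peak_doy),
              humidity_mean = humidity_mean, humidity_sd = humidity_sd,
              yll_baseline = yll_baseline, yll_noise_sd = yll_noise_sd,
              trend_slope = trend_slope, truth = truth,
              pollutant_effects = pollutant_effects,
              deaths_per_day_mean = deaths_per_day_mean,
              holiday_dates = holiday_dates)
  bad <- function(field, msg)
    stop(sprintf("invalid sim_config field '%s': %s", field, msg),
         call. = FALSE)
  if (!inherits(truth, "truth_surface")) bad("truth", "not a truth_surface")
  if (cfg$n_days < 2L * truth$max_lag + 1L)
    bad("n_days", sprintf("must be >= 2 * max_lag + 1 = %d",
                          2L * truth$max_lag + 1L))
  if (cfg$temp_ar1 < 0 || cfg$temp_ar1 >= 1) bad("temp_ar1", "not in [0, 1)")
  for (f in c("temp_noise_sd", "humidity_sd", "yll_noise_sd"))
    if (cfg[[f]] < 0) bad(f, "negative SD")
  if (cfg$temp_amplitude < 0) bad("temp_amplitude", "negative amplitude")
  if (cfg$deaths_per_day_mean < 0) bad("deaths_per_day_mean", "negative mean")
  if (is.null(cfg$holiday_dates)) {
    yrs <- unique(as.POSIXlt(cfg$start_date + seq_len(cfg$n_days) - 1L)$year) +
      1900L
    cfg$holiday_dates <- as.Date(c(
      outer(c("-01-01", "-01-02", "-01-03", "-10-01", "-10-02", "-10-03"),
            yrs, function(s, y) paste0(y, s))))
  }
  class(cfg) <- "sim_config"
  cfg
}

sim_dates <- function(config) config$start_date + seq_len(config$n_days) - 1L

# Target marginal mean/SD used for the log-normal pollutant marginals and the
# sign/strength of their coupling to temperature (negative for combustion
# pollutants, positive for ozone).
pollutant_params <- function() {
  data.frame(
    name = c("pm10", "no2", "so2", "co", "o3"),
    mean = c(124.67, 52.97, 22.17, 1.33, 48.43),
    sd   = c(86.07, 21.46, 15.19, 0.73, 22.09),
    coupling = c(-0.35, -0.4, -0.6, -0.55, 0.6),
    stringsAsFactors = FALSE)
}

#' Generate daily weather (temperature and relative humidity)
#'
#' Temperature is `temp_mean + temp_amplitude * cos(2*pi*(doy - peak_doy) /
#' 365.25)` plus AR(1) noise; humidity is an independent Gaussian series
#' clamped to `[0, 100]`. Deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return data frame with `date`, `temp`, `humidity`.
#' @export
generate_weather <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_days
  dates <- sim_dates(config)
  doy <- as.POSIXlt(dates)$yday + 1L
  seasonal <- config$temp_mean +
    config$temp_amplitude * cos(2 * pi * (doy - config$peak_doy) / 365.25)
  eps <- stats::rnorm(n, 0, config$temp_noise_sd)
  noise <- numeric(n)
  if (n > 0L) {
    noise[1L] <- if (config$temp_ar1 < 1 && config$temp_noise_sd > 0)
      stats::rnorm(1L, 0, config$temp_noise_sd /
                     sqrt(1 - config$temp_ar1^2)) else 0
    for (t in seq_len(n - 1L))
      noise[t + 1L] <- config$temp_ar1 * noise[t] + eps[t + 1L]
  }
  humidity <- pmin(100, pmax(0, stats::rnorm(n, config$humidity_mean,
                                             config$humidity_sd)))
  data.frame(date = dates, temp = seasonal + noise, humidity = humidity)
}

#' Generate daily pollutant concentrations
#'
#' Log-normal marginals calibrated to realistic urban means/SDs, with
#' log-scale coupling to standardized temperature: negative for the
#' combustion pollutants (PM10, NO2, SO2, CO -- winter heating), positive
#' for ozone (photochemistry). All values are strictly positive.
#'
#' @param config a [sim_config()].
#' @param weather output of [generate_weather()].
#' @param coupling optional named override of the per-pollutant coupling
#'   coefficients (fraction of log-scale SD tied to temperature; 0 gives
#'   independence).
#' @return data frame with `date` and one column per pollutant.
#' @export
generate_pollutants <- function(config, weather, coupling = NULL) {
  stopifnot(inherits(config, "sim_config"))
  pp <- pollutant_params()
  if (!is.null(coupling)) {
    ix <- match(names(coupling), pp$name)
    if (anyNA(ix)) stop("unknown pollutant in coupling: ",
                        paste(names(coupling)[is.na(ix)], collapse = ", "),
                        call. = FALSE)
    pp$coupling[ix] <- coupling
  }
  z <- as.numeric(scale(weather$temp))
  if (all(!is.finite(z))) z <- rep(0, nrow(weather))
  out <- data.frame(date = weather$date)
  for (i in seq_len(nrow(pp))) {
    v <- log(1 + pp$sd[i]^2 / pp$mean[i]^2)   # total log-scale variance
    mu <- log(pp$mean[i]) - v / 2
    b <- pp$coupling[i] * sqrt(v)
    resid_sd <- sqrt(max(0, v - b^2))
    out[[pp$name[i]]] <- exp(mu + b * z +
                               stats::rnorm(nrow(weather), 0, resid_sd))
  }
  out
}

#' Generate a daily YLL series from a known truth surface
#'
#' `YLL_t = baseline + trend_t + sum_l f(temp_(t-l), l) + pollutant terms +
#' Gaussian noise`. Days early in the series use the available lag history
#' (lags reaching before day 1 contribute nothing). The truth surface is
#' attached to the result so recovery can be tested.
#'
#' @param config a [sim_config()].
#' @param weather,pollutants outputs of the weather/pollutant generators.
#' @return data frame with `date`, YLL stratum columns (`all`, `male`,
#'   `female`, `nonacc_lt65`, `nonacc_ge65`, `male_ge65`, `female_ge65`,
#'   `resp_ge65`, `cv_ge65`), plus `signal` (the noiseless temperature
#'   contribution); attribute `"truth"` carries the surface.
#' @export
generate_yll_series <- function(config, weather, pollutants = NULL) {
  stopifnot(inherits(config, "sim_config"))
  truth <- config$truth
  n <- config$n_days
  L <- truth$max_lag
  if (n <= L)
    stop("truth surface max_lag incompatible with series length",
         call. = FALSE)
  # F[t0, l+1] = centred f(temp[t0], l). The truth's effect saturates at its
  # boundary knots, so extreme days beyond them are clamped silently here.
  Fm <- withCallingHandlers(
    vapply(0:L, function(l)
      evaluate_truth(truth, weather$temp, rep(l, n)), numeric(n)),
    warning = function(w) {
      if (grepl("clamped", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  signal <- numeric(n)
  for (l in 0:L) {
    rows <- (l + 1L):n
    signal[rows] <- signal[rows] + Fm[rows - l, l + 1L]
  }
  trend <- config$trend_slope * (seq_len(n) - (n + 1) / 2)
  pol_term <- 0
  if (!is.null(config$pollutant_effects) && !is.null(pollutants)) {
    pol_term <- rep(0, n)
    for (pn in names(config$pollutant_effects))
      pol_term <- pol_term + config$pollutant_effects[[pn]] * pollutants[[pn]]
  }
  noise <- stats::rnorm(n, 0, config$yll_noise_sd)
  all <- config$yll_baseline + trend + signal + pol_term + noise
  # stratum columns as fixed shares of the aggregate (the record-level
  # generator produces genuinely stratified series)
  shares <- c(male = 0.6, female = 0.4, nonacc_lt65 = 0.535,
              nonacc_ge65 = 0.465, male_ge65 = 0.248, female_ge65 = 0.217,
              resp_ge65 = 0.077, cv_ge65 = 0.231)
  out <- data.frame(date = weather$date, all = all)
  for (s in names(shares)) out[[s]] <- shares[[s]] * all
  out$signal <- signal
  attr(out, "truth") <- truth
  out
}

#' Generate a complete synthetic daily series
#'
#' Runs the weather, pollutant and YLL generators and assembles the full
#' analysis table (dates, weather, pollutants, day-of-week, holiday flag,
#' YLL strata) with the truth surface and config attached as attributes.
#'
#' @param config a [sim_config()].
#' @return data frame ready for [yll_dlnm()]; attributes `"truth"` and
#'   `"config"`.
#' @export
simulate_daily_series <- function(config = sim_config()) {
  weather <- generate_weather(config)
  pollutants <- generate_pollutants(config, weather)
  yll <- generate_yll_series(config, weather, pollutants)
  out <- cbind(weather,
               pollutants[, setdiff(names(pollutants), "date"),
                          drop = FALSE],
               yll[, setdiff(names(yll), "date"), drop = FALSE])
  out$dow <- as.POSIXlt(out$date)$wday
  out$holiday <- as.numeric(out$date %in% config$holiday_dates)
  attr(out, "truth") <- attr(yll, "truth")
  attr(out, "config") <- config
  out
}

#' Synthetic period life table
#'
#' Builds a stylized period life table: expected remaining life years decay
#' exponentially in age from sex-specific life expectancy at birth, with a
#' small secular improvement per calendar year. Strictly decreasing in age
#' and everywhere positive; ages run 0 to `max_age` (the terminal open age
#' group). Clearly labelled synthetic -- it stands in for national life
#' tables, which users supply via [read_life_table()] for real analyses.
#'
#' @param years calendar years covered.
#' @param max_age terminal age row.
#' @param e0 named life expectancy at birth per sex.
#' @return data frame `(year, sex, age, ex)` of class `"life_table"`.
#' @export
make_life_table <- function(years = 2014:2016, max_age = 100L,
                            e0 = c(male = 73.6, female = 79.4)) {
  grid <- expand.grid(age = 0:max_age, sex = names(e0), year = years,
                      stringsAsFactors = FALSE)
  # decay rate set so remaining life expectancy at 65 is realistic (~16 yr)
  lambda <- 43
  grid$ex <- (e0[grid$sex] + 0.2 * (grid$year - min(years))) *
    exp(-grid$age / lambda)
  grid <- grid[, c("year", "sex", "age", "ex")]
  rownames(grid) <- NULL
  class(grid) <- c("life_table", "data.frame")
  grid
}

#' Generate individual death records
#'
#' Daily death counts are Poisson with mean `deaths_per_day_mean`; ages are
#' drawn from a Gaussian kernel centred at 72 years truncated to the life
#' table's age range, genders from a 52/48 male/female split, and ICD-10
#' codes from a categorical mix over cardiovascular (I), respiratory (J),
#' neoplasm (C), other non-accidental (A/E/G/K/N/R) and external (V/W/X)
#' chapters.
#'
#' @param config a [sim_config()] (uses `n_days`, `start_date`, `seed`,
#'   `deaths_per_day_mean`).
#' @param life_table a life table covering the simulated ages and sexes.
#' @param cause_probs named probabilities for chapters
#'   `c(I, J, C, other, external)`.
#' @return list with `deaths` (data frame `date, age, sex, icd10`) and
#'   `life_table`.
#' @export
generate_death_records <- function(config, life_table = make_life_table(),
                                   cause_probs = c(I = 0.35, J = 0.10,
                                                   C = 0.20, other = 0.30,
                                                   external = 0.05)) {
  stopifnot(inherits(config, "sim_config"))
  if (!nrow(life_table)) stop("empty life table", call. = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed + 1L)
  dates <- sim_dates(config)
  counts <- stats::rpois(config$n_days, config$deaths_per_day_mean)
  total <- sum(counts)
  if (total == 0L)
    return(list(deaths = data.frame(date = as.Date(character(0)),
                                    age = integer(0), sex = character(0),
                                    icd10 = character(0)),
                life_table = life_table))
  max_age <- max(life_table$age)
  ages <- pmin(max_age, pmax(0L, round(stats::rnorm(total, 72, 15))))
  sexes <- sample(c("male", "female"), total, replace = TRUE,
                  prob = c(0.52, 0.48))
  chap <- sample(names(cause_probs), total, replace = TRUE,
                 prob = cause_probs)
  letter <- c(I = "I", J = "J", C = "C", other = NA, external = NA)[chap]
  letter[chap == "other"] <- sample(c("A", "E", "G", "K", "N", "R"),
                                    sum(chap == "other"), replace = TRUE)
  letter[chap == "external"] <- sample(c("V", "W", "X"),
                                       sum(chap == "external"),
                                       replace = TRUE)
  icd10 <- paste0(letter, sprintf("%02d", sample(0:99, total,
                                                 replace = TRUE)))
  deaths <- data.frame(date = rep(dates, counts), age = as.integer(ages),
                       sex = sexes, icd10 = icd10, stringsAsFactors = FALSE)
  list(deaths = deaths, life_table = life_table)
}
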