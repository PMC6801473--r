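---
title: "Modelling temperature effects on years of life lost with distributed-lag non-linear models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling temperature effects on years of life lost with distributed-lag non-linear models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## 1. From deaths to years of life lost

For a death on date $t$ of a person of sex $s$ and completed age $a$, the
years of life lost are the remaining period life expectancy

$$ \mathrm{YLL} = e_x(\mathrm{year}(t), s, a), $$

looked up in a period life table. `yll_for_death()` implements the lookup with
two conventions:

- if no table exists for $\mathrm{year}(t)$, the latest *earlier* table is
  used (a study period often outruns the available tables by a year);
- ages above the terminal open age group (100) are clamped to it.

`classify_cause()` maps ICD-10 codes: A00–R99 are non-accidental (chapter I
codes cardiovascular, chapter J respiratory); S, T, U and V–Z codes are
external/other and are excluded from every stratum. `aggregate_daily_yll()`
sums per-death YLL to daily series for nine strata (all, male, female,
non-accidental <65 and ≥65, the sex × ≥65 cells, and cardiovascular and
respiratory deaths at ≥65). The age-65 boundary goes to the ≥65 group.

## 2. The regression model

With $Y_t$ the daily YLL of a stratum, the model is the Gaussian time-series
regression

$$ \mathbb{E}(Y_t) \;=\; \alpha
   \;+\; \mathrm{CB}(T_t;\,\theta)
   \;+\; \textstyle\sum_p \mathrm{CB}(P_{p,t};\,\gamma_p)
   \;+\; \mathrm{NS}(t;\,7\ \mathrm{df/yr})
   \;+\; \mathrm{NS}(H_t;\,3)
   \;+\; \mathrm{DOW}_t \;+\; \mathrm{Holiday}_t , $$

fitted by ordinary least squares (`yll_dlnm()`). YLL is a continuous
aggregate, so a Gaussian family with identity link is the natural choice; it
also makes cumulative lag effects *exact sums* of single-lag effects, which
the test suite exploits.

### The temperature cross-basis

The cross-basis is the bilinear exposure–lag–response surface

$$ \mathrm{CB}(T_t) \;=\; \sum_{j=1}^{5}\sum_{k=1}^{5} \theta_{jk}
   \sum_{\ell=0}^{30} R_j(T_{t-\ell})\, C_k(\ell), $$

with

- $R_j$: quadratic B-spline over temperature, 5 df, interior knots **equally
  spaced over the observed range** (not quantiles), no intercept column;
- $C_k$: natural cubic spline over $\log(\ell+1)$, 5 df, knots equally
  spaced on the log scale, *with* intercept (lag 0 must carry an effect);
- maximum lag 30 days — cold effects on mortality are known to persist for
  weeks, and 30 days bounds the history a four-year series can support
  without losing much data (30 of 1461 days are dropped for lag history).

Pollutants use a smaller surface: natural cubic over concentration (3 df) ×
indicator strata for lags 0 and 1, reflecting the short lags over which acute
pollution effects act.

### Splines from first principles

The B-spline basis is computed by the Cox–de Boor recursion on a padded knot
vector, with the right boundary handled by continuity. Derivatives come from
the standard difference-weight matrices. The natural cubic basis is the cubic
B-spline basis post-multiplied by a null-space basis $Z$ of the two
second-derivative constraints at the boundary knots, so linearity beyond the
boundary holds by construction. Values outside the boundary knots are clamped
to it (constant extrapolation of the basis) with a warning. The test suite
verifies partition of unity, local support, a recursive scalar oracle, the
truncated-power representation of the natural spline space, and agreement of
fitted values with `splines::ns` as an independent reference.

## 3. Effects and their uncertainty

Cold is the contrast of the 1st versus the 25th percentile of observed
temperature; heat is the 99th versus the 75th (percentiles by the standard
linear-interpolation rule, `quantile` type 7). For a contrast vector $v$ (a
row of the cross-basis difference at a given lag, or the sum of rows over
lags $0..L$ for cumulative effects),

$$ \widehat{\Delta} = v^\top\hat\theta, \qquad
   \mathrm{CI}_{95} = \widehat{\Delta} \pm 1.96\sqrt{v^\top \Sigma v}, $$

with $\Sigma$ the OLS covariance of the cross-basis coefficients. Because the
link is the identity, the cumulative estimate equals the sum of single-lag
estimates exactly, while its variance correctly accounts for the correlation
between lags (it is *not* the sum of single-lag variances).
`summarize_curve()` renders the summaries used in published tables: runs of
significant lags ("Lag 5–14, lag 23–29"), the first-to-last significant
cumulative window ("Lag 0–9 to 30"), and the strongest significant effect
with ties broken toward the smaller lag.

## 4. The synthetic-data generator

`sim_config()` / `simulate_daily_series()` emulate a four-year (1461-day)
mid-latitude, semi-arid urban setting:

| parameter | default | rationale |
|---|---|---|
| `temp_mean`, `temp_amplitude` | 11.4 °C, 12 °C | annual mean and seasonal swing of a continental climate |
| `temp_ar1`, `temp_noise_sd` | 0.7, 2.9 °C | day-to-day weather persistence; total SD ≈ 9.4 °C |
| `humidity_mean`, `humidity_sd` | 51.5 %, 15.1 % | clamped to [0, 100] |
| `yll_baseline`, `yll_noise_sd` | 420, 60 years/day | a city of a few million with ~25 deaths/day |
| pollutant marginals | PM10 125, NO2 53, SO2 22, CO 1.3, O3 48 | log-normal, winter-high (O3 summer-high) via log-scale temperature coupling |

The truth surface (`truth_default()`) is a closed-form surface — cold: 15
years/°C below 5 °C distributed over lags 5–20 with a smooth profile; heat:
10 years/°C above 20 °C concentrated on lags 0–2 — projected by least squares
onto the model's own cross-basis with a fixed boundary (−20, 38 °C). The
projection makes the generating model *nested* in the fitted model, so OLS
recovery is exactly unbiased and confidence-interval coverage can be tested
at its nominal level rather than up to an approximation error. The
pre-projection closed form is kept as an attribute; `truth_null()` gives a
zero surface for type-I-error experiments. Pollutants are correlated with
temperature but have no causal effect on YLL by default, so pollutant
adjustment is validated as harmless, not as confounder control.

Stratum series are fixed shares of the aggregate (e.g. male 0.6, ≥65 0.465),
which keeps the strata internally consistent but means stratum-specific
effect *heterogeneity* is outside the generator's scope.

## 5. Numerical choices

- OLS via the QR decomposition (`lm.fit`); the coefficient covariance is
  $\hat\sigma^2 (X^\top X)^{-1}$ from `chol2inv` of the $R$ factor with pivot
  ordering restored, then symmetrized.
- Rank deficiency is an error that names the offending design block rather
  than silently dropping columns.
- 95% intervals use the normal quantile 1.96; with >1300 residual df the
  difference from the $t$ quantile is below 0.1%.
- Cross-basis rows with incomplete lag history are set to `NA` and dropped
  from the fit, never imputed.

## 6. Problem sizes

The defaults target a four-year daily series (1461 days, 115 design columns),
which fits in well under a tenth of a second; the replicate experiments in
the test suite (200 coverage replicates, 500 null replicates) run in a few
minutes. These sizes are the package's own validation choices, not limits.

## 7. Limitations

- Gaussian errors, no autocorrelation correction beyond the seasonal spline;
  overdispersed quasi-Poisson modelling of *death counts* is out of scope.
- Delta-method intervals are symmetric; for strongly non-linear functionals
  of $\theta$ a simulation-based interval would be preferable (the test suite
  checks the two agree for the contrasts used here).
- The generator's life tables and stratum shares are stylized; supply real
  tables with `read_life_table()` for substantive work.
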