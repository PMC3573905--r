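# dglmseas

Seasonal variation in hospitalization rates — winter excesses of stroke,
atrial fibrillation and other cardiovascular events — is usually summarized
by fitting one sinusoidal regression to an entire study period, which
forces the seasonality to be constant over decades and ignores the serial
dependence of a weekly time series.  `dglmseas` implements the alternative:
a **Poisson dynamic generalized linear model (DGLM)** in which the
regression coefficients themselves evolve over time, so the intensity and
timing of the seasonal variation may change gradually.  It is aimed at
epidemiologists and biostatisticians analyzing weekly event counts from
open cohorts or registries.

## Model

For weekly counts `y_t` with person-time offsets (100 person-year units):

    y_t | eta_t ~ Poisson(offset_t * lambda_t),   eta_t = log(lambda_t) = F_t' theta_t
    theta_t = G theta_{t-1} + omega_t,            omega_t ~ N(0, W)
    theta_0 ~ N(m0, C0)

with a six-dimensional state `theta_t = (level, slope, a1, b1, a2, b2)`: a
local linear trend plus the coefficients of two sinusoids with 12- and
6-month periods.  `W` is block diagonal and parameterized by eight
hyperparameters (four variances, four covariances) that tie the
coefficients of each sinusoid together.  Inference:

* **iterated extended Kalman smoothing** for the posterior mode of the
  states (repeated linearization of the Poisson likelihood);
* **EM** over the structured `W`, followed by Nelder–Mead maximization of
  the exact log-likelihood evaluated by **importance sampling** with
  antithetic variates (Durbin–Koopman simulation smoother);
* **AIC** comparison of dynamic vs static seasonal variation;
* derived summaries: weekly **peak-to-trough (PTT) incidence rate
  ratios**, calendar timing of peak and trough, seasonally adjusted trend
  rates with intervals, and residual diagnostics.

## Worked example

```r
library(dglmseas)

# three decades of synthetic weekly counts at registry scale, with known truth
sim <- stroke_af_scenario(seed = 1, n = 600)
print(sim$series)
#> weekly_series: 600 weeks, 1980-01-01 to 1991-06-25
#>   counts: median 21, range [4, 51]
#>   offsets (100 person-years/week): range [2.56, 14.1]

fit <- fit_dglm(sim$series, n_draws = 300, seed = 2,
                em_max_iter = 500, optim_maxit = 80)
print(fit)
#> dglm_fit (dynamic seasonal variation)
#>   phi_hat:  0.00031 1.3e-07 4.93e-06 2.89e-05 6.73e-05 2.48e-05 6.56e-05 1.08e-05
#>   loglik: -1829.13 (IS se 0.00234, 300 draws), AIC: 3686.3 (k = 14)
#>   EM: 118 iterations, converged = TRUE

summ <- seasonal_summary(fit)
round(summ[c(1, 600), c("ptt", "peak_day", "trough_day", "rate")], 3)
#>       ptt peak_day trough_day  rate
#> 1   1.353    8.813    113.802 4.154
#> 600 1.296    2.155    240.958 2.181
```

The `ptt` column is the peak-to-trough incidence rate ratio implied by the
smoothed state of each week (1.35 ≈ a 35% winter excess in this
realization), `peak_day` / `trough_day` its calendar timing (day-of-year,
1 January = 0: an early-January peak, with the trough drifting from spring
towards late August over the twelve simulated years), and `rate` the
seasonally adjusted trend incidence rate per 100 person-years (declining
from 4.2 to 2.2 here).  `residual_report(residual_set(fit))`
summarizes the innovation residuals for misspecification screening, and
`fit_dglm(..., dynamic_seasonal = FALSE)` fits the static-seasonality
variant for the AIC comparison.

A thin command-line wrapper covers the same pipeline
(`inst/scripts/dglmseas.R simulate | fit | summarize`).

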