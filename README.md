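# airerr

Exposure **measurement error simulation** for air pollution time-series
epidemiology: quantify how much error a monitor network carries, inject that
error into an exposure series as classical-like, Berkson-like or any
intermediate type, and measure (and analytically predict) what it does to
risk-ratio estimates from a Poisson health model.

## Who this is for

Environmental epidemiologists and exposure scientists running time-series
studies in which a central-monitor or population-weighted-average series
stands in for community exposure. The package answers: *given the spatial
heterogeneity of my pollutant, how biased is my risk ratio, in which
direction, and how much significance do I lose — and does the answer depend
on whether the error is classical or Berkson in nature?*

## The model in brief

**Error budget.** For monitors a distance h apart, the correlation R of
their normalized log series defines a scaled semivariance
γ′ = (1 − R)/(1 + R) ∈ [0, 1]. An exponential semivariogram
γ′(h) = n + (1 − n)(1 − e^(−3h/a)) (sill 1, nugget n from collocated
instruments, range a by least squares) is evaluated at census-tract centroid
distances and population-weighted over all tract pairs (i ≤ j, weights
p_i + p_j) to give one number per pollutant, γ̄′, and its correlation
equivalent R̄ = (1 − γ̄′)/(1 + γ̄′).

**Error injection.** A true series Z\*_t is standardized on the log scale
(χ\*), and error is added multiplicatively:

    χ_t = s · (χ*_t + σ_err N_t) / √(1 + σ_err²),   ln Z_t = μ + σ_lnZ* · χ_t

with σ_err = √(1/R̄ − 1) (so that R(ln Z, ln Z\*) = √R̄) and N_t a 3-day
running mean of standard normals rescaled to unit variance. The target SD
ratio s = σ_lnZ/σ_lnZ\* selects the error type: s = √(1 + σ_err²) is the
classical-like endpoint (error ⟂ truth), s = 1/√(1 + σ_err²) the
Berkson-like endpoint (error ⟂ measurement), and everything between is an
intermediate type at the same log-scale correlation.

**Health model.** log E(Y_t) = α + β Z_t + γ′·confounders_t, fitted as a
Poisson GLM with Pearson-dispersion-scaled SEs (quasi-Poisson); risk ratios
per unit (e^β) and per IQR (e^(β·IQR)); Monte Carlo sets aggregated via the
mean z-statistic.

**Attenuation.** Bias is expressed as percent attenuation
100·(RR\* − RR)/(RR\* − 1) (negative = bias away from the null) and
predicted analytically from the raw-scale slope m of (Z − Z\*) on Z:
per-unit ≈ 100·m, per-IQR ≈ 100·[1 − (1 − m)·IQR_Z/IQR_Z\*].

A synthetic-world generator (lognormal spatially correlated monitor fields,
census tracts, confounders, Poisson counts with known true RR) makes the
whole chain testable with ground truth; published error budgets and
risk-ratio tables from a six-year, twelve-pollutant Atlanta analysis are
included as reference data (`published_error_budgets()`,
`published_risk_ratios()`).

## Worked example

```r
library(airerr)
library(dplyr)

# a six-year synthetic world with a CO-like base case and known RR = 1.0139
world  <- world_config(n_days = 2192, n_sites = 1, seed = 1)
base   <- base_case_series(generate_monitor_field(world))
counts <- generate_health_counts(base, health_config(seed = 2))

fit_health_model(mutate(counts, exposure = base$value))
#> Quasi-Poisson health model (n = 2192 days, dispersion 1.03)
#>   RR per unit 1.0114 (1.0063-1.0165) | IQR 1.02 | RR per IQR 1.0116 (1.0064-1.0168) | p 1.08e-05

# inject the CO error budget (gamma_bar = 0.411) as classical-like error
spec <- error_spec(gamma_bar = 0.411, type = "C", n_sims = 50, seed = 3)
res  <- run_error_scenario(base, counts, spec)
res
#> Error scenario type C (gamma_bar 0.411, sigma_err 1.18, 50 draws)
#>   RR per unit 1.0028 | RR per IQR 1.0046 | p 0.00993
#>   attenuation per unit 75.1% (predicted 76.1%) | per IQR 60.0% (predicted 61.6%)
```

Reading this: the error-free fit recovers the generating association
(RR ≈ 1.011 per unit, p ≈ 1e-5). Injecting the amount of error measured for
1-hr max CO (γ̄′ = 0.411 → σ_err = 1.18) as classical-like error erases
three quarters of the per-unit excess risk (75% attenuation) and costs three
orders of magnitude of significance — and the first-order analytic
prediction (76%) tracks the simulation. Running the same spec with
`type = "B"` instead *inflates* the per-unit RR (negative attenuation) while
still attenuating on the per-IQR scale.

The closed-form error budget for any pollutant:

```r
error_budget_from_semivariance(0.411, pollutant = "1-hr max CO")
#>   pollutant   gamma_bar r_bar sigma_err s_ratio_b s_ratio_c
#> 1 1-hr max CO     0.411 0.417      1.18     0.646      1.55
```

Other entry points: `pairwise_log_correlations()` → `fit_semivariogram()` →
`population_weighted_semivariance()` for the error budget from monitor data;
`continuum_sweep()` for the Berkson-to-classical continuum;
`compare_predicted_observed()` for the analytic-vs-epidemiologic 1:1 check;
`run_error_study()` for the end-to-end pipeline with CSV outputs;
`autoplot()` / `plot_attenuation()` / `plot_significance()` for figures.

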