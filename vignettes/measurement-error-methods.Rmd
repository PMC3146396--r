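---
title: "Modelling exposure measurement error in air pollution time-series studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling exposure measurement error in air pollution time-series studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(airerr)
library(dplyr)
```

## The problem

Time-series studies of ambient air pollution regress daily counts of health
events (for example cardiovascular emergency-department visits) on daily
pollutant concentrations measured at a handful of monitors. The monitor value
stands in for a community-wide exposure, so two error sources are built into
the design: instrument imprecision, and spatial variability of the pollutant
across the study area. How much this measurement error distorts the estimated
risk ratio depends not only on the *amount* of error but on its *type*:

* **Classical-like error** — measurements scatter randomly about the truth;
  the error is independent of the true value, the measured series is *more*
  variable than the truth, and regression slopes are attenuated toward the
  null.
* **Berkson-like error** — the truth scatters randomly about the measurement
  (the natural frame when a population-average measurement stands in for many
  individual ambient levels); the error is independent of the measurement and
  the measured series is *less* variable than the truth.

Ambient concentrations are approximately lognormal, so `airerr` models both
types *multiplicatively*: additive on the log scale. That choice has a
consequence worth stating up front: log-scale Berkson-type error is **not**
raw-scale Berkson error, and it does bias per-unit risk ratios — away from
the null — even though textbook (raw-scale, linear-model) Berkson error does
not.

`airerr` implements the full chain: quantify the error budget from monitor
data, inject calibrated error of either endpoint type (or anything in
between) by Monte Carlo, refit the health model on each error-laden series,
and quantify and analytically predict the resulting risk-ratio bias.

## The error budget: population-weighted scaled semivariance

For two monitors a distance $h$ apart, let $R$ be the Pearson correlation of
their normalized log concentration series. The *scaled semivariance*

$$\gamma'(h) = \frac{1 - R}{1 + R}$$

is 0 for perfectly correlated monitors and 1 for uncorrelated ones, and is
unitless, so error amounts are comparable across pollutants
(`scaled_semivariance_from_r()`, `pairwise_log_correlations()`).

`fit_semivariogram()` fits the exponential family
$\gamma'(h) = n + (1-n)(1 - e^{-3h/a})$ with the sill fixed at 1; the nugget
$n$ (the collocated-instrument share) is supplied, not estimated, mirroring
practice where it comes from collocated instrument pairs; the factor 3 makes
$a$ the practical range (95% of sill). The fitted curve is then evaluated at
all pairs of census-tract centroids (within-tract pairs use a configurable
average between-residence distance, default 1 km — a typical tract-scale
separation; no canonical value exists) and averaged with weights
$p_{i,j} = p_i + p_j$ over all unordered pairs including $i = j$:

$$\bar\gamma' = \frac{\sum_{i \le j} p_{i,j}\,\gamma'(h_{ij})}{\sum_{i \le j} p_{i,j}},
\qquad \bar R = \frac{1 - \bar\gamma'}{1 + \bar\gamma'}.$$

The weight normalization makes $\bar\gamma'$ a proper weighted average lying
between nugget and sill, invariant to uniform population rescaling
(`population_weighted_semivariance()`).

A note on an alternative reading: normalizing the pair semivariance by the
temporal variance of the *average* of two normalized series naively yields
$2(1-R)/(1+R)$; the factor-of-2-free form above is the one consistent with
the reference error-budget tables, and is what the package implements.

## Calibrated error injection

Given a strictly positive base-case series $Z^*_t$, standardize on the log
scale (population-SD convention, so the standardized series has mean 0 and SD
exactly 1):

$$\chi^*_t = \frac{\ln Z^*_t - \mu_{\ln Z^*}}{\sigma_{\ln Z^*}}.$$

Error is injected as

$$\chi_t = s\,\frac{\chi^*_t + \varepsilon_t}{\sqrt{1+\sigma_{err}^2}},
\qquad \varepsilon_t = \sigma_{err} N_t,
\qquad \ln Z_t = \mu_{\ln Z^*} + \sigma_{\ln Z^*}\chi_t,$$

where $N_t$ is a 3-day running mean of iid standard normals rescaled to unit
marginal variance (lag-1 autocorrelation $2/3$), emulating the short-term
temporal autocorrelation seen in between-monitor differences. The running
mean is rescaled so that $\sigma_{err}$ keeps its meaning as the log-scale
error SD regardless of the window. The realised noise is centred per draw, so
simulated and true log means agree exactly, not just in expectation.

The single formula interpolates the whole error-type continuum through the
target SD ratio $s = \sigma_{\ln Z}/\sigma_{\ln Z^*}$:

* $s = \sqrt{1+\sigma_{err}^2}$ reduces to $\chi = \chi^* + \varepsilon$ —
  the classical-like (type C) endpoint, error independent of the truth;
* $s = (1+\sigma_{err}^2)^{-1/2}$ reduces to
  $\chi = (\chi^* + \varepsilon)/(1+\sigma_{err}^2)$ — the Berkson-like
  (type B) endpoint, error independent of the measurement;
* every intermediate $s$ keeps the same log-scale correlation with the truth,
  $R(\ln Z, \ln Z^*) = (1+\sigma_{err}^2)^{-1/2}$, while sweeping the
  variance ratio. No canonical interpolation formula exists in the
  literature for the intermediate types; this one is the minimal
  one-parameter family containing both endpoints at fixed correlation.

The error amount is calibrated so that $R(\ln Z, \ln Z^*) = \sqrt{\bar R}$
(two independently error-laden series then correlate at $\bar R$):

$$\sigma_{err} = \sqrt{1/\bar R - 1}.$$

```{r}
error_budget_from_semivariance(published_error_budgets()$gamma_bar,
  pollutant = published_error_budgets()$pollutant
)
```

## The health model and its reporting conventions

`fit_health_model()` fits the log-linear count model
$\log E(Y_t) = \alpha + \beta Z_t + \boldsymbol\gamma' \mathrm{conf}_t$ by
Poisson GLM with standard errors scaled by the Pearson dispersion
(`quasipoisson`), the standard correction for overdispersed daily counts.
Associations are same-day (lag 0). Risk ratios are reported per unit of
measurement, $e^\beta$, and per interquartile range, $e^{\beta\,IQR}$, with
95% CIs from $\pm 1.96$ asymptotic SEs. The per-IQR scale matters because
error changes the spread of the measured series: classical-like error widens
the IQR, Berkson-like error narrows it, so per-unit and per-IQR biases can
have opposite signs. The IQR is computed per simulated draw and averaged for
reporting.

Monte Carlo sets are aggregated the way multi-simulation analyses report:
means over draws of $\beta$, SE and IQR; the p-value is the two-sided normal
tail of the *mean* z-statistic (`aggregate_fits()`).

The optional confounder design (`default_confounder_terms()`) mirrors common
practice: day-of-week and season indicators, cubic polynomials in maximum
temperature and dew point, and a natural spline in the day index with one
degree of freedom per ~30 days. Exact knot placement is not critical; any
smooth trend with roughly monthly flexibility serves the same role.

## Attenuation and its analytic prediction

Observed bias is expressed as percent attenuation toward the null,
$100\,(RR^* - RR)/(RR^* - 1)$, negative values meaning bias away from the
null (`percent_attenuation()`). For $\beta$ near 0 and in the absence of
confounders, the attenuation is predicted from the raw-scale least-squares
slope $m$ of the error $Z - Z^*$ on the measurement $Z$:

$$\text{per-unit } \% \approx 100\,m, \qquad
\text{per-IQR } \% \approx 100\left[1 - (1-m)\frac{IQR_Z}{IQR_{Z^*}}\right],$$

with the algebraic identity $1 - m = \mathrm{Cov}(Z^*, Z)/\mathrm{Var}(Z)$
(`predicted_attenuation()`). Raw-scale Berkson error gives $m = 0$: no
first-order per-unit bias. The slope is computed per draw and averaged,
matching the per-draw health-model fits. The predictions are only *asserted*
against confounder-free fits; with confounders they are reported but the gap
from the 1:1 line is itself informative — it indicates how much confounding
is leaking into the exposure term (`compare_predicted_observed()`).

`continuum_sweep()` traverses the error-type continuum at a fixed amount,
running a full scenario at each target $s$ with the same scenario seed, so
the endpoints reproduce plain type B/C runs exactly and adjacent steps are
paired. Along the sweep the per-unit attenuation rises from negative (bias
away) at the Berkson-like end through zero — at the error type that is
Berkson on the *raw* scale, located numerically as the point where
$R(Z - Z^*, Z)$ crosses zero rather than assumed — to strongly positive at
the classical-like end.

## The synthetic world

Because the original monitor records and visit counts are not
redistributable, the package generates study worlds with the statistical
structure the analysis assumes (`world_config()`,
`generate_monitor_field()`, `generate_tracts()`, `generate_confounders()`,
`generate_health_counts()`):

* **Exposure fields.** Marginally lognormal daily series; log-scale
  means/SDs configurable. The default single-site base case
  (`log_mean = 0.18`, `log_sd = 0.6`) resembles a 1-hr maximum CO series in
  ppm: median ≈ 1.2, IQR ≈ 1.0, matching the reference base case's IQR of
  1.00 ppm. Temporal autocorrelation comes from the same 3-day running-mean
  filter as the error process. Between-site log correlation follows
  $R(h) = (1-\gamma'(h))/(1+\gamma'(h))$ with $\gamma'(h)$ the same
  exponential semivariogram family the fitting stage uses — chosen
  deliberately so that a collocated pair's sample scaled semivariance equals
  the generating nugget and the semivariance stage can recover the
  generating nugget and range from a simulated field (an end-to-end
  identifiability check, verified in the test suite to within 20% at 10
  sites and 2,192 days). The exponential family is the simplest stationary
  isotropic model consistent with monotone empirical semivariograms;
  anisotropy is deliberately ignored.
* **Calendar.** Six calendar years, 1999-01-01 to 2004-12-31 = 2,192 days,
  the reference study period.
* **Counts.** Poisson draws from the log-linear risk model, default baseline
  76 events/day (≈ 167,000 over six years) and true RR 1.0139 per unit — the
  reference base-case association. A negative-binomial switch (`nb_size`)
  exercises the overdispersion scaling at dispersion > 1; by default counts
  are pure Poisson (dispersion ≈ 1) so both regimes are tested.
* **Tracts.** Uniformly scattered centroids with lognormal (or uniform)
  populations around a mean of 4,000 — a typical census-tract size.

What the generator does *not* emulate: real monitor siting, seasonal cycles
in the pollutant itself, cross-pollutant correlation, missing-data patterns,
or true within-city exposure gradients. Passing tests therefore demonstrate
the internal consistency and calibration of the method, not the magnitudes
any particular real dataset would produce — published risk-ratio tables from
the reference Atlanta analysis are shipped as data
(`published_risk_ratios()`) for the worked examples precisely because those
magnitudes depend on the original series.

## Numerical and design choices

* Population (1/n) SD convention throughout normalization, so standardized
  series have SD exactly 1 and the injection algebra is exact rather than
  approximate.
* Per-draw seeds derive deterministically from the scenario seed
  (`simulate_error_set()`), and all stage seeds in `run_error_study()` from
  one master seed, so every draw is independently reproducible.
* Comparative experiments (amount grids, continuum sweeps) reuse one
  scenario seed across cells — common random numbers — so monotonicity
  comparisons are paired and far more precise at a given number of draws.
* The semivariogram range is a 1-D least-squares problem solved by golden
  section (`stats::optimize`) on (0.001, 10 × max distance); a fit is
  refused when all pairs sit at one distance (range unidentifiable).
* Degenerate inputs fail loudly: constant series (zero log variance),
  constant exposure (rank-deficient design), all-zero counts, misaligned
  dates, SD-ratio targets outside the admissible interval
  $[(1+\sigma_{err}^2)^{-1/2}, (1+\sigma_{err}^2)^{1/2}]$.
* Correlation matrices implied by the semivariogram transform are factored
  by Cholesky with an eigenvalue-clipping fallback for numerically
  semi-definite cases (e.g. collocated sites).

### Problem sizes used in the shipped checks

The test suite runs the distributional calibration at the full study scale
(2,192 days, 1,000 draws), and the error-impact structure on ten independent
2,192-day worlds at 100 draws per scenario cell (12 amounts × 2 types), with
a 9-step continuum sweep at the CO-like error amount. Sign and monotonicity
assertions are made on across-world cell means: single-world means of the
smallest-amount Berkson cells sit within a Monte Carlo standard error of
zero, so pooling worlds is what gives the sign checks their power. Parameter
recovery uses 100 independent worlds. These sizes keep the full suite in the
minutes range on a single core while leaving every check comfortably
powered.

## Worked example

```{r, fig.width = 6, fig.height = 4}
world <- world_config(n_days = 2192, n_sites = 1, seed = 1)
base <- base_case_series(generate_monitor_field(world))
counts <- generate_health_counts(base, health_config(seed = 2))

spec <- error_spec(gamma_bar = 0.411, type = "C", n_sims = 50, seed = 3)
res <- run_error_scenario(base, counts, spec)
res
glance(res) |> select(type, gamma_bar, rr_unit, rr_iqr, p_value, att_unit, pred_unit)
```

## Known limitations

* The analytic attenuation predictions are first-order in $\beta$ and
  confounder-free by derivation; with strong confounding they are a
  diagnostic, not a bias correction.
* No bias-correction machinery (regression calibration, SIMEX) is included;
  the package quantifies and predicts bias, it does not undo it.
* Single pollutant at a time; correlated multi-pollutant error is out of
  scope.
* The error type of real data is not estimated — the continuum sweep shows
  the consequences of each assumed type.
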