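# Risk-ratio bias under measurement error: observed percent attenuation,
# its first-order analytic prediction from the error-vs-measurement
# regression slope, the error-type continuum sweep, and the
# predicted-vs-observed comparison.

#' Percent attenuation of a risk ratio toward the null
#'
#' \deqn{\%\,attenuation = 100\,(RR^* - RR) / (RR^* - 1)} where \eqn{RR^*}
#' is the true (error-free) risk ratio and \eqn{RR} the risk ratio obtained
#' under measurement error. 0 means no bias, 100 means the excess risk is
#' fully erased (RR = 1), and negative values mean bias *away* from the
#' null.
#'
#' @param rr_true True risk ratio(s), not equal to 1.
#' @param rr_obs Observed risk ratio(s) under error.
#' @return Percent attenuation value(s).
#' @export
#' @examples
#' percent_attenuation(1.0139, 1.0011) # ~92: nearly all excess risk erased
#' percent_attenuation(1.0139, 1.0182) # ~-31: bias away from the null
percent_attenuation <- function(rr_true, rr_obs) {
  if (any(rr_true == 1)) {
    abort("`rr_true` = 1: attenuation is undefined for a null true risk ratio.")
  }
  100 * (rr_true - rr_obs) / (rr_true - 1)
}

#' First-order error-regression slope on the raw scale
#'
#' The least-squares slope `m` of the raw-scale error (Z - Z*) regressed on
#' the measurement Z. Algebraically `m = 1 - Cov(Z*, Z)/Var(Z)`, the
#' first-order attenuation of a regression slope when Z replaces Z*. Pure
#' raw-scale Berkson error (Z* scattered about Z) gives m = 0 and hence no
#' first-order slope bias.
#'
#' @param simulated Tibble with columns `true` (Z*) and `value` (Z), as
#'   returned by [simulate_error_series()].
#' @return The scalar slope `m`.
#' @export
error_regression_slope <- function(simulated) {
  z <- simulated$value
  zs <- simulated$true
  v <- var(z)
  if (v == 0) abort("Zero variance of the measured series: slope undefined.")
  cov(z - zs, z) / v
}

#' Analytic first-order prediction of risk-ratio attenuation
#'
#' For log rate ratios near zero and in the absence of confounders, the
#' attenuation of the per-unit effect is predicted by the error-regression
#' slope `m` of [error_regression_slope()]:
#' per-unit percent attenuation \eqn{\approx 100\,m}, and per-IQR percent
#' attenuation \eqn{\approx 100\,[1 - (1 - m)\,IQR_Z / IQR_{Z^*}]} (the
#' per-IQR effect additionally rescales by the simulated-to-true IQR
#' ratio).
#'
#' @inheritParams error_regression_slope
#' @return A one-row tibble: `m_slope`, `predicted_percent_unit`,
#'   `predicted_percent_iqr`, `iqr_ratio`.
#' @export
predicted_attenuation <- function(simulated) {
  m <- error_regression_slope(simulated)
  iqr_ratio <- IQR(simulated$value) / IQR(simulated$true)
  tibble::tibble(
    m_slope = m,
    predicted_percent_unit = 100 * m,
    predicted_percent_iqr = 100 * (1 - (1 - m) * iqr_ratio),
    iqr_ratio = iqr_ratio
  )
}

#' Run one full error scenario
#'
#' Simulates `spec$n_sims` error-laden exposure series from the true base
#' case, fits the health model to each, and summarizes: aggregated risk
#' ratios (see [aggregate_fits()]), observed percent attenuation relative
#' to the error-free fit (both from aggregated RRs and as the mean of
#' per-draw attenuations), and the analytic first-order predictions.
#'
#' @param base Tibble `date`, `value`: the true exposure series.
#' @param health_data Tibble with `date`, `count` and any confounder
#'   columns, aligned to `base$date`.
#' @param spec An [error_spec()].
#' @param confounders Optional character vector of confounder model terms
#'   passed to [fit_health_model()].
#' @param base_fit Optional pre-computed error-free `epi_fit` on `base`
#'   (computed here when omitted).
#' @return An object of class `scenario_result`: list with `spec`,
#'   `base_fit`, per-draw tibble `draws` and one-row tibble `summary`.
#'   `tidy()` returns the draws, `glance()` the summary.
#' @export
run_error_scenario <- function(base, health_data, spec, confounders = NULL,
                               base_fit = NULL) {
  stopifnot(inherits(spec, "error_spec"))
  if (!identical(as.Date(health_data$date), as.Date(base$date))) {
    abort("`health_data` dates are not aligned with `base` dates.")
  }
  covars <- dplyr::select(health_data, -dplyr::any_of("exposure"))
  if (is.null(base_fit)) {
    base_fit <- fit_health_model(
      dplyr::mutate(covars, exposure = base$value),
      confounders = confounders
    )
  }
  sims <- simulate_error_set(base, spec, keep_series = TRUE)
  draws <- purrr::map_dfr(seq_len(nrow(sims)), function(i) {
    sim <- sims$series[[i]]
    fit <- fit_health_model(
      dplyr::mutate(covars, exposure = sim$value),
      confounders = confounders
    )
    pred <- predicted_attenuation(sim)
    tibble::tibble(
      draw = i,
      beta = fit$beta, se_beta = fit$se_beta, z = fit$z, p_value = fit$p,
      dispersion = fit$dispersion, iqr = fit$iqr_used,
      rr_unit = fit$rr_unit, rr_iqr = fit$rr_iqr,
      r_log = sims$r_log[i], s_ratio = sims$s_ratio[i],
      att_unit = percent_attenuation(base_fit$rr_unit, fit$rr_unit),
      att_iqr = percent_attenuation(base_fit$rr_iqr, fit$rr_iqr),
      m_slope = pred$m_slope,
      pred_unit = pred$predicted_percent_unit,
      pred_iqr = pred$predicted_percent_iqr,
      r_raw_err = cor(sim$value - sim$true, sim$value)
    )
  })
  agg <- aggregate_fits(draws)
  summary <- dplyr::bind_cols(
    tibble::tibble(
      type = spec$type, gamma_bar = spec$gamma_bar,
      sigma_err = spec$sigma_err, target_s_ratio = spec$s_ratio
    ),
    agg,
    tibble::tibble(
      att_unit = percent_attenuation(base_fit$rr_unit, agg$rr_unit),
      att_iqr = percent_attenuation(base_fit$rr_iqr, agg$rr_iqr),
      mean_att_unit = mean(draws$att_unit), sd_att_unit = sd(draws$att_unit),
      mean_att_iqr = mean(draws$att_iqr), sd_att_iqr = sd(draws$att_iqr),
      pred_unit = mean(draws$pred_unit), sd_pred_unit = sd(draws$pred_unit),
      pred_iqr = mean(draws$pred_iqr), sd_pred_iqr = sd(draws$pred_iqr),
      mean_r_raw_err = mean(draws$r_raw_err)
    )
  )
  structure(
    list(spec = spec, base_fit = base_fit, draws = draws, summary = summary),
    class = "scenario_result"
  )
}

#' @export
print.scenario_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "Error scenario type %s (gamma_bar %.3f, sigma_err %.2f, %d draws)\n",
    s$type, s$gamma_bar, s$sigma_err, s$n_fits
  ))
  cat(sprintf(
    "  RR per unit %.4f | RR per IQR %.4f | p %.3g\n",
    s$rr_unit, s$rr_iqr, s$p_value
  ))
  cat(sprintf(
    "  attenuation per unit %.1f%% (predicted %.1f%%) | per IQR %.1f%% (predicted %.1f%%)\n",
    s$att_unit, s$pred_unit, s$att_iqr, s$pred_iqr
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.scenario_result <- function(x, ...) x$draws

#' @exportS3Method generics::glance
glance.scenario_result <- function(x, ...) x$summary

#' Sweep the error-type continuum between Berkson and classical endpoints
#'
#' Holds the amount of error fixed and varies the target log-SD ratio
#' \eqn{s = \sigma_{\ln Z}/\sigma_{\ln Z^*}} over `n_steps` equally spaced
#' values from the Berkson-like endpoint \eqn{(1+\sigma_{err}^2)^{-1/2}} to
#' the classical-like endpoint \eqn{(1+\sigma_{err}^2)^{1/2}}, running a
#' full scenario at each step with the same scenario seed (so the endpoint
#' rows reproduce plain type B / type C runs exactly).
#'
#' @inheritParams run_error_scenario
#' @param sigma_err Log-scale error SD (> 0) defining the error amount.
#' @param n_steps Number of s-ratio steps (>= 2).
#' @param n_sims Draws per step.
#' @param seed Scenario seed shared by all steps.
#' @return A tibble of class `continuum_sweep`: one summary row per step
#'   (columns as in the `summary` of [run_error_scenario()]).
#' @export
continuum_sweep <- function(base, health_data, sigma_err, n_steps = 9,
                            n_sims = 100, seed = 1L, confounders = NULL) {
  if (sigma_err <= 0) abort("`sigma_err` must be positive for a sweep.")
  if (n_steps < 2) abort("`n_steps` must be >= 2.")
  s_lo <- sd_ratio(sigma_err, "B")
  s_hi <- sd_ratio(sigma_err, "C")
  s_grid <- seq(s_lo, s_hi, length.out = n_steps)
  covars <- dplyr::select(health_data, -dplyr::any_of("exposure"))
  base_fit <- fit_health_model(
    dplyr::mutate(covars, exposure = base$value),
    confounders = confounders
  )
  out <- purrr::map_dfr(seq_along(s_grid), function(k) {
    s <- s_grid[k]
    spec <- if (k == 1) {
      error_spec(sigma_err = sigma_err, type = "B", n_sims = n_sims, seed = seed)
    } else if (k == n_steps) {
      error_spec(sigma_err = sigma_err, type = "C", n_sims = n_sims, seed = seed)
    } else {
      error_spec(
        sigma_err = sigma_err, type = "intermediate", s_ratio = s,
        n_sims = n_sims, seed = seed
      )
    }
    res <- run_error_scenario(base, health_data, spec,
      confounders = confounders, base_fit = base_fit
    )
    dplyr::mutate(res$summary, step = k, .before = 1)
  })
  class(out) <- c("continuum_sweep", class(out))
  out
}

#' Locate the s-ratio at which per-unit attenuation changes sign
#'
#' Along a continuum sweep the predicted per-unit attenuation is negative
#' at the Berkson-like end and positive at the classical-like end; the
#' crossing marks the error type that is Berkson on the *raw* (unlogged)
#' scale, where the raw-scale error is uncorrelated with the measurement
#' and first-order slope bias vanishes. Located by linear interpolation of
#' the sweep column.
#'
#' @param sweep A [continuum_sweep()] result.
#' @param column Which attenuation column to root-find (default the
#'   analytic `pred_unit`).
#' @return The interpolated `s_ratio` at the sign change, or `NA` if the
#'   column does not change sign inside the sweep.
#' @export
sweep_zero_crossing <- function(sweep, column = "pred_unit") {
  s <- sweep$target_s_ratio
  y <- sweep[[column]]
  sgn <- sign(y)
  idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  if (length(idx) == 0) {
    return(NA_real_)
  }
  i <- idx[1]
  s[i] + (0 - y[i]) * (s[i + 1] - s[i]) / (y[i + 1] - y[i])
}

#' Compare analytic predictions with epidemiologic-model attenuation
#'
#' Pairs the analytic first-order attenuation predictions with the
#' attenuation observed in the health-model fits across scenarios, and
#' reports the mean absolute deviation from the 1:1 line on both the
#' per-unit and per-IQR scales. Close 1:1 agreement is expected for
#' confounder-free worlds; a growing gap indicates confounding leaking
#' into the exposure effect.
#'
#' @param scenarios A list of `scenario_result` objects, or a tibble of
#'   scenario summary rows (as from `glance()`).
#' @return An object of class `attenuation_comparison`: list with the
#'   pairwise `comparison` tibble and scalars `mad_unit`, `mad_iqr`
#'   (mean absolute deviations, percentage points).
#' @export
compare_predicted_observed <- function(scenarios) {
  summaries <- if (is.data.frame(scenarios)) {
    tibble::as_tibble(scenarios)
  } else {
    if (length(scenarios) < 2) abort("Need at least 2 scenarios to compare.")
    purrr::map_dfr(scenarios, glance)
  }
  comparison <- summaries |>
    dplyr::transmute(
      type = .data$type, gamma_bar = .data$gamma_bar,
      observed_unit = .data$mean_att_unit, predicted_unit = .data$pred_unit,
      observed_iqr = .data$mean_att_iqr, predicted_iqr = .data$pred_iqr
    )
  structure(
    list(
      comparison = comparison,
      mad_unit = mean(abs(comparison$observed_unit - comparison$predicted_unit)),
      mad_iqr = mean(abs(comparison$observed_iqr - comparison$predicted_iqr))
    ),
    class = "attenuation_comparison"
  )
}

#' @export
print.attenuation_comparison <- function(x, ...) {
  cat(sprintf(
    "Predicted vs observed attenuation over %d scenarios\n", nrow(x$comparison)
  ))
  cat(sprintf(
    "  mean |predicted - observed|: %.2f pp (per unit), %.2f pp (per IQR)\n",
    x$mad_unit, x$mad_iqr
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.attenuation_comparison <- function(x, ...) x$comparison

#' @exportS3Method generics::glance
glance.attenuation_comparison <- function(x, ...) {
  tibble::tibble(
    n_scenarios = nrow(x$comparison),
    mad_unit = x$mad_unit, mad_iqr = x$mad_iqr
  )
}
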