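# Overdispersion-scaled Poisson health model: fits daily counts against an
# exposure series (lag 0) plus confounders, and reports risk ratios per
# measurement unit and per interquartile range with asymptotic uncertainty.

#' Default confounder model terms
#'
#' The confounder design used by the reference analysis style: day-of-week
#' and season indicators, cubic polynomials in maximum temperature and dew
#' point, and a natural cubic spline in the day index with roughly monthly
#' flexibility (one df per ~30 days of follow-up).
#'
#' @param n_days Study length, used to size the time spline.
#' @return Character vector of model terms for [fit_health_model()].
#' @export
default_confounder_terms <- function(n_days) {
  df_time <- max(3L, round(n_days / 30.44))
  c(
    "dow", "season",
    "poly(temperature, 3)", "poly(dew_point, 3)",
    sprintf("splines::ns(day_index, df = %d)", df_time)
  )
}

#' Fit the quasi-Poisson health model
#'
#' Fits the log-linear count model
#' \deqn{\log E(Y_t) = \alpha + \beta Z_t + \gamma' \mathrm{conf}_t}
#' by Poisson GLM with standard errors scaled by the square root of the
#' Pearson dispersion (`stats::glm` with `family = quasipoisson`), the
#' standard correction for overdispersed daily counts. The association is
#' same-day (lag 0): `data` is one row per day with the count and that
#' day's exposure.
#'
#' @param data A tibble with one row per day containing the count column,
#'   the exposure column, and any confounder columns referenced by
#'   `confounders`.
#' @param exposure,count Column names (strings) of the exposure and the
#'   daily count.
#' @param confounders Optional character vector of confounder model terms
#'   (e.g. `default_confounder_terms(nrow(data))`); `NULL` fits the
#'   exposure-only model.
#' @return An object of class `epi_fit`: log rate ratio `beta` with scaled
#'   `se`, Pearson `dispersion`, `z`, two-sided normal `p`, the exposure
#'   `iqr`, and risk ratios per unit and per IQR with 95% CIs. Supports
#'   [tidy()] and [glance()].
#' @export
fit_health_model <- function(data, exposure = "exposure", count = "count",
                             confounders = NULL) {
  if (!all(c(exposure, count) %in% names(data))) {
    abort(sprintf("`data` must contain columns '%s' and '%s'.", exposure, count))
  }
  y <- data[[count]]
  if (anyNA(y) || any(y < 0) || any(y != round(y))) {
    abort("Counts must be nonnegative integers with no missing values.")
  }
  if (all(y == 0)) abort("Degenerate fit: all counts are zero.")
  z_var <- data[[exposure]]
  if (pop_sd(z_var) == 0) {
    abort("Exposure is constant: beta is unidentifiable (rank-deficient design).")
  }
  rhs <- paste(c(sprintf("`%s`", exposure), confounders), collapse = " + ")
  form <- stats::as.formula(sprintf("`%s` ~ %s", count, rhs))
  fit <- withCallingHandlers(
    glm(form, family = quasipoisson(link = "log"), data = data),
    warning = function(w) {
      if (grepl("did not converge", conditionMessage(w))) {
        abort(paste0("Health-model fit did not converge: ", conditionMessage(w)))
      }
      invokeRestart("muffleWarning")
    }
  )
  cf <- coef(fit)
  if (anyNA(cf)) {
    abort(paste0(
      "Rank-deficient health-model design; aliased terms: ",
      paste(names(cf)[is.na(cf)], collapse = ", ")
    ))
  }
  sm <- summary(fit)
  idx <- sprintf("`%s`", exposure)
  if (!idx %in% rownames(sm$coefficients)) idx <- exposure
  beta <- sm$coefficients[idx, "Estimate"]
  se <- sm$coefficients[idx, "Std. Error"]
  z_stat <- beta / se
  iqr <- IQR(z_var)
  structure(
    c(
      list(
        beta = beta, se_beta = se, dispersion = sm$dispersion,
        z = z_stat, p = 2 * pnorm(-abs(z_stat)),
        iqr_used = iqr, n_days = length(y), df_residual = fit$df.residual
      ),
      as.list(risk_ratios(beta, se, iqr))
    ),
    class = "epi_fit"
  )
}

#' @export
print.epi_fit <- function(x, ...) {
  cat(sprintf(
    "Quasi-Poisson health model (n = %d days, dispersion %.2f)\n",
    x$n_days, x$dispersion
  ))
  cat(sprintf(
    "  RR per unit %.4f (%.4f-%.4f) | IQR %.2f | RR per IQR %.4f (%.4f-%.4f) | p %.3g\n",
    x$rr_unit, x$rr_unit_lo, x$rr_unit_hi, x$iqr_used,
    x$rr_iqr, x$rr_iqr_lo, x$rr_iqr_hi, x$p
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.epi_fit <- function(x, ...) {
  tibble::tibble(
    term = "exposure",
    estimate = x$beta, std.error = x$se_beta,
    statistic = x$z, p.value = x$p
  )
}

#' @exportS3Method generics::glance
glance.epi_fit <- function(x, ...) {
  tibble::tibble(
    beta = x$beta, se_beta = x$se_beta, dispersion = x$dispersion,
    z = x$z, p_value = x$p, iqr = x$iqr_used,
    rr_unit = x$rr_unit, rr_unit_lo = x$rr_unit_lo, rr_unit_hi = x$rr_unit_hi,
    rr_iqr = x$rr_iqr, rr_iqr_lo = x$rr_iqr_lo, rr_iqr_hi = x$rr_iqr_hi,
    n_days = x$n_days
  )
}

#' Risk ratios per unit and per interquartile range
#'
#' \eqn{RR_{unit} = e^{\beta}} with 95% CI \eqn{e^{\beta \pm 1.96\,se}};
#' \eqn{RR_{IQR} = e^{\beta \cdot IQR}} with CI
#' \eqn{e^{(\beta \pm 1.96\,se) \cdot IQR}}. The per-IQR scale expresses
#' the effect over the realised spread of the exposure series, which makes
#' results comparable across error scenarios whose measured series have
#' different spreads.
#'
#' @param beta Log rate ratio per exposure unit.
#' @param se Standard error of `beta` (>= 0).
#' @param iqr Interquartile range of the exposure (> 0).
#' @return A one-row tibble: `rr_unit`, `rr_unit_lo`, `rr_unit_hi`,
#'   `rr_iqr`, `rr_iqr_lo`, `rr_iqr_hi`.
#' @export
#' @examples
#' risk_ratios(log(1.0021), 0.00095, iqr = 1.57)
risk_ratios <- function(beta, se, iqr) {
  if (any(se < 0)) abort("`se` must be nonnegative.")
  if (any(iqr <= 0)) abort("`iqr` must be positive.")
  tibble::tibble(
    rr_unit = exp(beta),
    rr_unit_lo = exp(beta - 1.96 * se),
    rr_unit_hi = exp(beta + 1.96 * se),
    rr_iqr = exp(beta * iqr),
    rr_iqr_lo = exp((beta - 1.96 * se) * iqr),
    rr_iqr_hi = exp((beta + 1.96 * se) * iqr)
  )
}

#' Aggregate health-model fits over Monte Carlo draws
#'
#' Summarizes a set of per-draw fits the way the reference analysis
#' reports them: coefficients, standard errors and IQRs are averaged over
#' draws, the p-value is the two-sided normal tail of the *average*
#' z-statistic, and 95% CIs use the average asymptotic SE around the
#' average coefficient.
#'
#' @param fits A list of `epi_fit` objects, or a tibble of per-draw
#'   statistics with columns `beta`, `se_beta`, `z`, `iqr` (e.g. from
#'   `purrr::map_dfr(fits, glance)`).
#' @return A one-row tibble of class `epi_summary`: `n_fits`, `mean_beta`,
#'   `sd_beta`, `mean_se`, `mean_z`, `p_value`, `mean_iqr`, `mean_dispersion`
#'   and aggregated risk ratios `rr_unit`/`rr_iqr` with CIs.
#' @export
aggregate_fits <- function(fits) {
  if (inherits(fits, "epi_fit")) fits <- list(fits)
  draws <- if (is.data.frame(fits)) {
    tibble::as_tibble(fits)
  } else {
    if (length(fits) == 0) abort("No fits to aggregate.")
    purrr::map_dfr(fits, function(f) {
      tibble::tibble(
        beta = f$beta, se_beta = f$se_beta, z = f$z,
        iqr = f$iqr_used, dispersion = f$dispersion
      )
    })
  }
  if (nrow(draws) == 0) abort("No fits to aggregate.")
  if (!"iqr" %in% names(draws) && "iqr_used" %in% names(draws)) {
    draws$iqr <- draws$iqr_used
  }
  mean_beta <- mean(draws$beta)
  mean_se <- mean(draws$se_beta)
  mean_z <- mean(draws$z)
  mean_iqr <- mean(draws$iqr)
  rr <- risk_ratios(mean_beta, mean_se, mean_iqr)
  out <- dplyr::bind_cols(
    tibble::tibble(
      n_fits = nrow(draws),
      mean_beta = mean_beta, sd_beta = sd(draws$beta) %||% NA_real_,
      mean_se = mean_se, mean_z = mean_z,
      p_value = 2 * pnorm(-abs(mean_z)),
      mean_iqr = mean_iqr,
      mean_dispersion = if ("dispersion" %in% names(draws)) mean(draws$dispersion) else NA_real_
    ),
    rr
  )
  class(out) <- c("epi_summary", class(out))
  out
}
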