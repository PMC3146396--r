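# ggplot2 views of the main result types.

#' @exportS3Method ggplot2::autoplot
autoplot.semivariogram_fit <- function(object, ...) {
  h_max <- max(object$pairs$distance_km)
  curve_tbl <- tibble::tibble(
    distance_km = seq(0, h_max * 1.05, length.out = 200),
    gamma = predict(object, seq(0, h_max * 1.05, length.out = 200))
  )
  ggplot2::ggplot(object$pairs, ggplot2::aes(x = .data$distance_km, y = .data$gamma)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = curve_tbl, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(
      x = "Distance between monitors (km)",
      y = "Scaled semivariance γ'",
      title = sprintf(
        "Scaled semivariogram (nugget %.2f, range %.0f km)",
        object$nugget, object$range_km
      )
    ) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.error_sim_set <- function(object, ...) {
  spec <- attr(object, "spec")
  ggplot2::ggplot(object, ggplot2::aes(x = "", y = .data$r_log)) +
    ggplot2::geom_boxplot(width = 0.3, fill = "grey85") +
    ggplot2::geom_hline(
      yintercept = 1 / sqrt(1 + spec$sigma_err^2),
      colour = "steelblue", linetype = "dashed"
    ) +
    ggplot2::labs(
      x = NULL, y = "R(ln Z, ln Z*) per draw",
      title = sprintf(
        "Achieved log-scale correlation, type %s (target %.3f)",
        spec$type, 1 / sqrt(1 + spec$sigma_err^2)
      )
    ) +
    ggplot2::theme_minimal()
}

#' P-value versus error amount across scenarios
#'
#' Aggregated health-model p-values against the population-weighted scaled
#' semivariance, by error type: statistical significance erodes as the
#' error budget grows.
#'
#' @param summary Scenario summary tibble (from `tidy()` of an
#'   `error_study`, or any tibble with `gamma_bar`, `p_value`, `type`).
#' @return A ggplot object.
#' @export
plot_significance <- function(summary) {
  ggplot2::ggplot(summary, ggplot2::aes(
    x = .data$gamma_bar, y = .data$p_value,
    colour = .data$type, shape = .data$type
  )) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0.05, linetype = "dashed") +
    ggplot2::labs(
      x = "Population-weighted scaled semivariance γ̄'",
      y = "p-value (from mean z)",
      colour = "Error type", shape = "Error type"
    ) +
    ggplot2::theme_minimal()
}

#' Attenuation versus error amount across scenarios
#'
#' Observed percent attenuation (mean over draws, with SD bars) against
#' the error budget, per unit of measurement and per IQR, by error type.
#'
#' @inheritParams plot_significance
#' @return A ggplot object.
#' @export
plot_attenuation <- function(summary) {
  long <- summary |>
    dplyr::select(
      "gamma_bar", "type",
      unit = "mean_att_unit", iqr = "mean_att_iqr",
      sd_unit = "sd_att_unit", sd_iqr = "sd_att_iqr"
    ) |>
    tidyr::pivot_longer(c("unit", "iqr"), names_to = "scale", values_to = "attenuation") |>
    dplyr::mutate(sd = ifelse(.data$scale == "unit", .data$sd_unit, .data$sd_iqr))
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$gamma_bar, y = .data$attenuation,
    colour = .data$type, shape = .data$type
  )) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$attenuation - .data$sd,
      ymax = .data$attenuation + .data$sd
    )) +
    ggplot2::facet_wrap(~ .data$scale, labeller = ggplot2::labeller(
      scale = c(unit = "per unit of measurement", iqr = "per IQR")
    )) +
    ggplot2::labs(
      x = "Population-weighted scaled semivariance γ̄'",
      y = "Percent attenuation in RR",
      colour = "Error type", shape = "Error type"
    ) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.continuum_sweep <- function(object, ...) {
  long <- object |>
    dplyr::select(
      "target_s_ratio",
      unit = "mean_att_unit", iqr = "mean_att_iqr",
      sd_unit = "sd_att_unit", sd_iqr = "sd_att_iqr"
    ) |>
    tidyr::pivot_longer(c("unit", "iqr"), names_to = "scale", values_to = "attenuation") |>
    dplyr::mutate(sd = ifelse(.data$scale == "unit", .data$sd_unit, .data$sd_iqr))
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$target_s_ratio, y = .data$attenuation,
    colour = .data$scale, shape = .data$scale
  )) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$attenuation - .data$sd,
      ymax = .data$attenuation + .data$sd
    )) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = expression(sigma[lnZ] / sigma[lnZ * "*"] ~ "(Berkson-like → classical-like)"),
      y = "Percent attenuation in RR",
      colour = "Scale", shape = "Scale"
    ) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.attenuation_comparison <- function(object, ...) {
  long <- object$comparison |>
    tidyr::pivot_longer(
      cols = c("observed_unit", "observed_iqr"),
      names_to = "scale", values_to = "observed"
    ) |>
    dplyr::mutate(
      predicted = ifelse(.data$scale == "observed_unit",
        .data$predicted_unit, .data$predicted_iqr
      ),
      scale = ifelse(.data$scale == "observed_unit", "per unit", "per IQR")
    )
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$predicted, y = .data$observed,
    colour = .data$type
  )) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::facet_wrap(~ .data$scale, scales = "free") +
    ggplot2::labs(
      x = "Predicted attenuation (%)", y = "Observed attenuation (%)",
      colour = "Error type"
    ) +
    ggplot2::theme_minimal()
}
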