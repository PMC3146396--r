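# End-to-end orchestration: synthesize a study world, quantify its spatial
# error budget, inject error over a grid of amounts and types, fit health
# models, and tabulate attenuation -- reproducibly from one master seed.

#' Configure an end-to-end error study
#'
#' @param world A [world_config()] for the synthetic monitor field. Use
#'   `n_sites >= 2` if the semivariance stage should be run on the
#'   generated field.
#' @param health A [health_config()] for the synthetic counts.
#' @param gamma_bars Numeric vector of population-weighted scaled
#'   semivariances defining the error amounts (default: the twelve
#'   published budgets of [published_error_budgets()]).
#' @param labels Optional labels for the error amounts.
#' @param types Error types to run per amount (default both endpoints).
#' @param n_sims Monte Carlo draws per scenario.
#' @param n_tracts Number of synthetic census tracts for the semivariance
#'   stage (used when `world$n_sites >= 2`).
#' @param confounders `NULL` for confounder-free fits, or a character
#'   vector of model terms (see [default_confounder_terms()]); the same
#'   terms' data columns must be generated, so `TRUE` means "use the
#'   synthetic confounders with the default design".
#' @param master_seed Single integer from which all stage seeds derive.
#' @param out_dir Optional directory: when given, stage outputs are
#'   written as CSVs plus a run manifest.
#' @return An object of class `study_config`.
#' @export
study_config <- function(world = world_config(), health = health_config(),
                         gamma_bars = published_error_budgets()$gamma_bar,
                         labels = NULL, types = c("C", "B"),
                         n_sims = 100, n_tracts = 100,
                         confounders = NULL, master_seed = 1L,
                         out_dir = NULL) {
  stopifnot(inherits(world, "world_config"), inherits(health, "health_config"))
  if (any(!types %in% c("C", "B"))) abort("`types` must be 'C' and/or 'B'.")
  labels <- labels %||% (
    if (identical(gamma_bars, published_error_budgets()$gamma_bar)) {
      published_error_budgets()$pollutant
    } else {
      sprintf("amount_%02d", seq_along(gamma_bars))
    }
  )
  if (length(labels) != length(gamma_bars)) {
    abort("`labels` must match `gamma_bars` in length.")
  }
  if (anyDuplicated(labels)) abort("Scenario labels must be unique.")
  structure(
    list(
      world = world, health = health,
      gamma_bars = gamma_bars, labels = labels, types = types,
      n_sims = as.integer(n_sims), n_tracts = as.integer(n_tracts),
      confounders = confounders,
      master_seed = as.integer(master_seed), out_dir = out_dir
    ),
    class = "study_config"
  )
}

#' Run a full error-impact study
#'
#' Executes the whole pipeline on one synthetic world:
#' 1. generate the monitor field, tract table, confounders and counts;
#' 2. (if the world has >= 2 sites) estimate the world's own error budget:
#'    pairwise log correlations, semivariogram fit, population-weighted
#'    semivariance;
#' 3. for every (error amount x error type) cell, simulate error-laden
#'    series, fit health models, and compute observed and predicted
#'    attenuation.
#'
#' All stage seeds derive deterministically from `config$master_seed`, so
#' reruns are bit-for-bit identical. When `config$out_dir` is set, the
#' error-budget table, the scenario summary table (risk ratios and
#' p-values), the attenuation table and a run manifest are written as CSVs.
#'
#' @param config A [study_config()].
#' @return An object of class `error_study`: list with `base` (true
#'   series), `base_fit`, `world_budget` (or `NULL`), `scenarios` (named
#'   list of `scenario_result`), `summary` (one row per scenario),
#'   `budgets` (closed-form error budget per amount) and `config`.
#' @export
run_error_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  seeds <- derive_seeds(config$master_seed, 4 + length(config$gamma_bars) * length(config$types))

  world <- config$world
  world$seed <- seeds[1]
  field <- generate_monitor_field(world)
  base <- base_case_series(field)

  conf_tbl <- generate_confounders(world$n_days, world$start_date, seed = seeds[2])
  health <- config$health
  health$seed <- seeds[3]
  counts <- generate_health_counts(base, health, confounders = conf_tbl)
  health_data <- dplyr::left_join(counts, conf_tbl, by = "date")

  world_budget <- NULL
  if (world$n_sites >= 2) {
    pairs <- pairwise_log_correlations(field, min_overlap = min(365, world$n_days))
    svfit <- fit_semivariogram(pairs, nugget = world$nugget)
    tracts <- generate_tracts(config$n_tracts, seed = seeds[4])
    pw <- population_weighted_semivariance(svfit, tracts)
    world_budget <- dplyr::bind_cols(
      error_budget_from_semivariance(pw$gamma_bar, pollutant = "synthetic world"),
      tibble::tibble(fitted_range_km = svfit$range_km, nugget = svfit$nugget)
    )
  }

  covars <- health_data
  base_fit <- fit_health_model(
    dplyr::mutate(covars, exposure = base$value),
    confounders = config$confounders
  )

  grid <- tidyr::expand_grid(
    label = config$labels,
    type = config$types
  ) |>
    dplyr::left_join(
      tibble::tibble(label = config$labels, gamma_bar = config$gamma_bars),
      by = "label"
    )
  scenario_seeds <- seeds[-(1:4)]
  scenarios <- purrr::map(seq_len(nrow(grid)), function(k) {
    spec <- error_spec(
      gamma_bar = grid$gamma_bar[k], type = grid$type[k],
      n_sims = config$n_sims, seed = scenario_seeds[k]
    )
    run_error_scenario(base, health_data, spec,
      confounders = config$confounders, base_fit = base_fit
    )
  })
  names(scenarios) <- paste(grid$label, grid$type, sep = " / ")
  summary <- purrr::map_dfr(seq_along(scenarios), function(k) {
    dplyr::bind_cols(
      tibble::tibble(scenario = names(scenarios)[k], label = grid$label[k]),
      scenarios[[k]]$summary
    )
  })

  study <- structure(
    list(
      base = base, base_fit = base_fit, world_budget = world_budget,
      scenarios = scenarios, summary = summary,
      budgets = error_budget_from_semivariance(config$gamma_bars, pollutant = config$labels),
      config = config
    ),
    class = "error_study"
  )
  if (!is.null(config$out_dir)) write_study_outputs(study, config$out_dir)
  study
}

#' @export
print.error_study <- function(x, ...) {
  cat(sprintf(
    "Measurement-error impact study: %d scenarios x %d draws on a %d-day world\n",
    nrow(x$summary), x$config$n_sims, x$config$world$n_days
  ))
  cat(sprintf(
    "  base case RR per unit %.4f (p %.2g)\n",
    x$base_fit$rr_unit, x$base_fit$p
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.error_study <- function(x, ...) x$summary

#' @exportS3Method generics::glance
glance.error_study <- function(x, ...) {
  tibble::tibble(
    n_scenarios = nrow(x$summary),
    n_sims = x$config$n_sims,
    n_days = x$config$world$n_days,
    base_rr_unit = x$base_fit$rr_unit,
    base_p = x$base_fit$p
  )
}

# Stage outputs as plain-text CSVs plus a manifest of seeds and parameters.
write_study_outputs <- function(study, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(study$budgets, file.path(out_dir, "error_budgets.csv"))
  if (!is.null(study$world_budget)) {
    readr::write_csv(study$world_budget, file.path(out_dir, "world_budget.csv"))
  }
  rr_tbl <- study$summary |>
    dplyr::select(
      "scenario", "type", "gamma_bar",
      "rr_unit", "rr_unit_lo", "rr_unit_hi",
      "mean_iqr", "rr_iqr", "rr_iqr_lo", "rr_iqr_hi", "p_value"
    )
  readr::write_csv(rr_tbl, file.path(out_dir, "risk_ratios.csv"))
  att_tbl <- study$summary |>
    dplyr::select(
      "scenario", "type", "gamma_bar",
      "att_unit", "att_iqr", "mean_att_unit", "sd_att_unit",
      "mean_att_iqr", "sd_att_iqr",
      "pred_unit", "sd_pred_unit", "pred_iqr", "sd_pred_iqr"
    )
  readr::write_csv(att_tbl, file.path(out_dir, "attenuation.csv"))
  manifest <- tibble::tibble(
    key = c(
      "master_seed", "n_sims", "n_days", "n_sites", "n_tracts",
      "log_mean", "log_sd", "spatial_range", "nugget",
      "alpha", "beta_true", "airerr_version"
    ),
    value = as.character(c(
      study$config$master_seed, study$config$n_sims,
      study$config$world$n_days, study$config$world$n_sites,
      study$config$n_tracts,
      study$config$world$log_mean, study$config$world$log_sd,
      study$config$world$spatial_range, study$config$world$nugget,
      study$config$health$alpha, study$config$health$beta_true,
      as.character(utils::packageVersion("airerr"))
    ))
  )
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
  invisible(study)
}
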