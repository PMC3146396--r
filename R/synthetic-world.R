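# Synthetic study world: emulates the inputs a real analysis would obtain
# from a monitor network, the census, and hospital records -- a lognormal
# daily pollutant field with distance-decaying between-site correlation,
# tract populations, confounders, and Poisson daily counts generated from a
# known log-linear risk model -- so every downstream stage is testable with
# known ground truth.

#' Configure a synthetic monitoring world
#'
#' @param n_days Study length in days (default 2192 = the six calendar years
#'   1999--2004).
#' @param start_date First study day.
#' @param n_sites Number of monitoring sites.
#' @param site_coords Optional matrix/data frame of site coordinates in km
#'   (columns x, y). When omitted, sites are scattered uniformly over
#'   `extent_km` x `extent_km` under `seed`.
#' @param extent_km Side of the square study region (km), default 60 (a
#'   metropolitan-scale domain).
#' @param log_mean,log_sd Mean and SD of the log daily concentration. The
#'   defaults (0.18, 0.6) give a series resembling 1-hr maximum CO in ppm:
#'   median about 1.2 ppm and interquartile range about 1.0 ppm.
#' @param spatial_range Practical range (km) of the between-site scaled
#'   semivariogram: gamma' reaches ~95% of the sill at this distance.
#' @param nugget Collocated-instrument share of the scaled semivariance at
#'   h = 0, in \[0, 1).
#' @param temporal_corr_days Running-average window giving the log series
#'   its short-term autocorrelation (default 3 days).
#' @param seed Integer seed.
#' @return An object of class `world_config` (validated list).
#' @export
world_config <- function(n_days = 2192, start_date = "1999-01-01",
                         n_sites = 1, site_coords = NULL, extent_km = 60,
                         log_mean = 0.18, log_sd = 0.6,
                         spatial_range = 50, nugget = 0.05,
                         temporal_corr_days = 3, seed = 1L) {
  n_days <- as.integer(n_days)
  if (n_days < 30) abort("`n_days` must be at least 30.")
  if (!is.finite(log_sd) || log_sd <= 0) abort("`log_sd` must be positive.")
  if (nugget < 0 || nugget >= 1) abort("`nugget` must lie in [0, 1).")
  if (spatial_range <= 0) abort("`spatial_range` must be positive.")
  if (is.null(site_coords)) {
    site_coords <- with_seed(seed, matrix(runif(2 * n_sites, 0, extent_km), ncol = 2))
  } else {
    site_coords <- as.matrix(as.data.frame(site_coords))
    if (ncol(site_coords) != 2) abort("`site_coords` must have two columns (x, y in km).")
    n_sites <- nrow(site_coords)
  }
  if (!all(is.finite(site_coords))) abort("Site coordinates must be finite.")
  structure(
    list(
      n_days = n_days, start_date = start_date,
      n_sites = as.integer(n_sites), site_coords = site_coords,
      log_mean = log_mean, log_sd = log_sd,
      spatial_range = spatial_range, nugget = nugget,
      temporal_corr_days = as.integer(temporal_corr_days),
      seed = as.integer(seed)
    ),
    class = "world_config"
  )
}

# Between-site log-correlation implied by the generating semivariogram:
# R(h) = (1 - gamma'(h)) / (1 + gamma'(h)) with the same exponential family
# the fitting module uses, so the semivariance stage can recover the
# generating nugget and range from a simulated field.
world_correlation_matrix <- function(config) {
  h <- pair_distances(config$site_coords)
  g <- semivariogram_model(h, config$nugget, config$spatial_range)
  cmat <- (1 - g) / (1 + g)
  diag(cmat) <- 1
  cmat
}

# Cholesky-like factor with an eigenvalue-clipping fallback for correlation
# matrices that are numerically semi-definite (e.g. collocated sites).
corr_factor <- function(cmat) {
  ch <- tryCatch(chol(cmat), error = function(e) NULL)
  if (!is.null(ch)) return(t(ch))
  e <- eigen(cmat, symmetric = TRUE)
  vals <- pmax(e$values, 1e-12)
  e$vectors %*% diag(sqrt(vals), length(vals))
}

#' Generate a synthetic monitor field
#'
#' Simulates strictly positive daily concentration series at each site. The
#' log series are marginally N(`log_mean`, `log_sd`^2), share the
#' running-average temporal autocorrelation of [autocorrelated_noise()]
#' (lag-1 autocorrelation (w-1)/w for window w), and have between-site
#' correlations that decay with distance according to the generating scaled
#' semivariogram `nugget + (1 - nugget)(1 - exp(-3h/spatial_range))`
#' (a pair's sample scaled semivariance at h = 0 therefore equals the
#' nugget).
#'
#' @param config A [world_config()].
#' @return A tibble with columns `date`, `site_id`, `x_km`, `y_km`, `value`
#'   (one row per site-day).
#' @export
#' @examples
#' field <- generate_monitor_field(world_config(n_days = 365, n_sites = 4, seed = 7))
#' dplyr::count(field, site_id)
generate_monitor_field <- function(config) {
  stopifnot(inherits(config, "world_config"))
  L <- corr_factor(world_correlation_matrix(config))
  x <- with_seed(config$seed, {
    innov <- vapply(
      seq_len(config$n_sites),
      function(i) autocorrelated_noise(config$n_days, config$temporal_corr_days),
      numeric(config$n_days)
    )
    innov %*% t(L)
  })
  dates <- study_dates(config$n_days, config$start_date)
  purrr::map_dfr(seq_len(config$n_sites), function(i) {
    tibble::tibble(
      date = dates,
      site_id = sprintf("site_%02d", i),
      x_km = config$site_coords[i, 1],
      y_km = config$site_coords[i, 2],
      value = exp(config$log_mean + config$log_sd * x[, i])
    )
  })
}

#' Extract one site's series from a monitor field
#'
#' Convenience accessor returning the `date`/`value` tibble for a single
#' site, the shape every error-model and health-model function takes as the
#' true base-case series.
#'
#' @param field Monitor-field tibble.
#' @param site_id Site to extract; default the first.
#' @return Tibble with columns `date`, `value`.
#' @export
base_case_series <- function(field, site_id = NULL) {
  site_id <- site_id %||% field$site_id[1]
  out <- field |>
    dplyr::filter(.data$site_id == !!site_id) |>
    dplyr::select("date", "value") |>
    dplyr::arrange(.data$date)
  if (nrow(out) == 0) abort(sprintf("No rows for site '%s'.", site_id))
  out
}

#' Generate a synthetic census-tract table
#'
#' @param n_tracts Number of tracts (the reference study area has 660).
#' @param extent_km Side of the square region over which centroids are
#'   scattered uniformly.
#' @param population_law `"lognormal"` (default; right-skewed tract sizes)
#'   or `"uniform"` (every tract gets `mean_population`).
#' @param mean_population Target mean tract population (default 4000,
#'   a typical census-tract size).
#' @param seed Integer seed.
#' @return A tibble with columns `tract_id`, `x_km`, `y_km`, `population`.
#' @export
generate_tracts <- function(n_tracts, extent_km = 60,
                            population_law = c("lognormal", "uniform"),
                            mean_population = 4000, seed = 1L) {
  if (n_tracts < 1) abort("`n_tracts` must be >= 1.")
  population_law <- match.arg(population_law)
  out <- with_seed(seed, {
    pop <- switch(population_law,
      uniform = rep(round(mean_population), n_tracts),
      lognormal = {
        sdl <- 0.5
        round(rlnorm(n_tracts, meanlog = log(mean_population) - sdl^2 / 2, sdlog = sdl))
      }
    )
    tibble::tibble(
      tract_id = sprintf("tract_%03d", seq_len(n_tracts)),
      x_km = runif(n_tracts, 0, extent_km),
      y_km = runif(n_tracts, 0, extent_km),
      population = as.integer(pop)
    )
  })
  if (sum(out$population) <= 0) abort("Generated zero total population.")
  out
}

#' Generate synthetic confounder series
#'
#' Daily day-of-week and season factors, smooth seasonal maximum
#' temperature and dew point (sinusoid plus noise, southeastern-US scale),
#' and a day index for long-term-trend splines. No missing values.
#'
#' @param n_days Number of days.
#' @param start_date First day.
#' @param seed Integer seed.
#' @return A tibble with columns `date`, `dow`, `season`, `temperature`,
#'   `dew_point`, `day_index`.
#' @export
generate_confounders <- function(n_days, start_date = "1999-01-01", seed = 1L) {
  dates <- study_dates(n_days, start_date)
  doy <- as.integer(format(dates, "%j"))
  month <- as.integer(format(dates, "%m"))
  seasonal <- sin(2 * pi * (doy - 105) / 365.25)
  with_seed(seed, tibble::tibble(
    date = dates,
    dow = factor(weekdays(dates, abbreviate = TRUE),
      levels = weekdays(as.Date("2001-01-01") + 0:6, abbreviate = TRUE)
    ),
    season = factor(
      dplyr::case_when(
        month %in% c(12, 1, 2) ~ "winter",
        month %in% 3:5 ~ "spring",
        month %in% 6:8 ~ "summer",
        TRUE ~ "fall"
      ),
      levels = c("winter", "spring", "summer", "fall")
    ),
    temperature = 22 + 10 * seasonal + rnorm(n_days, sd = 3),
    dew_point = 12 + 9 * seasonal + rnorm(n_days, sd = 3),
    day_index = seq_len(n_days)
  ))
}

#' Configure the synthetic health-outcome model
#'
#' @param alpha Log baseline daily count. The default `log(76)` matches a
#'   six-year study with roughly 166,950 visits over 2,192 days.
#' @param beta_true Log rate ratio per exposure unit; default
#'   `log(1.0139)`, a realistic single-pollutant cardiovascular effect.
#' @param confounder_effects Optional named numeric vector of log-scale
#'   effects; names must match columns of the expanded confounder design
#'   (numeric columns by name, factor levels as in `model.matrix`, e.g.
#'   `"dowSat"`, `"seasonsummer"`, `"temperature"`).
#' @param nb_size Optional negative-binomial size (dispersion switch);
#'   `NULL` (default) generates pure Poisson counts.
#' @param seed Integer seed.
#' @return An object of class `health_config`.
#' @export
health_config <- function(alpha = log(76), beta_true = log(1.0139),
                          confounder_effects = NULL, nb_size = NULL,
                          seed = 1L) {
  if (!is.finite(alpha) || exp(alpha) <= 0 || exp(alpha) >= 1e6) {
    abort("`alpha` must give a baseline count in (0, 1e6).")
  }
  if (!is.finite(beta_true)) abort("`beta_true` must be finite.")
  if (!is.null(nb_size) && nb_size <= 0) abort("`nb_size` must be positive.")
  structure(
    list(
      alpha = alpha, beta_true = beta_true,
      confounder_effects = confounder_effects,
      nb_size = nb_size, seed = as.integer(seed)
    ),
    class = "health_config"
  )
}

#' Generate daily health-outcome counts from a known risk model
#'
#' Draws daily counts from the log-linear model
#' \deqn{\log E(Y_t) = \alpha + \beta Z^*_t + \gamma' \mathrm{conf}_t,}
#' Poisson by default or negative-binomial when `health$nb_size` is set
#' (count variance `mu + mu^2/size`, exercising the overdispersion scaling
#' of the fitting stage).
#'
#' @param truth Tibble with columns `date`, `value`: the true exposure.
#' @param health A [health_config()].
#' @param confounders Optional confounder tibble aligned to `truth$date`
#'   (see [generate_confounders()]); required when
#'   `health$confounder_effects` is set.
#' @return A tibble with columns `date`, `count`.
#' @export
generate_health_counts <- function(truth, health = health_config(),
                                   confounders = NULL) {
  stopifnot(inherits(health, "health_config"))
  eta <- health$alpha + health$beta_true * truth$value
  if (!is.null(health$confounder_effects)) {
    if (is.null(confounders)) abort("`confounders` required for confounder effects.")
    if (!identical(as.Date(confounders$date), as.Date(truth$date))) {
      abort("`confounders` dates are not aligned with `truth` dates.")
    }
    mm <- stats::model.matrix(~., data = dplyr::select(confounders, -"date"))
    eff <- health$confounder_effects
    missing_terms <- setdiff(names(eff), colnames(mm))
    if (length(missing_terms) > 0) {
      abort(paste0(
        "Confounder effects not found in design: ",
        paste(missing_terms, collapse = ", ")
      ))
    }
    eta <- eta + as.numeric(mm[, names(eff), drop = FALSE] %*% eff)
  }
  mu <- exp(eta)
  counts <- with_seed(health$seed, {
    if (is.null(health$nb_size)) {
      rpois(length(mu), mu)
    } else {
      rnbinom(length(mu), mu = mu, size = health$nb_size)
    }
  })
  tibble::tibble(date = truth$date, count = as.integer(counts))
}

#' Write / read the plain-text study-world interchange files
#'
#' CSV round-trip helpers for the three study-world tables: monitor
#' observations (`date,site_id,pollutant,x_km,y_km,value`), tracts
#' (`tract_id,x_km,y_km,population`) and daily counts with confounders.
#' Dates are written ISO-8601.
#'
#' @param field,tracts,counts Tables as produced by the generators.
#' @param path Output file path.
#' @param pollutant Pollutant label stored in the monitor CSV.
#' @return The input, invisibly (writers); a tibble (readers).
#' @name world_io
NULL

#' @rdname world_io
#' @export
write_monitor_csv <- function(field, path, pollutant = "pollutant") {
  field |>
    dplyr::mutate(pollutant = pollutant) |>
    dplyr::select("date", "site_id", "pollutant", "x_km", "y_km", "value") |>
    readr::write_csv(path)
  invisible(field)
}

#' @rdname world_io
#' @export
read_monitor_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE) |>
    dplyr::mutate(date = as.Date(.data$date))
}

#' @rdname world_io
#' @export
write_tract_csv <- function(tracts, path) {
  readr::write_csv(tracts, path)
  invisible(tracts)
}

#' @rdname world_io
#' @export
read_tract_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' @rdname world_io
#' @export
write_counts_csv <- function(counts, path) {
  readr::write_csv(counts, path)
  invisible(counts)
}

#' @rdname world_io
#' @export
read_counts_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE) |>
    dplyr::mutate(date = as.Date(.data$date))
}
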