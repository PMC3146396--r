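# Scaled semivariogram analysis: quantifies combined instrument-imprecision
# and spatial-variability error for a pollutant as a population-weighted
# scaled semivariance, and converts it to a population-weighted correlation.

#' Convert a between-monitor correlation to a scaled semivariance
#'
#' The scaled semivariance \eqn{\gamma'} rescales the spatial semivariance of
#' normalized log concentrations so that 0 means perfectly correlated
#' monitors (R = 1) and 1 means uncorrelated monitors (R = 0). It is related
#' to the Pearson correlation R between the normalized log series by
#' \deqn{\gamma' = (1 - R) / (1 + R).}
#'
#' @param r Pearson correlation(s) in (-1, 1].
#' @return Scaled semivariance value(s), strictly decreasing in `r`.
#' @seealso [correlation_from_semivariance()] for the exact inverse.
#' @export
#' @examples
#' scaled_semivariance_from_r(c(1, 0.903, 0.320))
scaled_semivariance_from_r <- function(r) {
  if (any(is.na(r)) || any(r <= -1) || any(r > 1)) {
    abort("`r` must lie in (-1, 1]: gamma' is undefined at r = -1.")
  }
  (1 - r) / (1 + r)
}

#' Convert a scaled semivariance to a correlation
#'
#' Inverse of [scaled_semivariance_from_r()]:
#' \eqn{R = (1 - \gamma') / (1 + \gamma')}. Applied to the
#' population-weighted scaled semivariance \eqn{\bar\gamma'} it yields the
#' population-weighted correlation \eqn{\bar R}, the quantity that calibrates
#' the amount of error injected by the simulation engine.
#'
#' @param gamma Scaled semivariance value(s), >= 0. Values in \[0, 1\] map to
#'   correlations in \[0, 1\]; empirical pair semivariances slightly above 1
#'   (sampling noise around uncorrelated monitors) map to small negative
#'   correlations.
#' @return Correlation value(s) in (-1, 1\].
#' @export
#' @examples
#' correlation_from_semivariance(c(0, 0.411, 0.337))
correlation_from_semivariance <- function(gamma) {
  if (any(is.na(gamma)) || any(gamma < 0)) {
    abort("`gamma` must be nonnegative.")
  }
  (1 - gamma) / (1 + gamma)
}

#' Exponential scaled-semivariogram model
#'
#' Model family used for fitting and for the synthetic generator:
#' \deqn{\gamma'(h) = nugget + (1 - nugget)\,(1 - e^{-3h/range})}
#' with the sill fixed at 1. The factor 3 makes `range_km` the practical
#' range: \eqn{\gamma'} reaches ~95% of the sill at `h = range_km`.
#'
#' @param h Distances (km), `h >= 0`.
#' @param nugget Nugget in \[0, 1): the collocated-instrument (h = 0) share
#'   of the scaled semivariance.
#' @param range_km Practical range (km), > 0.
#' @return \eqn{\gamma'(h)} values in \[`nugget`, 1).
#' @export
semivariogram_model <- function(h, nugget, range_km) {
  stopifnot(nugget >= 0, nugget < 1, range_km > 0)
  if (any(h < 0)) abort("Distances `h` must be nonnegative.")
  nugget + (1 - nugget) * (1 - exp(-3 * h / range_km))
}

#' Pairwise correlations of normalized log series between monitors
#'
#' Computes, for every unordered pair of monitoring sites, the Pearson
#' correlation of the normalized log concentration series over the days both
#' sites report, together with the between-site distance and the implied
#' scaled semivariance. Pairs with fewer overlapping days than `min_overlap`
#' are dropped with a warning; correlations on short overlaps are too noisy
#' to constrain the semivariogram.
#'
#' @param field A monitor-field tibble with columns `date`, `site_id`,
#'   `x_km`, `y_km`, `value` (one row per site-day), as produced by
#'   [generate_monitor_field()] or read from a monitor CSV.
#' @param min_overlap Minimum number of common non-missing days per pair
#'   (default 365, one year of daily data).
#' @return A tibble with columns `site_a`, `site_b`, `distance_km`,
#'   `n_overlap`, `r`, `gamma` sorted by distance.
#' @export
pairwise_log_correlations <- function(field, min_overlap = 365) {
  req <- c("date", "site_id", "x_km", "y_km", "value")
  if (!all(req %in% names(field))) {
    abort(paste0("`field` must have columns ", paste(req, collapse = ", "), "."))
  }
  sites <- dplyr::distinct(field, .data$site_id, .data$x_km, .data$y_km)
  if (nrow(sites) < 2) abort("Need at least 2 sites to form pairs.")
  check_positive_series(field$value[!is.na(field$value)], "field$value")

  wide <- field |>
    dplyr::mutate(log_value = log(.data$value)) |>
    dplyr::select("date", "site_id", "log_value") |>
    tidyr::pivot_wider(names_from = "site_id", values_from = "log_value") |>
    dplyr::arrange(.data$date)
  dmat <- pair_distances(as.matrix(sites[, c("x_km", "y_km")]))

  combos <- utils::combn(seq_len(nrow(sites)), 2)
  res <- purrr::map_dfr(seq_len(ncol(combos)), function(k) {
    i <- combos[1, k]; j <- combos[2, k]
    a <- as.character(sites$site_id[i]); b <- as.character(sites$site_id[j])
    xa <- wide[[a]]; xb <- wide[[b]]
    ok <- !is.na(xa) & !is.na(xb)
    tibble::tibble(
      site_a = a, site_b = b,
      distance_km = dmat[i, j],
      n_overlap = sum(ok),
      r = if (sum(ok) >= 2) cor(scale(xa[ok]), scale(xb[ok]))[1, 1] else NA_real_
    )
  })
  dropped <- res$n_overlap < min_overlap | is.na(res$r)
  if (any(dropped)) {
    warn(sprintf(
      "%d of %d monitor pairs dropped (overlap < %d days).",
      sum(dropped), nrow(res), min_overlap
    ))
  }
  res <- res[!dropped, , drop = FALSE]
  if (nrow(res) == 0) abort("All monitor pairs dropped: insufficient overlap.")
  res |>
    dplyr::mutate(gamma = scaled_semivariance_from_r(pmin(.data$r, 1))) |>
    dplyr::arrange(.data$distance_km)
}

#' Fit a scaled semivariogram with fixed sill and nugget
#'
#' Fits the exponential model [semivariogram_model()] to empirical pair
#' semivariances by least squares over the practical range, with the sill
#' fixed at exactly 1 and the nugget supplied externally (in the field it
#' comes from collocated-instrument time-series; for synthetic data it is
#' the generator's truth).
#'
#' @param pairs Tibble of pair records from [pairwise_log_correlations()]
#'   (needs `distance_km` and `gamma`).
#' @param nugget Known nugget in \[0, 1).
#' @param range_interval Search interval for the range (km); defaults to
#'   (1e-3, 10 x max pair distance).
#' @return An object of class `semivariogram_fit`: a list with `nugget`,
#'   `sill` (always 1), `range_km`, `rss`, `n_pairs` and the `pairs` used.
#'   Supports [tidy()], [glance()], `predict()` and [autoplot()].
#' @export
fit_semivariogram <- function(pairs, nugget, range_interval = NULL) {
  stopifnot(nugget >= 0, nugget < 1)
  pos <- pairs[pairs$distance_km > 0, , drop = FALSE]
  if (nrow(pos) == 0) abort("No positive-distance pairs: cannot fit a range.")
  if (length(unique(signif(pos$distance_km, 10))) < 2) {
    abort("All pairs lie at a single distance: the range is unidentifiable (ill-posed fit).")
  }
  range_interval <- range_interval %||% c(1e-3, 10 * max(pos$distance_km))
  rss_fn <- function(rng) {
    sum((semivariogram_model(pos$distance_km, nugget, rng) - pos$gamma)^2)
  }
  opt <- optimize(rss_fn, interval = range_interval, tol = 1e-10)
  if (!is.finite(opt$objective)) {
    abort("Semivariogram range optimization failed to converge.")
  }
  structure(
    list(
      nugget = nugget, sill = 1, range_km = opt$minimum,
      rss = opt$objective, n_pairs = nrow(pos), pairs = pairs
    ),
    class = "semivariogram_fit"
  )
}

#' @export
print.semivariogram_fit <- function(x, ...) {
  cat("Scaled semivariogram fit (exponential, sill = 1)\n")
  cat(sprintf(
    "  nugget %.3f | range %.1f km | RSS %.4g | %d pairs\n",
    x$nugget, x$range_km, x$rss, x$n_pairs
  ))
  invisible(x)
}

#' @export
predict.semivariogram_fit <- function(object, h, ...) {
  semivariogram_model(h, object$nugget, object$range_km)
}

#' @exportS3Method generics::tidy
tidy.semivariogram_fit <- function(x, ...) {
  tibble::tibble(
    term = c("nugget", "sill", "range_km"),
    estimate = c(x$nugget, x$sill, x$range_km),
    fixed = c(TRUE, TRUE, FALSE)
  )
}

#' @exportS3Method generics::glance
glance.semivariogram_fit <- function(x, ...) {
  tibble::tibble(
    nugget = x$nugget, range_km = x$range_km,
    rss = x$rss, n_pairs = x$n_pairs
  )
}

#' Population-weighted scaled semivariance over a tract table
#'
#' Evaluates a fitted (or known) scaled semivariogram at the distances
#' between census-tract centroids and averages with population weights to
#' give the single-number error budget \eqn{\bar\gamma'} for a pollutant:
#' \deqn{\bar\gamma' = \sum_{i \le j} p_{i,j}\,\gamma'(h_{ij}) /
#'   \sum_{i \le j} p_{i,j}}
#' over all unordered tract pairs including i = j, with
#' \eqn{p_{i,j} = p_i + p_j} the summed population of the two tracts. For
#' within-tract (i = j) pairs an average between-residence distance
#' `within_tract_km` replaces the zero centroid distance.
#'
#' @param fit A `semivariogram_fit` or any function of distance returning
#'   \eqn{\gamma'(h)}.
#' @param tracts Tract tibble with columns `tract_id`, `x_km`, `y_km`,
#'   `population` (see [generate_tracts()]).
#' @param within_tract_km Average distance (km) between residences in the
#'   same tract, used for i = j pairs; default 1.
#' @return A one-row tibble: `gamma_bar`, `r_bar` (via
#'   [correlation_from_semivariance()]), `within_tract_km`, `n_tracts`.
#' @export
population_weighted_semivariance <- function(fit, tracts, within_tract_km = 1) {
  if (nrow(tracts) == 0) abort("`tracts` is empty.")
  if (any(tracts$population < 0) || sum(tracts$population) <= 0) {
    abort("Tract populations must be nonnegative with a positive total.")
  }
  gamma_fun <- if (inherits(fit, "semivariogram_fit")) {
    function(h) predict(fit, h)
  } else if (is.function(fit)) {
    fit
  } else {
    abort("`fit` must be a semivariogram_fit or a function of distance.")
  }
  h <- pair_distances(as.matrix(tracts[, c("x_km", "y_km")]))
  diag(h) <- within_tract_km
  g <- matrix(gamma_fun(h), nrow(tracts), nrow(tracts))
  p <- tracts$population
  w <- outer(p, p, "+")
  keep <- upper.tri(w, diag = TRUE)
  gamma_bar <- sum(w[keep] * g[keep]) / sum(w[keep])
  tibble::tibble(
    gamma_bar = gamma_bar,
    r_bar = correlation_from_semivariance(gamma_bar),
    within_tract_km = within_tract_km,
    n_tracts = nrow(tracts)
  )
}

#' Closed-form error budget from a population-weighted semivariance
#'
#' Expands \eqn{\bar\gamma'} into the full set of Monte Carlo error
#' parameters: the population-weighted correlation \eqn{\bar R}, the
#' log-scale error SD \eqn{\sigma_{err} = \sqrt{1/\bar R - 1}} (so that the
#' simulated-vs-true log correlation equals \eqn{\sqrt{\bar R}}), and the
#' simulated-to-true log-SD ratios at the Berkson-like and classical-like
#' endpoints, \eqn{(1+\sigma_{err}^2)^{\mp 1/2}}.
#'
#' @param gamma_bar Population-weighted scaled semivariance(s) in \[0, 1).
#' @param pollutant Optional label(s) carried through.
#' @return A tibble with columns `pollutant` (if given), `gamma_bar`,
#'   `r_bar`, `sigma_err`, `s_ratio_b`, `s_ratio_c`.
#' @export
#' @examples
#' error_budget_from_semivariance(published_error_budgets()$gamma_bar,
#'   pollutant = published_error_budgets()$pollutant
#' )
error_budget_from_semivariance <- function(gamma_bar, pollutant = NULL) {
  r_bar <- correlation_from_semivariance(gamma_bar)
  sigma_err <- sigma_err_from_r(r_bar)
  out <- tibble::tibble(
    gamma_bar = gamma_bar,
    r_bar = r_bar,
    sigma_err = sigma_err,
    s_ratio_b = sd_ratio(sigma_err, "B"),
    s_ratio_c = sd_ratio(sigma_err, "C")
  )
  if (!is.null(pollutant)) out <- dplyr::bind_cols(tibble::tibble(pollutant = pollutant), out)
  out
}
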