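# Monte Carlo injection of multiplicative (log-additive) measurement error
# of classical-like (type C), Berkson-like (type B) or intermediate type
# into a strictly positive daily exposure series.

#' Standardize a positive series on the log scale
#'
#' Computes \eqn{\chi^*_t = (\ln Z^*_t - \mu_{\ln Z^*}) / \sigma_{\ln Z^*}}
#' using the population (1/n) SD convention, so the output has mean exactly
#' 0 and SD exactly 1.
#'
#' @param series Tibble with columns `date` and `value` (strictly positive).
#' @return Tibble with columns `date`, `chi`; attributes `log_mean` and
#'   `log_sd` carry the moments needed by [denormalize_series()].
#' @export
normalize_series <- function(series) {
  check_positive_series(series$value, "series$value")
  lz <- log(series$value)
  mu <- mean(lz)
  sdv <- pop_sd(lz)
  if (sdv == 0) abort("Degenerate series: zero log-scale variance.")
  out <- tibble::tibble(date = series$date, chi = (lz - mu) / sdv)
  attr(out, "log_mean") <- mu
  attr(out, "log_sd") <- sdv
  out
}

#' Back-transform a standardized log series to concentrations
#'
#' Inverse of [normalize_series()]:
#' \eqn{Z_t = \exp(\mu_{\ln Z^*} + \sigma_{\ln Z^*} \chi_t)}.
#'
#' @param chi Tibble with columns `date`, `chi` (or a numeric vector).
#' @param log_mean,log_sd Log-scale moments of the true series; taken from
#'   the attributes of `chi` when omitted.
#' @return Tibble with columns `date`, `value`.
#' @export
denormalize_series <- function(chi, log_mean = NULL, log_sd = NULL) {
  log_mean <- log_mean %||% attr(chi, "log_mean")
  log_sd <- log_sd %||% attr(chi, "log_sd")
  if (is.null(log_mean) || is.null(log_sd)) {
    abort("`log_mean` and `log_sd` are required (or must be attributes of `chi`).")
  }
  if (is.data.frame(chi)) {
    tibble::tibble(date = chi$date, value = exp(log_mean + log_sd * chi$chi))
  } else {
    exp(log_mean + log_sd * chi)
  }
}

#' Temporally autocorrelated unit-variance noise
#'
#' A `window`-day running mean of iid standard normals, rescaled by
#' \eqn{\sqrt{window}} so the marginal variance is 1. The short-term
#' autocorrelation is that of a moving-average process: lag-k
#' autocorrelation (window - k)/window for k < window, 0 beyond. The
#' default 3-day window reproduces the short-term temporal autocorrelation
#' observed in between-monitor differences.
#'
#' @param n_days Length of the noise series.
#' @param window Running-average window in days (default 3).
#' @param seed Optional integer seed; when supplied the draw is reproducible
#'   and the caller's RNG stream is left untouched.
#' @return Numeric vector of length `n_days`, marginally N(0, 1).
#' @export
autocorrelated_noise <- function(n_days, window = 3, seed = NULL) {
  window <- as.integer(window)
  if (window < 1) abort("`window` must be >= 1.")
  if (window > n_days) abort("`window` cannot exceed `n_days`.")
  draw <- function() {
    z <- rnorm(n_days + window - 1L)
    # running mean of `window` values, scaled back to unit variance
    as.numeric(stats::filter(z, rep(1 / sqrt(window), window), sides = 1))[window:(n_days + window - 1L)]
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Log-scale error SD implied by a population-weighted correlation
#'
#' Calibrates the amount of injected error: \eqn{\sigma_{err} =
#' \sqrt{1/\bar R - 1}}, so that the correlation between the log of an
#' error-laden series and the log of the true series is \eqn{\sqrt{\bar R}}
#' (two independently error-laden series then correlate at \eqn{\bar R}).
#'
#' @param r_bar Population-weighted correlation(s) in (0, 1].
#' @return \eqn{\sigma_{err}} value(s).
#' @export
#' @examples
#' sigma_err_from_r(c(0.418, 0.819, 1))
sigma_err_from_r <- function(r_bar) {
  if (any(is.na(r_bar)) || any(r_bar <= 0) || any(r_bar > 1)) {
    abort("`r_bar` must lie in (0, 1].")
  }
  sqrt(1 / r_bar - 1)
}

#' Simulated-to-true log-SD ratio for an error type
#'
#' The ratio \eqn{\sigma_{\ln Z}/\sigma_{\ln Z^*}} indexes error type along
#' the Berkson-to-classical continuum: classical-like (type C) error
#' scatters measurements about the truth and inflates the log SD to
#' \eqn{\sqrt{1+\sigma_{err}^2}}; Berkson-like (type B) error scatters truth
#' about the measurement and deflates it to \eqn{1/\sqrt{1+\sigma_{err}^2}}.
#'
#' @param sigma_err Log-scale error SD(s), >= 0.
#' @param type `"C"` (classical-like) or `"B"` (Berkson-like).
#' @return The SD ratio(s).
#' @export
#' @examples
#' sd_ratio(1.46, "C") # 1.77
#' sd_ratio(1.46, "B") # 0.57
sd_ratio <- function(sigma_err, type = c("C", "B")) {
  if (any(is.na(sigma_err)) || any(sigma_err < 0)) abort("`sigma_err` must be >= 0.")
  type <- match.arg(type)
  switch(type,
    C = sqrt(1 + sigma_err^2),
    B = 1 / sqrt(1 + sigma_err^2)
  )
}

#' Specify an error-injection scenario
#'
#' Bundles the error amount, error type, Monte Carlo size and seeding for
#' one simulation scenario. The amount can be given as any one of
#' `gamma_bar` (population-weighted scaled semivariance), `r_bar`
#' (population-weighted correlation) or `sigma_err` directly; the others are
#' derived. The type can be the endpoint labels `"C"`/`"B"` or an explicit
#' `s_ratio` anywhere in the admissible interval
#' \eqn{[(1+\sigma_{err}^2)^{-1/2},\ (1+\sigma_{err}^2)^{1/2}]} for
#' intermediate types.
#'
#' @param gamma_bar,r_bar,sigma_err Exactly one of these fixes the amount.
#' @param type `"C"`, `"B"`, or `"intermediate"` (requires `s_ratio`).
#' @param s_ratio Target \eqn{\sigma_{\ln Z}/\sigma_{\ln Z^*}}; implied by
#'   `type` for the endpoints.
#' @param n_sims Number of Monte Carlo draws (default 1000).
#' @param window Running-average window of the error process (default 3).
#' @param seed Scenario seed; per-draw seeds are derived from it.
#' @return An object of class `error_spec`.
#' @export
#' @examples
#' error_spec(gamma_bar = 0.411, type = "C", n_sims = 1000, seed = 1)
error_spec <- function(gamma_bar = NULL, r_bar = NULL, sigma_err = NULL,
                       type = c("C", "B", "intermediate"), s_ratio = NULL,
                       n_sims = 1000, window = 3, seed = 1L) {
  type <- match.arg(type)
  given <- !c(is.null(gamma_bar), is.null(r_bar), is.null(sigma_err))
  if (sum(given) != 1) {
    abort("Give exactly one of `gamma_bar`, `r_bar`, `sigma_err`.")
  }
  if (!is.null(gamma_bar)) r_bar <- correlation_from_semivariance(gamma_bar)
  if (!is.null(r_bar)) sigma_err <- sigma_err_from_r(r_bar)
  lo <- sd_ratio(sigma_err, "B")
  hi <- sd_ratio(sigma_err, "C")
  if (type == "intermediate") {
    if (is.null(s_ratio)) abort("`type = \"intermediate\"` requires `s_ratio`.")
    if (s_ratio < lo - 1e-12 || s_ratio > hi + 1e-12) {
      abort(sprintf(
        "`s_ratio` = %.4f outside the admissible interval [%.4f, %.4f].",
        s_ratio, lo, hi
      ))
    }
  } else {
    if (!is.null(s_ratio)) abort("`s_ratio` is only used with `type = \"intermediate\"`.")
    s_ratio <- if (type == "C") hi else lo
  }
  structure(
    list(
      sigma_err = sigma_err,
      r_bar = 1 / (1 + sigma_err^2),
      gamma_bar = scaled_semivariance_from_r(1 / (1 + sigma_err^2)),
      s_ratio = s_ratio, type = type,
      n_sims = as.integer(n_sims), window = as.integer(window),
      seed = as.integer(seed)
    ),
    class = "error_spec"
  )
}

#' @export
print.error_spec <- function(x, ...) {
  cat(sprintf(
    "Error scenario: type %s | sigma_err %.3f (gamma_bar %.3f) | s_ratio %.3f | %d sims | window %d | seed %d\n",
    x$type, x$sigma_err, x$gamma_bar, x$s_ratio, x$n_sims, x$window, x$seed
  ))
  invisible(x)
}

#' Simulate one error-laden exposure series
#'
#' Draws one realisation of an error-laden series from a true base-case
#' series. On the standardized log scale the measurement is
#' \deqn{\chi_t = s \,(\chi^*_t + \varepsilon_t)/\sqrt{1+\sigma_{err}^2},
#'   \qquad \varepsilon_t = \sigma_{err} N_t,}
#' with \eqn{N_t} the unit-variance autocorrelated noise of
#' [autocorrelated_noise()] and \eqn{s} the target SD ratio. At
#' \eqn{s = \sqrt{1+\sigma_{err}^2}} this reduces to the classical-like
#' endpoint \eqn{\chi = \chi^* + \varepsilon} (error independent of truth);
#' at \eqn{s = 1/\sqrt{1+\sigma_{err}^2}} to the Berkson-like endpoint
#' \eqn{\chi = (\chi^* + \varepsilon)/(1+\sigma_{err}^2)} (error independent
#' of the measurement). For every `s`, the population correlation of
#' \eqn{\ln Z} with \eqn{\ln Z^*} is \eqn{(1+\sigma_{err}^2)^{-1/2}}, and
#' the log means of the simulated and true series agree exactly.
#'
#' @param base Tibble with columns `date`, `value`: the true series.
#' @param spec An [error_spec()].
#' @param draw_seed Seed for this draw's noise.
#' @return Tibble with columns `date`, `true`, `value`; attributes
#'   `achieved_r_log` (sample log-scale correlation with the base),
#'   `achieved_s_ratio` (sample log-SD ratio) and `iqr`.
#' @export
simulate_error_series <- function(base, spec, draw_seed = spec$seed) {
  stopifnot(inherits(spec, "error_spec"))
  chi_star <- normalize_series(base)
  n <- nrow(chi_star)
  eps <- spec$sigma_err * autocorrelated_noise(n, spec$window, seed = draw_seed)
  # centre the realised noise so the simulated log-mean equals the base
  # log-mean exactly, not just in expectation
  eps <- eps - mean(eps)
  chi <- spec$s_ratio * (chi_star$chi + eps) / sqrt(1 + spec$sigma_err^2)
  sim <- denormalize_series(
    tibble::tibble(date = chi_star$date, chi = chi),
    attr(chi_star, "log_mean"), attr(chi_star, "log_sd")
  )
  out <- tibble::tibble(date = base$date, true = base$value, value = sim$value)
  attr(out, "achieved_r_log") <-
    if (spec$sigma_err == 0) 1 else cor(log(out$value), log(out$true))
  attr(out, "achieved_s_ratio") <- pop_sd(log(out$value)) / pop_sd(log(out$true))
  attr(out, "iqr") <- IQR(out$value)
  out
}

#' Simulate a Monte Carlo set of error-laden series
#'
#' Runs [simulate_error_series()] `spec$n_sims` times with per-draw seeds
#' derived deterministically from the scenario seed, and returns per-draw
#' achieved-error summaries (log-scale correlation with the base, log-SD
#' ratio, IQR), optionally keeping every simulated series.
#'
#' @inheritParams simulate_error_series
#' @param keep_series Keep each simulated series as a list-column
#'   (default `TRUE`; set `FALSE` to save memory for summary-only use).
#' @return A tibble of class `error_sim_set` with one row per draw: `draw`,
#'   `draw_seed`, `r_log`, `s_ratio`, `iqr` and (optionally) `series`.
#'   Attribute `spec` carries the scenario.
#' @export
simulate_error_set <- function(base, spec, keep_series = TRUE) {
  stopifnot(inherits(spec, "error_spec"), spec$n_sims >= 1)
  seeds <- derive_seeds(spec$seed, spec$n_sims)
  rows <- purrr::map(seq_len(spec$n_sims), function(i) {
    sim <- simulate_error_series(base, spec, draw_seed = seeds[i])
    list(
      draw = i, draw_seed = seeds[i],
      r_log = attr(sim, "achieved_r_log"),
      s_ratio = attr(sim, "achieved_s_ratio"),
      iqr = attr(sim, "iqr"),
      series = if (keep_series) sim else NULL
    )
  })
  out <- tibble::tibble(
    draw = purrr::map_int(rows, "draw"),
    draw_seed = purrr::map_dbl(rows, "draw_seed"),
    r_log = purrr::map_dbl(rows, "r_log"),
    s_ratio = purrr::map_dbl(rows, "s_ratio"),
    iqr = purrr::map_dbl(rows, "iqr")
  )
  if (keep_series) out$series <- purrr::map(rows, "series")
  attr(out, "spec") <- spec
  class(out) <- c("error_sim_set", class(out))
  out
}

#' @exportS3Method generics::glance
glance.error_sim_set <- function(x, ...) {
  spec <- attr(x, "spec")
  tibble::tibble(
    type = spec$type, sigma_err = spec$sigma_err, target_s_ratio = spec$s_ratio,
    target_r_log = 1 / sqrt(1 + spec$sigma_err^2),
    n_sims = nrow(x),
    mean_r_log = mean(x$r_log), sd_r_log = sd(x$r_log),
    mean_s_ratio = mean(x$s_ratio), sd_s_ratio = sd(x$s_ratio),
    mean_iqr = mean(x$iqr), sd_iqr = sd(x$iqr)
  )
}
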