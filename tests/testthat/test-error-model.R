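test_that("log-scale normalization uses the population SD convention and round-trips", {
  s <- tibble::tibble(date = study_dates(3), value = exp(c(-1, 0, 1)))
  chi <- normalize_series(s)
  expect_equal(chi$chi, c(-sqrt(3 / 2), 0, sqrt(3 / 2)))
  expect_equal(mean(chi$chi), 0)
  expect_equal(sqrt(mean(chi$chi^2)), 1)
  back <- denormalize_series(chi)
  expect_equal(back$value, s$value, tolerance = 1e-14)

  expect_error(normalize_series(tibble::tibble(date = study_dates(3), value = rep(2, 3))), "Degenerate")
  expect_error(normalize_series(tibble::tibble(date = study_dates(2), value = c(1, -1))), "positive")
})

test_that("running-average noise has unit variance and moving-average autocorrelation", {
  n <- 1e5
  x1 <- autocorrelated_noise(n, window = 1, seed = 11)
  expect_equal(var(x1), 1, tolerance = 0.02)
  expect_lt(abs(lag_cor(x1, 1)), 0.02)

  x3 <- autocorrelated_noise(n, window = 3, seed = 12)
  expect_equal(var(x3), 1, tolerance = 0.02)
  expect_equal(lag_cor(x3, 1), 2 / 3, tolerance = 0.02)
  expect_equal(lag_cor(x3, 2), 1 / 3, tolerance = 0.02)
  expect_lt(abs(lag_cor(x3, 3)), 0.02)

  expect_error(autocorrelated_noise(5, window = 6), "exceed")
  expect_identical(
    autocorrelated_noise(100, 3, seed = 5),
    autocorrelated_noise(100, 3, seed = 5)
  )
})

test_that("error-amount and SD-ratio formulas reproduce the reference calibration", {
  expect_equal(round(sigma_err_from_r(0.418), 2), 1.18)
  expect_equal(round(sigma_err_from_r(0.819), 2), 0.47)
  expect_equal(sigma_err_from_r(1), 0)
  expect_error(sigma_err_from_r(0), "0, 1")

  expect_equal(round(sd_ratio(1.46, "C"), 2), 1.77)
  expect_equal(round(sd_ratio(1.46, "B"), 2), 0.57)
  expect_equal(round(sd_ratio(0.33, "B"), 2), 0.95)
  expect_equal(sd_ratio(0, "C"), 1)
  expect_equal(sd_ratio(0, "B"), 1)
  expect_error(sd_ratio(1, "Q"))
})

test_that("error specs validate the admissible SD-ratio interval", {
  spec <- error_spec(gamma_bar = 0.411, type = "C", seed = 1)
  expect_equal(spec$sigma_err, sigma_err_from_r(correlation_from_semivariance(0.411)))
  expect_equal(spec$s_ratio, sd_ratio(spec$sigma_err, "C"))
  expect_equal(spec$gamma_bar, 0.411, tolerance = 1e-12)

  mid <- error_spec(sigma_err = 1, type = "intermediate", s_ratio = 1, seed = 1)
  expect_equal(mid$s_ratio, 1)
  expect_error(
    error_spec(sigma_err = 1, type = "intermediate", s_ratio = 2, seed = 1),
    "admissible"
  )
  expect_error(error_spec(gamma_bar = 0.4, r_bar = 0.4, type = "C"), "exactly one")
})

test_that("a single simulated draw honours the exact contracts of the injection formula", {
  base <- make_base(n_days = 2192, seed = 7)
  # no error: the identity
  s0 <- simulate_error_series(base, error_spec(sigma_err = 0, type = "C", seed = 3))
  expect_equal(s0$value, base$value, tolerance = 1e-12)

  for (ty in c("C", "B")) {
    spec <- error_spec(gamma_bar = 0.411, type = ty, seed = 5)
    sim <- simulate_error_series(base, spec, draw_seed = 99)
    # exact log-mean preservation (population convention)
    expect_equal(mean(log(sim$value)), mean(log(base$value)), tolerance = 1e-10)
    expect_true(all(sim$value > 0))
    expect_equal(nrow(sim), nrow(base))
  }

  # type C reduces to chi* + eps: achieved SD ratio ~ sqrt(1 + sigma^2) on average
  spec_c <- error_spec(gamma_bar = 0.411, type = "C", n_sims = 200, seed = 8)
  set_c <- simulate_error_set(base, spec_c, keep_series = FALSE)
  expect_equal(mean(set_c$s_ratio), spec_c$s_ratio, tolerance = 0.02)
  expect_equal(mean(set_c$r_log), 1 / sqrt(1 + spec_c$sigma_err^2), tolerance = 0.01)
})

test_that("type C error is independent of the truth and type B of the measurement", {
  base <- make_base(n_days = 2192, seed = 9)
  n_draws <- 150
  for (ty in c("C", "B")) {
    spec <- error_spec(gamma_bar = 0.411, type = ty, n_sims = n_draws, seed = 21)
    sims <- simulate_error_set(base, spec)
    rs <- purrr::map_dbl(sims$series, function(s) {
      err <- log(s$value) - log(s$true)
      if (ty == "C") cor(err, log(s$true)) else cor(err, log(s$value))
    })
    # mean correlation of the error with its defining partner is ~0
    expect_lt(abs(mean(rs)), 3 * sd(rs) / sqrt(n_draws) + 0.005)
    # ... and with the *other* partner decidedly not 0
    rs_other <- purrr::map_dbl(sims$series, function(s) {
      err <- log(s$value) - log(s$true)
      if (ty == "C") cor(err, log(s$value)) else cor(err, log(s$true))
    })
    expect_gt(abs(mean(rs_other)), 0.2)
  }
})

test_that("simulation sets are deterministic, ordered by type, and match the calibrated correlation", {
  base <- make_base(n_days = 2192, seed = 13)
  spec <- error_spec(gamma_bar = 0.411, type = "C", n_sims = 50, seed = 17)
  a <- simulate_error_set(base, spec, keep_series = FALSE)
  b <- simulate_error_set(base, spec, keep_series = FALSE)
  expect_identical(as.data.frame(a), as.data.frame(b))

  spec_b <- error_spec(gamma_bar = 0.411, type = "B", n_sims = 50, seed = 17)
  set_b <- simulate_error_set(base, spec_b, keep_series = FALSE)
  base_iqr <- IQR(base$value)
  # classical-like error widens the IQR, Berkson-like narrows it
  expect_gt(mean(a$iqr), base_iqr)
  expect_lt(mean(set_b$iqr), base_iqr)
  # log-SD ordering: type C inflates, type B deflates
  expect_gt(mean(a$s_ratio), 1)
  expect_lt(mean(set_b$s_ratio), 1)

  # wider correlation spread for a larger error amount
  spread_small <- sd(simulate_error_set(
    base, error_spec(gamma_bar = 0.051, type = "C", n_sims = 50, seed = 19),
    keep_series = FALSE
  )$r_log)
  spread_large <- sd(simulate_error_set(
    base, error_spec(gamma_bar = 0.516, type = "C", n_sims = 50, seed = 19),
    keep_series = FALSE
  )$r_log)
  expect_gt(spread_large, spread_small)
})

test_that("at window 1 the injected pair matches a direct bivariate-normal construction", {
  # long iid lognormal base so sample moments are tight
  n <- 1e5
  set.seed(31)
  base <- tibble::tibble(date = seq_len(n), value = exp(0.18 + 0.6 * rnorm(n)))
  sigma <- 1.18
  for (s_target in c(sd_ratio(sigma, "B"), 1, sd_ratio(sigma, "C"))) {
    spec <- error_spec(
      sigma_err = sigma, type = "intermediate", s_ratio = s_target,
      window = 1, seed = 37
    )
    sim <- simulate_error_series(base, spec, draw_seed = 41)
    lz <- log(sim$value); lzs <- log(sim$true)
    rho <- 1 / sqrt(1 + sigma^2)
    # oracle: (ln Z*, ln Z) jointly normal with correlation rho and SD ratio s
    expect_equal(cor(lz, lzs), rho, tolerance = 0.01)
    expect_equal(sd(lz) / sd(lzs), s_target, tolerance = 0.01)
    expect_equal(mean(lz), mean(lzs), tolerance = 1e-10)
  }
})
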