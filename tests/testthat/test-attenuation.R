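test_that("percent attenuation reproduces the reference worked examples", {
  expect_equal(round(percent_attenuation(1.0139, 1.0011)), 92)
  expect_equal(round(percent_attenuation(1.0139, 1.0182)), -31)
  expect_equal(round(percent_attenuation(1.0139, 1.0020)), 86)
  expect_equal(round(percent_attenuation(1.0139, 1.0092)), 34)
  expect_equal(percent_attenuation(1.5, 1.5), 0)
  expect_equal(percent_attenuation(1.5, 1), 100)
  expect_error(percent_attenuation(1, 1.2), "undefined")
})

test_that("the error-regression slope agrees with an OLS oracle and its algebraic identity", {
  set.seed(5)
  n <- 5000
  zs <- exp(rnorm(n, 0.2, 0.5))

  # no error: zero slope, zero predictions
  same <- tibble::tibble(true = zs, value = zs)
  expect_equal(error_regression_slope(same), 0)
  pred0 <- predicted_attenuation(same)
  expect_equal(pred0$predicted_percent_unit, 0)
  expect_equal(pred0$predicted_percent_iqr, 0)

  # additive classical error on the raw scale: m ~ Var(e)/Var(Z)
  e <- rnorm(n, sd = 0.8)
  z <- zs + e
  sim <- tibble::tibble(true = zs, value = z)
  m <- error_regression_slope(sim)
  expect_equal(m, unname(coef(lm(I(z - zs) ~ z))[2]), tolerance = 1e-10)
  expect_equal(m, var(e) / var(z), tolerance = 0.05)

  # raw-scale Berkson construction: truth scatters about the measurement, m ~ 0
  z2 <- exp(rnorm(n, 0.2, 0.5))
  zs2 <- z2 + rnorm(n, sd = 0.5)
  m_berk <- error_regression_slope(tibble::tibble(true = zs2, value = z2))
  expect_lt(abs(m_berk), 0.03)
  expect_lt(abs(predicted_attenuation(tibble::tibble(true = zs2, value = z2))$predicted_percent_unit), 3)

  expect_error(error_regression_slope(tibble::tibble(true = zs, value = rep(1, n))), "Zero variance")
})

test_that("1 - m equals Cov(Z*, Z)/Var(Z) to machine precision on simulated draws", {
  base <- make_base(n_days = 500, seed = 23)
  for (ty in c("C", "B")) {
    spec <- error_spec(gamma_bar = 0.3, type = ty, n_sims = 5, seed = 29)
    sims <- simulate_error_set(base, spec)
    for (s in sims$series) {
      m <- error_regression_slope(s)
      expect_equal(1 - m, cov(s$true, s$value) / var(s$value), tolerance = 1e-12)
    }
  }
})

test_that("scenario runs attenuate classical-like error and inflate Berkson-like per-unit estimates", {
  base <- make_base(n_days = 2192, seed = 31)
  counts <- make_health_data(base, seed = 32)
  res_c <- run_error_scenario(
    base, counts, error_spec(gamma_bar = 0.411, type = "C", n_sims = 30, seed = 33)
  )
  res_b <- run_error_scenario(
    base, counts, error_spec(gamma_bar = 0.411, type = "B", n_sims = 30, seed = 33)
  )
  expect_gt(res_c$summary$mean_att_unit, 30)
  expect_gt(res_c$summary$mean_att_iqr, 20)
  expect_lt(res_b$summary$mean_att_unit, res_c$summary$mean_att_unit)
  expect_gt(res_b$summary$mean_att_iqr, 0)
  # Berkson-like draws scatter more widely than classical-like at equal amount
  expect_gt(res_b$summary$sd_att_unit, res_c$summary$sd_att_unit)
  # significance is reduced relative to the error-free fit for both types
  expect_gt(res_c$summary$p_value, res_c$base_fit$p)
  expect_gt(res_b$summary$p_value, res_b$base_fit$p)
})

test_that("the continuum sweep endpoints reproduce plain type B and type C scenarios", {
  base <- make_base(n_days = 400, seed = 41)
  counts <- make_health_data(base, seed = 42)
  sweep <- continuum_sweep(base, counts,
    sigma_err = 1.18, n_steps = 3,
    n_sims = 5, seed = 43
  )
  expect_equal(nrow(sweep), 3)
  plain_b <- run_error_scenario(
    base, counts, error_spec(sigma_err = 1.18, type = "B", n_sims = 5, seed = 43)
  )
  plain_c <- run_error_scenario(
    base, counts, error_spec(sigma_err = 1.18, type = "C", n_sims = 5, seed = 43)
  )
  expect_equal(
    as.data.frame(sweep[1, names(plain_b$summary)]),
    as.data.frame(plain_b$summary)
  )
  expect_equal(
    as.data.frame(sweep[3, names(plain_c$summary)]),
    as.data.frame(plain_c$summary)
  )
  # the middle step targets an intermediate SD ratio inside (B, C)
  expect_gt(sweep$target_s_ratio[2], sweep$target_s_ratio[1])
  expect_lt(sweep$target_s_ratio[2], sweep$target_s_ratio[3])
})

test_that("zero-crossing interpolation brackets a sign change", {
  fake <- tibble::tibble(
    target_s_ratio = c(0.6, 1.0, 1.6),
    pred_unit = c(-10, -2, 14)
  )
  x <- sweep_zero_crossing(fake)
  expect_gt(x, 1.0)
  expect_lt(x, 1.6)
  expect_equal(x, 1.0 + 2 / 16 * 0.6)
  expect_true(is.na(sweep_zero_crossing(tibble::tibble(
    target_s_ratio = c(1, 2), pred_unit = c(1, 2)
  ))))
})

test_that("predicted-vs-observed comparison reports zero deviation for duplicated scenarios", {
  base <- make_base(n_days = 400, seed = 51)
  counts <- make_health_data(base, seed = 52)
  res <- run_error_scenario(
    base, counts, error_spec(gamma_bar = 0.3, type = "C", n_sims = 5, seed = 53)
  )
  cmp <- compare_predicted_observed(list(res, res))
  expect_equal(nrow(cmp$comparison), 2)
  expect_equal(
    cmp$comparison$observed_unit[1] - cmp$comparison$predicted_unit[1],
    cmp$comparison$observed_unit[2] - cmp$comparison$predicted_unit[2]
  )
  expect_error(compare_predicted_observed(list(res)), "at least 2")
})

test_that("confounding widens the gap between predicted and observed attenuation", {
  n <- 732
  cf <- generate_confounders(n, seed = 62)
  # exposure that co-varies with temperature, so an unadjusted fit is confounded
  seasonal_base <- make_base(n_days = n, seed = 61) |>
    dplyr::mutate(value = value * exp(0.04 * (cf$temperature - mean(cf$temperature))))
  hc <- health_config(confounder_effects = c(temperature = 0.03), seed = 63)
  counts <- generate_health_counts(seasonal_base, hc, confounders = cf)
  spec <- error_spec(gamma_bar = 0.411, type = "C", n_sims = 20, seed = 64)
  # fit WITHOUT adjusting for temperature: prediction should degrade
  res_unadj <- run_error_scenario(seasonal_base, counts, spec)
  gap_unadj <- abs(res_unadj$summary$mean_att_unit - res_unadj$summary$pred_unit)
  # same world with no confounder effect on the outcome: prediction stays close
  counts_clean <- generate_health_counts(seasonal_base, health_config(seed = 63))
  res_clean <- run_error_scenario(seasonal_base, counts_clean, spec)
  gap_clean <- abs(res_clean$summary$mean_att_unit - res_clean$summary$pred_unit)
  expect_gt(gap_unadj, gap_clean)
})
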