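test_that("scaled semivariance and correlation are exact inverses with the documented endpoints", {
  expect_equal(scaled_semivariance_from_r(1), 0)
  expect_equal(correlation_from_semivariance(0), 1)
  expect_equal(correlation_from_semivariance(1), 0)
  # published-table style values round-trip through both directions
  expect_equal(round(scaled_semivariance_from_r(0.903), 3), 0.051)
  expect_equal(round(scaled_semivariance_from_r(0.320), 3), 0.515, tolerance = 1e-8)
  expect_equal(round(correlation_from_semivariance(0.411), 3), 0.417)
  expect_equal(round(correlation_from_semivariance(0.337), 3), 0.496)
  for (r in seq(-0.98, 1, by = 0.02)) {
    expect_equal(correlation_from_semivariance(scaled_semivariance_from_r(r)), r,
      tolerance = 1e-12
    )
  }
  expect_error(scaled_semivariance_from_r(-1), "undefined")
  expect_error(correlation_from_semivariance(-0.1), "nonnegative")
})

test_that("pairwise log correlations respect identity, noise dilution and the overlap rule", {
  n <- 2192
  dates <- study_dates(n)
  set.seed(42)
  lz <- rnorm(n)
  twin <- dplyr::bind_rows(
    tibble::tibble(date = dates, site_id = "a", x_km = 0, y_km = 0, value = exp(lz)),
    tibble::tibble(date = dates, site_id = "b", x_km = 0, y_km = 0, value = exp(lz))
  )
  p <- pairwise_log_correlations(twin)
  expect_equal(p$r, 1, tolerance = 1e-12)
  expect_equal(p$distance_km, 0)
  expect_equal(p$gamma, 0, tolerance = 1e-12)

  # second series = first plus independent unit-variance log noise: R -> 1/sqrt(2)
  noisy <- dplyr::bind_rows(
    tibble::tibble(date = dates, site_id = "a", x_km = 0, y_km = 0, value = exp(lz)),
    tibble::tibble(
      date = dates, site_id = "b", x_km = 5, y_km = 0,
      value = exp(lz + rnorm(n))
    )
  )
  p2 <- pairwise_log_correlations(noisy)
  expect_equal(p2$r, 1 / sqrt(2), tolerance = 0.03)

  # disjoint coverage: the pair is dropped, leaving nothing -> analysis error
  half <- dplyr::bind_rows(
    tibble::tibble(date = dates[1:1000], site_id = "a", x_km = 0, y_km = 0, value = exp(lz[1:1000])),
    tibble::tibble(date = dates[1001:2000], site_id = "b", x_km = 5, y_km = 0, value = exp(lz[1001:2000]))
  )
  expect_error(
    suppressWarnings(pairwise_log_correlations(half)),
    "insufficient overlap"
  )
})

test_that("semivariogram fitting recovers a range encoded in a single far pair", {
  nug <- 0.2
  h_far <- 30
  range_true <- 25
  gamma_far <- semivariogram_model(h_far, nug, range_true)
  pairs <- tibble::tibble(
    distance_km = c(0.001, 0.001, 0.001, h_far),
    gamma = c(nug, nug, nug, gamma_far)
  )
  fit <- fit_semivariogram(pairs, nugget = nug)
  # closed form from the far residual alone:
  # range = -3 h / log(1 - (gamma - nugget)/(1 - nugget))
  closed <- -3 * h_far / log(1 - (gamma_far - nug) / (1 - nug))
  expect_equal(fit$range_km, closed, tolerance = 1e-3)
  expect_equal(fit$range_km, range_true, tolerance = 1e-3)
  expect_equal(fit$sill, 1)
  expect_equal(predict(fit, 0), nug)

  expect_error(
    fit_semivariogram(
      tibble::tibble(distance_km = c(10, 10, 10), gamma = c(0.4, 0.5, 0.6)),
      nugget = 0.1
    ),
    "unidentifiable"
  )
  expect_error(
    fit_semivariogram(tibble::tibble(distance_km = 0, gamma = 0.1), nugget = 0.1),
    "positive-distance"
  )
})

test_that("population weighting matches a brute-force pair enumeration and its invariances", {
  # three collinear tracts at x = 0, 1, 3 with an arbitrary gamma lookup
  tracts <- tibble::tibble(
    tract_id = c("t1", "t2", "t3"),
    x_km = c(0, 1, 3), y_km = 0,
    population = c(1L, 2L, 3L)
  )
  lookup <- c("0.5" = 0.05, "1" = 0.1, "2" = 0.3, "3" = 0.2)
  gamma_fun <- function(h) unname(lookup[as.character(h)])
  got <- population_weighted_semivariance(gamma_fun, tracts, within_tract_km = 0.5)

  # independent oracle: loop over all unordered pairs including i = j
  num <- 0; den <- 0
  for (i in 1:3) for (j in i:3) {
    w <- tracts$population[i] + tracts$population[j]
    h <- if (i == j) 0.5 else abs(tracts$x_km[i] - tracts$x_km[j])
    num <- num + w * gamma_fun(h)
    den <- den + w
  }
  expect_equal(got$gamma_bar, num / den)
  expect_equal(got$gamma_bar, 3.2 / 24)
  expect_equal(got$r_bar, correlation_from_semivariance(3.2 / 24))

  # constant gamma field: weighted mean is that constant
  flat <- population_weighted_semivariance(function(h) rep(0.3, length(h)), tracts)
  expect_equal(flat$gamma_bar, 0.3)

  # single tract: only the within-tract distance matters
  one <- population_weighted_semivariance(
    function(h) 0.1 + 0.05 * h, tracts[1, ],
    within_tract_km = 2
  )
  expect_equal(one$gamma_bar, 0.2)

  # invariance under uniform population scaling
  scaled <- dplyr::mutate(tracts, population = population * 17L)
  expect_equal(
    population_weighted_semivariance(gamma_fun, scaled, within_tract_km = 0.5)$gamma_bar,
    got$gamma_bar
  )

  # monotonicity: inflating any pair's gamma weakly increases the average
  bumped <- function(h) gamma_fun(h) + ifelse(h == 2, 0.2, 0)
  expect_gt(
    population_weighted_semivariance(bumped, tracts, within_tract_km = 0.5)$gamma_bar,
    got$gamma_bar
  )

  expect_error(population_weighted_semivariance(gamma_fun, tracts[0, ]), "empty")
})

test_that("the closed-form error budget chain is internally consistent", {
  budget <- error_budget_from_semivariance(c(0, 0.411, 0.9))
  expect_equal(budget$r_bar, correlation_from_semivariance(c(0, 0.411, 0.9)))
  expect_equal(budget$sigma_err[1], 0)
  expect_equal(budget$s_ratio_b[1], 1)
  expect_equal(budget$s_ratio_c[1], 1)
  # B and C ratios are reciprocal and bracket 1
  expect_equal(budget$s_ratio_b * budget$s_ratio_c, rep(1, 3))
  expect_true(all(budget$s_ratio_c >= 1 & budget$s_ratio_b <= 1))
})
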