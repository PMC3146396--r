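# Shared builders for small synthetic worlds used across tests.

# A single-site lognormal base-case series (CO-like defaults).
make_base <- function(n_days = 400, seed = 1, log_mean = 0.18, log_sd = 0.6) {
  cfg <- world_config(
    n_days = n_days, n_sites = 1, log_mean = log_mean, log_sd = log_sd,
    seed = seed
  )
  base_case_series(generate_monitor_field(cfg))
}

# Counts + exposure-ready health data for a base series.
make_health_data <- function(base, alpha = log(76), beta_true = log(1.0139),
                             seed = 2) {
  generate_health_counts(
    base,
    health_config(alpha = alpha, beta_true = beta_true, seed = seed)
  )
}

# Pearson lag-k autocorrelation of a numeric vector.
lag_cor <- function(x, k) {
  n <- length(x)
  cor(x[1:(n - k)], x[(k + 1):n])
}
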