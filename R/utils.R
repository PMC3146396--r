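# Internal helpers shared across modules.

#' Build the daily date index for a study period
#'
#' @param n_days Number of consecutive days.
#' @param start_date First day (anything `as.Date()` accepts). The default
#'   start, 1999-01-01, with the default study length of 2192 days spans the
#'   six calendar years 1999--2004 (two leap years included).
#' @return A `Date` vector of length `n_days`.
#' @export
#' @examples
#' length(study_dates(2192)) # 2192 days: 1999-01-01 .. 2004-12-31
study_dates <- function(n_days, start_date = "1999-01-01") {
  n_days <- as.integer(n_days)
  if (is.na(n_days) || n_days < 1) abort("`n_days` must be a positive integer.")
  seq(as.Date(start_date), by = "day", length.out = n_days)
}

# Population (1/n) standard deviation: the normalization convention used
# throughout, so that standardized series have SD exactly 1.
pop_sd <- function(x) {
  x <- x[!is.na(x)]
  sqrt(mean((x - mean(x))^2))
}

# Deterministic child seeds derived from one parent seed, kept < 2^31.
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, n >= 1)
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so package functions never disturb user RNG.
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}

# Euclidean distance between rows of a two-column coordinate matrix.
pair_distances <- function(xy) {
  as.matrix(stats::dist(xy))
}

check_positive_series <- function(values, what = "series") {
  if (anyNA(values)) abort(paste0("`", what, "` contains missing values."))
  if (any(values <= 0)) {
    abort(paste0("`", what, "` must be strictly positive (lognormal scale)."))
  }
  invisible(values)
}
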