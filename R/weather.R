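#' Generate a synthetic daily-rain weather series
#'
#' The surrogate only needs weather for one purpose: the rain-delay rule for
#' fertiliser applications (an application scheduled on a rainy day slides
#' forward one day at a time until the first dry day). Rain is modelled as
#' independent Bernoulli days at probability `rain_prob`, reproducible from
#' `seed`. Day 1 of the grid is 1 March of each season.
#'
#' @param n_seasons number of cropping seasons (default 9).
#' @param n_days days tracked per season from 1 March (default 160, well past
#'   the last nominal application day, day 113).
#' @param rain_prob probability a given day is wet (default 0.3, a typical
#'   west-of-England frequency of rain days).
#' @param seed integer seed; the same seed gives a bit-identical rain grid.
#' @return object of class `weather_series` with a logical
#'   `n_seasons x n_days` matrix `rain_days`.
#' @export
weather_series <- function(n_seasons = 9L, n_days = 160L, rain_prob = 0.3,
                           seed = 1L) {
  stopifnot(n_seasons >= 1L, n_days >= 1L,
            rain_prob >= 0, rain_prob <= 1)
  rain <- with_preserved_rng(seed, {
    matrix(stats::runif(n_seasons * n_days) < rain_prob,
           nrow = n_seasons, ncol = n_days)
  })
  structure(list(n_seasons = as.integer(n_seasons),
                 n_days = as.integer(n_days),
                 rain_prob = rain_prob,
                 seed = as.integer(seed),
                 rain_days = rain),
            class = "weather_series")
}

#' @export
print.weather_series <- function(x, ...) {
  cat(sprintf(
    "<weather_series> %d seasons x %d days, P(rain) = %.2f, seed %d (%.0f%% wet days drawn)\n",
    x$n_seasons, x$n_days, x$rain_prob, x$seed, 100 * mean(x$rain_days)))
  invisible(x)
}

# Run code with a local RNG seed without disturbing the caller's RNG state.
with_preserved_rng <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Derive a named sub-seed from a master seed
#'
#' All randomness in a pipeline run flows from one explicit master seed;
#' each component (weather, per-soil optimizer, combiner, ...) draws from its
#' own stream whose seed is a deterministic hash of the master seed and the
#' stream name. Result is always in `[0, 2^31 - 2]`.
#'
#' @param seed master integer seed.
#' @param name character stream name.
#' @return integer sub-seed.
#' @export
sub_seed <- function(seed, name) {
  stopifnot(length(name) == 1L, is.character(name))
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% 2147483647
  as.integer((abs(as.numeric(seed)) %% 2147483647 * 31 + h) %% 2147483647)
}
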