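# Independent oracles and shared fixtures for the test suite.

# O(n^2) front peeling built on scalar pairwise dominance only: for each
# peel, a point joins the front iff no unassigned point dominates it.
oracle_nd_rank <- function(obj, directions) {
  n <- nrow(obj)
  rank <- rep(NA_integer_, n)
  r <- 0L
  while (anyNA(rank)) {
    open <- which(is.na(rank))
    for (j in open) {
      dominated <- FALSE
      for (i in open) {
        if (i != j && dominates(obj[i, ], obj[j, ], directions)) {
          dominated <- TRUE
          break
        }
      }
      if (!dominated) rank[j] <- r
    }
    r <- r + 1L
  }
  rank
}

# ZDT1 test problem: d decision variables in [0,1], both objectives
# minimized; true front is f2 = 1 - sqrt(f1) at x2..xd = 0.
zdt1_evaluate <- function(genome) {
  d <- length(genome)
  f1 <- genome[1L]
  g <- 1 + 9 * sum(genome[-1L]) / (d - 1)
  c(f1 = f1, f2 = g * (1 - sqrt(f1 / g)))
}

zdt1_bounds <- function(d = 8L) {
  list(lower = rep(0, d), upper = rep(1, d), integer = rep(FALSE, d),
       names = paste0("x", seq_len(d)))
}

# Closed-form hypervolume of the true ZDT1 front w.r.t. reference (r, r),
# r >= 1: integral of (r - (1 - sqrt(a))) over a in [0,1] plus the strip
# a in [1, r] of height r.
zdt1_true_hv <- function(r = 1.1) (r - 1) + 2 / 3 + (r - 1) * r

random_objectives <- function(n, m, duplicates = TRUE) {
  obj <- matrix(stats::runif(n * m), n, m)
  if (duplicates && n > 4L) {
    # duplicated rows and duplicated single coordinates (adversarial ties)
    obj[2L, ] <- obj[1L, ]
    obj[3L, 1L] <- obj[4L, 1L]
    obj <- round(obj, 2)
  }
  obj
}

test_soils <- read_soils()
test_calib <- read_calibration()
test_weather <- weather_series(n_seasons = 9L, seed = 20260911L)

random_plan <- function() {
  rates <- ifelse(stats::runif(9) < 0.5, 0, stats::runif(9, 0, 100))
  management_plan(rates, stats::runif(1, 0, 3), sample(0:3, 1L))
}

# Tiny frontier on the package's six objectives: n points on a line where
# yield rises as profit falls (mutually non-dominated), everything else flat.
toy_frontier <- function(n, shift = 0) {
  obj <- cbind(yield = seq_len(n) + shift,
               profit = rev(seq_len(n)) + shift,
               n2o = rep(1, n), delta_soc = rep(0, n),
               nue = rep(0.7, n), n_surplus = rep(40, n))
  genomes <- matrix(stats::runif(n * 11, 0, 1), n, 11,
                    dimnames = list(NULL, plan_bounds()$names))
  frontier(genomes, obj)
}
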