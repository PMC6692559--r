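# reference reimplementation of bound repair for the DE closed-form check
repair_genome_ref <- function(g, b) {
  g <- pmin(pmax(g, b$lower), b$upper)
  g[b$integer] <- round(g[b$integer])
  g
}

test_that("dominance is standard, direction-aware Pareto dominance", {
  d2 <- c(a = 1, b = -1)   # maximize a, minimize b
  expect_false(dominates(c(1, 2), c(1, 2), d2))
  expect_true(dominates(c(2, 1), c(1, 2), d2))
  expect_false(dominates(c(2, 3), c(1, 2), d2))   # better a, worse b
  expect_true(dominates(c(1, 1), c(1, 2), d2))    # equal a, better b
  expect_error(dominates(c(1, 2, 3), c(1, 2), d2), "equal length")
})

test_that("fast non-dominated sort matches the pairwise oracle", {
  expect_equal(nd_sort(matrix(1:2, 1), c(1, 1))$rank, 0L)
  # chain of mutually dominating points: three singleton fronts
  chain <- rbind(c(3, 3), c(2, 2), c(1, 1))
  srt <- nd_sort(chain, c(1, 1))
  expect_equal(srt$rank, 0:2)
  expect_equal(lengths(srt$fronts), rep(1L, 3))

  set.seed(4321)
  for (i in 1:25) {
    m <- sample(2:6, 1)
    n <- sample(10:60, 1)
    dirs <- sample(c(-1, 1), m, replace = TRUE)
    obj <- random_objectives(n, m)
    srt <- nd_sort(obj, dirs)
    expect_equal(srt$rank, oracle_nd_rank(obj, dirs))
    # rank-0 members are exactly the undominated ones
    expect_setequal(srt$fronts[[1L]], which(srt$rank == 0L))
  }
})

test_that("crowding distance matches hand computation and tie rules", {
  # 2-point front: both boundaries
  expect_equal(crowding_distance(rbind(c(0, 1), c(1, 0))), c(Inf, Inf))
  # 3 collinear equally spaced points, 2 objectives: middle = 1 + 1
  cd <- crowding_distance(rbind(c(0, 2), c(1, 1), c(2, 0)))
  expect_equal(cd[2], 2)
  expect_equal(cd[c(1, 3)], c(Inf, Inf))
  # all-identical objectives: interior distances 0 (zero-range objectives)
  cd <- crowding_distance(matrix(5, nrow = 4, ncol = 3))
  expect_equal(sum(is.finite(cd)), 2)
  expect_equal(cd[is.finite(cd)], c(0, 0))
})

test_that("DE trial vectors follow rand/1/bin with bound repair", {
  set.seed(7)
  g <- matrix(stats::runif(8 * 11, 0, 100), 8, 11)
  b <- plan_bounds()
  g[, 10] <- stats::runif(8, 0, 3)
  g[, 11] <- sample(0:3, 8, replace = TRUE)

  # F = 0, CR = 1: trial is exactly donor x_r1 (up to integer rounding)
  set.seed(42)
  r1 <- sample(setdiff(1:8, 1L), 3L)[1L]
  set.seed(42)
  trial <- de_trial(1L, g, de_F = 0, de_CR = 1, b)
  expect_equal(trial, repair_genome_ref(g[r1, ], b))

  # CR = 0: exactly one gene differs (the guaranteed donor gene)
  for (i in 1:5) {
    trial <- de_trial(2L, g, de_F = 0.5, de_CR = 0, b)
    expect_lte(sum(trial != g[2L, ]), 1)
  }

  # determinism given the RNG state
  set.seed(99); t1 <- de_trial(3L, g, 0.8, 0.9, b)
  set.seed(99); t2 <- de_trial(3L, g, 0.8, 0.9, b)
  expect_identical(t1, t2)

  # bounds always respected, timing gene integer
  set.seed(5)
  for (i in 1:50) {
    tr <- de_trial(sample(8, 1), g, 1.5, 0.9, b)
    expect_true(all(tr >= b$lower & tr <= b$upper))
    expect_equal(tr[11], round(tr[11]))
  }
  expect_error(de_trial(1L, g[1:3, ], 0.5, 0.5, b), ">= 4")
})

test_that("initial population seeding applies the sparse 6-8-zero rule", {
  cfg <- optimizer_config(pop_size = 100, sparse_seed_fraction = 0.5)
  seeds <- default_user_seeds()
  set.seed(11)
  pop <- seed_initial_population(cfg, seeds)
  expect_equal(dim(pop), c(100L, 11L))
  b <- plan_bounds()
  expect_true(all(apply(pop, 1, function(r)
    all(r >= b$lower & r <= b$upper))))
  expect_equal(pop[1, 1:9], plan_genome(seeds[[1]])[1:9],
               ignore_attr = TRUE)
  zero_counts <- rowSums(pop[, 1:9] == 0)
  sparse_rows <- 3 + seq_len(50)   # after the 3 user seeds
  expect_true(all(zero_counts[sparse_rows] >= 6 &
                    zero_counts[sparse_rows] <= 8))
  # the rest (fully random) essentially never hit 6 zeros by chance
  expect_true(all(zero_counts[54:100] < 6))
  # fraction 0: no sparse members
  set.seed(11)
  pop0 <- seed_initial_population(
    optimizer_config(pop_size = 40, sparse_seed_fraction = 0), list())
  expect_true(all(rowSums(pop0[, 1:9] == 0) < 6))
  expect_error(optimizer_config(sparse_seed_fraction = 0.7), "0.5")
})

test_that("trim_frontier keeps extremes and the archive size", {
  n <- 200
  obj <- cbind(yield = seq_len(n), profit = rev(seq_len(n)),
               n2o = rep(1, n), delta_soc = rep(0, n), nue = rep(0.7, n),
               n_surplus = rep(40, n))
  f <- frontier(matrix(stats::runif(n * 11), n, 11), obj)
  t100 <- trim_frontier(f, 100)
  expect_equal(frontier_size(t100), 100)
  expect_true(1 %in% t100$objectives[, "yield"])     # extremes retained
  expect_true(n %in% t100$objectives[, "yield"])
  # output still mutually non-dominated
  expect_equal(max(nd_sort(t100$objectives)$rank), 0L)
  # no-op when already small enough
  expect_equal(frontier_size(trim_frontier(t100, 150)), 100)
})

test_that("hypervolume: exact 2-D staircase and Monte Carlo agree", {
  # two maximized objectives, ref (0,0): union of rectangles = 5
  obj <- rbind(c(3, 1), c(1, 3))
  expect_equal(hypervolume(obj, c(1, 1), c(0, 0)), 5)
  # dominated point contributes nothing
  expect_equal(hypervolume(rbind(obj, c(1, 1)), c(1, 1), c(0, 0)), 5)
  # MC estimate on the same set embedded in 3-D (flat third objective)
  obj3 <- cbind(obj, c(1, 1))
  hv3 <- hypervolume(obj3, c(1, 1, 1), c(0, 0, 0), nsamples = 50000,
                     seed = 1)
  expect_equal(hv3, 5, tolerance = 0.05)
  expect_identical(hv3, hypervolume(obj3, c(1, 1, 1), c(0, 0, 0),
                                    nsamples = 50000, seed = 1))
})

test_that("evolve is elitist, deterministic, and solves a unimodal problem", {
  # degenerate 1-objective case: second objective constant; optimum of
  # the sphere at 0.3 found by comparison with a fine grid search
  sphere <- function(g) c(f1 = sum((g - 0.3)^2), f2 = 1)
  b <- list(lower = rep(0, 3), upper = rep(1, 3), integer = rep(FALSE, 3),
            names = paste0("x", 1:3))
  cfg <- optimizer_config(pop_size = 30, n_generations = 60, seed = 5,
                          sparse_seed_fraction = 0)
  f <- evolve(sphere, b, cfg, directions = c(f1 = -1, f2 = -1))
  grid_best <- min(apply(as.matrix(expand.grid(
    x = seq(0, 1, 0.05), y = seq(0, 1, 0.05), z = seq(0, 1, 0.05))),
    1, function(g) sphere(g)[["f1"]]))
  expect_lt(min(f$objectives[, "f1"]), grid_best + 1e-4)

  # determinism: same seed, identical frontier
  f2 <- evolve(sphere, b, cfg, directions = c(f1 = -1, f2 = -1))
  expect_identical(f$objectives, f2$objectives)

  # elitism on ZDT1: per-objective bests never worsen between generations
  zb <- zdt1_bounds(6L)
  cfgz <- optimizer_config(pop_size = 20, n_generations = 15, seed = 3,
                           sparse_seed_fraction = 0, hv_every = 1,
                           hv_ref = c(f1 = 2, f2 = 11))
  logged <- list()
  fz <- evolve(zdt1_evaluate, zb, cfgz, directions = c(f1 = -1, f2 = -1),
               log = function(gen, fs, hv)
                 logged[[length(logged) + 1L]] <<- hv)
  hvs <- unlist(logged)
  expect_equal(length(hvs), 15)
  expect_true(all(diff(hvs) >= -1e-9))   # dominated volume never shrinks
  expect_equal(max(nd_sort(fz$objectives,
                           c(-1, -1))$rank), 0L)
})

test_that("evaluation failures are absorbed as worst objectives", {
  flaky <- function(g) {
    if (g[1] > 0.5) stop("simulator blew up")
    c(f1 = g[1], f2 = 1 - g[1])
  }
  b <- list(lower = 0, upper = 1, integer = FALSE, names = "x")
  # population of 6 genomes spanning the failure region
  cfg <- optimizer_config(pop_size = 6, n_generations = 4, seed = 2,
                          sparse_seed_fraction = 0)
  expect_message(
    f <- evolve(flaky, b, cfg, directions = c(f1 = 1, f2 = 1)),
    "evaluation failed")
  expect_true(all(is.finite(f$objectives)))
})

test_that("frontier CSV round-trips with deterministic row order", {
  f <- toy_frontier(12)
  path <- withr::local_tempfile(fileext = ".csv")
  write_frontier(f, path)
  g <- read_frontier(path)
  expect_equal(frontier_size(g), 12)
  expect_equal(colnames(g$objectives), colnames(f$objectives))
  # rows sorted lexicographically by objectives
  df <- utils::read.csv(path)
  expect_equal(df$obj_yield, sort(df$obj_yield))
  # second write is byte-identical
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_frontier(g, path2)
  expect_identical(readLines(path), readLines(path2))
})
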