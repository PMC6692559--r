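dry_weather <- function(n_seasons = 1L, n_days = 160L) {
  w <- weather_series(n_seasons = n_seasons, n_days = n_days, rain_prob = 0,
                      seed = 1L)
  stopifnot(!any(w$rain_days))
  w
}

test_that("soil profiles validate texture and carry Table-style fields", {
  expect_error(soil_profile("x", 0.5, 0.4, 0.2, 1, 7, 1.3, 8),
               "sum to 1")
  expect_error(soil_profile("x", 0.5, 0.4, 0.1, -1, 7, 1.3, 8), "soc_init")
  s <- test_soils
  expect_named(s, c("clay", "sandy_clay", "sandy_loam"))
  expect_equal(s$clay$clay_frac, 0.76)
  expect_equal(s$sandy_loam$soc_init, 0.96)
  expect_equal(vapply(s, `[[`, numeric(1), "y_pot"),
               c(clay = 8.7, sandy_clay = 7.0, sandy_loam = 7.5))
})

test_that("management plan bounds are enforced with the offending gene named", {
  expect_error(management_plan(rep(0, 8)), "exactly 9")
  expect_error(management_plan(c(rep(0, 4), 101, rep(0, 4))), "n_rates\\[5\\]")
  expect_error(management_plan(rep(0, 9), fym_amount = 3.5), "fym_amount")
  expect_error(management_plan(rep(0, 9), fym_weeks_before_sowing = 5),
               "fym_weeks")
  p <- management_plan(rep(50, 9), 2, 3)
  expect_identical(plan_from_genome(plan_genome(p)), p)
})

test_that("application scheduling follows nominal dates and the rain-delay rule", {
  w <- dry_weather()
  expect_equal(nrow(schedule_applications(management_plan(rep(0, 9)), w, 1)), 0)

  one <- management_plan(c(50, rep(0, 8)))
  sched <- schedule_applications(one, w, 1)
  expect_equal(sched$day, 1L)
  expect_equal(sched$rate, 50)

  all9 <- management_plan(rep(10, 9))
  sched <- schedule_applications(all9, w, 1)
  expect_equal(sched$day, 1L + 14L * (0:8))

  # rain on the nominal day and the next: application slides two days
  w2 <- dry_weather()
  w2$rain_days[1, 1:2] <- TRUE
  sched <- schedule_applications(one, w2, 1)
  expect_equal(sched$day, 3L)
  expect_equal(sched$delay_days, 2L)

  # delays never reorder applications
  w3 <- dry_weather()
  w3$rain_days[1, 1:20] <- TRUE
  sched <- schedule_applications(management_plan(c(10, 10, rep(0, 7))), w3, 1)
  expect_equal(sched$day, c(21L, 22L))

  expect_error(schedule_applications(one, w, 5), "out of range")
})

test_that("yield response is saturating, concave and anchored at y_pot", {
  soil <- test_soils$sandy_loam
  expect_error(yield_response(-1, soil, test_calib), ">= 0")
  y0 <- yield_response(0, soil, test_calib)
  expect_equal(y0, soil$y_pot *
                 (1 - exp(-test_calib$n_background / test_calib$n_scale)))
  expect_gt(y0, 0)
  expect_equal(yield_response(1e7, soil, test_calib), soil$y_pot)
  # concavity: equal N increments buy less at high N
  expect_lt(yield_response(100, soil, test_calib) -
              yield_response(80, soil, test_calib),
            yield_response(40, soil, test_calib) -
              yield_response(20, soil, test_calib))
  # strictly increasing
  ns <- seq(0, 300, by = 10)
  expect_true(all(diff(yield_response(ns, soil, test_calib)) > 0))
})

test_that("N2O response is convex in N and ordered by texture", {
  calib <- test_calib
  base <- n2o_emission(0, 0, test_soils$clay, calib)
  expect_equal(base, (calib$tex0 + calib$tex1 * 0.76) * calib$e0)
  # fine textures emit more at the same management
  for (N in c(0, 50, 150, 300)) {
    e <- vapply(test_soils, function(s) n2o_emission(N, 1, s, calib),
                numeric(1))
    expect_gt(e[["clay"]], e[["sandy_clay"]])
    expect_gt(e[["sandy_clay"]], e[["sandy_loam"]])
  }
  # convexity by evaluation
  s <- test_soils$sandy_clay
  expect_gt(n2o_emission(200, 0, s, calib) - n2o_emission(100, 0, s, calib),
            n2o_emission(100, 0, s, calib) - n2o_emission(0, 0, s, calib))
  expect_error(n2o_emission(-5, 0, s, calib), ">= 0")
})

test_that("SOC recurrence decays without inputs and grows with them", {
  calib <- test_calib
  expect_equal(soc_update(2, 0, 0, calib), 2 * (1 - calib$soc_decay))
  expect_equal(soc_update(2, 1, 0, calib) - soc_update(2, 0, 0, calib),
               calib$h_fym)
  expect_gt(soc_update(2, 0, 1.5, calib), soc_update(2, 0, 1, calib))
  expect_error(soc_update(-0.1, 0, 0, calib), "> 0")
})

test_that("simulation honours the stated accounting contract", {
  soil <- test_soils$sandy_clay
  zero <- management_plan(rep(0, 9))
  res <- simulate_seasons(zero, soil, test_weather, test_calib)
  expect_equal(nrow(res), 9)
  # zero-input plan: inputs are deposition only, every season at baseline
  expect_true(all(res$n_inputs == test_calib$deposition))
  expect_equal(res$yield_t_ha,
               rep(yield_response(0, soil, test_calib), 9))
  # ... and SOC declines over nine zero-input seasons
  expect_lt(delta_soc(res), 0)

  # determinism: identical seed, identical outputs
  w1 <- weather_series(seed = 7)
  w2 <- weather_series(seed = 7)
  p <- management_plan(c(0, 40, 0, 80, 0, 0, 20, 0, 0), 1.5, 2)
  expect_identical(simulate_seasons(p, soil, w1, test_calib),
                   simulate_seasons(p, soil, w2, test_calib))

  # FYM raises both SOC and N2O in every season, at matched mineral N
  with_fym <- management_plan(c(50, 50, rep(0, 7)), 3, 1)
  no_fym <- management_plan(c(50, 50, rep(0, 7)), 0, 1)
  a <- simulate_seasons(with_fym, soil, test_weather, test_calib)
  b <- simulate_seasons(no_fym, soil, test_weather, test_calib)
  expect_true(all(a$soc_end > b$soc_end))
  expect_true(all(a$n2o_co2eq > b$n2o_co2eq))
})

test_that("yield is bounded by y_pot and monotone in any single rate", {
  set.seed(99)
  for (soil in test_soils) {
    for (rep in 1:5) {
      p <- random_plan()
      res <- simulate_seasons(p, soil, test_weather, test_calib)
      expect_true(all(res$yield_t_ha <= soil$y_pot))
      # raise one gene (keeping within bounds): mean yield never decreases
      g <- plan_genome(p)
      i <- sample.int(9, 1)
      g[i] <- min(100, g[i] + 25)
      res2 <- simulate_seasons(plan_from_genome(g), soil, test_weather,
                               test_calib)
      expect_gte(mean(res2$yield_t_ha), mean(res$yield_t_ha))
    }
  }
})

test_that("weather series is reproducible and seed-sensitive", {
  a <- weather_series(seed = 11)
  b <- weather_series(seed = 11)
  c <- weather_series(seed = 12)
  expect_identical(a$rain_days, b$rain_days)
  expect_false(identical(a$rain_days, c$rain_days))
  expect_equal(dim(a$rain_days), c(9L, 160L))
})
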