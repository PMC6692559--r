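#' Schedule fertiliser applications for one season
#'
#' Nominal application dates start on 1 March (day 1 of the weather grid)
#' with subsequent slots at two-week intervals: slot i falls on day
#' `1 + 14*(i - 1)`. An application scheduled on a rainy day is delayed one
#' day at a time until the first dry day. Zero-rate slots are omitted from
#' the schedule. Delays cannot reorder applications: each application starts
#' looking no earlier than the day after the previous one went on. Days past
#' the end of the rain grid are treated as dry.
#'
#' @param plan a [management_plan()].
#' @param weather a [weather_series()].
#' @param season season index (1-based).
#' @return data.frame with columns `slot`, `day`, `rate`, `delay_days`
#'   (one row per non-zero application).
#' @export
schedule_applications <- function(plan, weather, season) {
  validate_plan(plan)
  if (season < 1L || season > weather$n_seasons)
    stop("season ", season, " out of range 1..", weather$n_seasons)
  s <- schedule_core(plan$n_rates, weather$rain_days[season, ])
  data.frame(slot = s$slot, day = s$day, rate = plan$n_rates[s$slot],
             delay_days = s$delay)
}

# Vector core of the scheduler (hot path: called per season per evaluation).
schedule_core <- function(rates, rain) {
  slots <- which(rates > 0)
  k <- length(slots)
  day <- integer(k)
  delay <- integer(k)
  nr <- length(rain)
  day_prev <- 0L
  for (j in seq_len(k)) {
    nominal <- 1L + 14L * (slots[j] - 1L)
    d <- max(nominal, day_prev + 1L)
    while (d <= nr && rain[d]) d <- d + 1L
    day[j] <- d
    delay[j] <- d - nominal
    day_prev <- d
  }
  list(slot = slots, day = day, delay = delay)
}

#' Saturating (Mitscherlich-type) yield response to nitrogen
#'
#' `y = y_pot * (1 - exp(-(effective_n + n_background) / n_scale))`:
#' strictly increasing and concave in N, asymptote `y_pot`, positive at zero
#' fertiliser N because the soil supplies a background N pool
#' (`n_background`, mineralization plus deposition available to the crop).
#'
#' @param effective_n plant-available fertiliser N, kg N/ha (>= 0).
#' @param soil a [soil_profile()].
#' @param calib calibration list from [read_calibration()].
#' @return grain yield, t/ha.
#' @export
yield_response <- function(effective_n, soil, calib = read_calibration()) {
  if (any(!is.finite(effective_n)) || any(effective_n < 0))
    stop("effective_n must be >= 0")
  soil$y_pot * (1 - exp(-(effective_n + calib$n_background) / calib$n_scale))
}

#' Nitrous oxide emission response
#'
#' Convex (super-linear) response to total N input with a texture
#' multiplier increasing in clay content, so at equal management fine
#' textured soils emit more than coarse ones, plus a manure term:
#' `e = (tex0 + tex1 * clay_frac) * (e0 + e1 * N^alpha + e2 * fym)`,
#' with `alpha > 1`. Units follow the package's emission scale
#' (10^3 kg CO2-equivalent per ha per year).
#'
#' @param total_n_input total N entering the soil, kg N/ha (mineral +
#'   manure + atmospheric deposition).
#' @param fym_amount farm-yard manure applied, t/ha.
#' @param soil a [soil_profile()].
#' @param calib calibration list.
#' @return emission, 10^3 kg CO2-eq /ha /yr.
#' @export
n2o_emission <- function(total_n_input, fym_amount, soil,
                         calib = read_calibration()) {
  if (any(total_n_input < 0) || any(fym_amount < 0))
    stop("N input and FYM amount must be >= 0")
  tex <- calib$tex0 + calib$tex1 * soil$clay_frac
  tex * (calib$e0 + calib$e1 * total_n_input^calib$alpha +
           calib$e2 * fym_amount)
}

#' One-season soil organic carbon update
#'
#' Linear recurrence: SOC gains from manure and crop residue carbon, and
#' decays by a constant fractional rate:
#' `soc_next = soc_prev + h_fym * fym + h_res * residue_c - d * soc_prev`.
#' Monotone increasing in both inputs.
#'
#' @param soc_prev SOC at season start, % mass (> 0).
#' @param fym_amount manure applied, t/ha.
#' @param residue_c crop residue carbon returned, t C/ha.
#' @param calib calibration list.
#' @return SOC at season end, %.
#' @export
soc_update <- function(soc_prev, fym_amount, residue_c,
                       calib = read_calibration()) {
  if (any(soc_prev <= 0)) stop("soc_prev must be > 0")
  soc_prev + calib$h_fym * fym_amount + calib$h_res * residue_c -
    calib$soc_decay * soc_prev
}

#' Simulate a management plan over all seasons
#'
#' Deterministic given the weather seed. Per season: the application
#' schedule is built with the rain-delay rule; each application contributes
#' `rate * efficiency` plant-available N, where efficiency rises mildly with
#' the slot index (`eff_base + eff_slope * (slot - 1)`, a timing bonus for
#' later spring applications) and is reduced by `delay_penalty` per delay
#' day; a texture-dependent fraction (`leach0 + leach1 * sand_frac`) of all
#' applied N (mineral + manure) is leached and removed from the available
#' pool; manure contributes `fym_amount * fym_n_content` kg N of which
#' `fym_avail_base + fym_avail_week * weeks_before_sowing` is
#' plant-available. Yield follows [yield_response()], emissions
#' [n2o_emission()], and SOC the [soc_update()] recurrence on residue
#' carbon `residue_c_per_t * yield`. N inputs include mineral N, manure N
#' and constant atmospheric deposition; N exported in grain and straw is
#' `n_out_per_t * yield`.
#'
#' @param plan a [management_plan()].
#' @param soil a [soil_profile()].
#' @param weather a [weather_series()].
#' @param calib calibration list.
#' @return data.frame with one row per season (columns `season`,
#'   `yield_t_ha`, `n2o_co2eq`, `n_leached`, `n_inputs`,
#'   `n_outputs_grain_straw`, `soc_end`) and attribute `soc_init`.
#' @export
simulate_seasons <- function(plan, soil, weather,
                             calib = read_calibration()) {
  validate_plan(plan)
  mineral_n <- sum(plan$n_rates)
  fym_n <- plan$fym_amount * calib$fym_n_content
  leach_frac <- calib$leach0 + calib$leach1 * soil$sand_frac
  fym_avail <- max(0, calib$fym_avail_base +
                     calib$fym_avail_week * plan$fym_weeks_before_sowing)
  n_inputs <- mineral_n + fym_n + calib$deposition
  n2o <- n2o_emission(n_inputs, plan$fym_amount, soil, calib)
  n_leached <- leach_frac * (mineral_n + fym_n)

  avail_fym <- fym_n * fym_avail * (1 - leach_frac)
  soc <- soil$soc_init
  ns <- weather$n_seasons
  yield_s <- numeric(ns)
  soc_s <- numeric(ns)
  for (s in seq_len(ns)) {
    sched <- schedule_core(plan$n_rates, weather$rain_days[s, ])
    eff <- pmax(0, calib$eff_base + calib$eff_slope * (sched$slot - 1) -
                  calib$delay_penalty * sched$delay)
    avail_mineral <- sum(plan$n_rates[sched$slot] * eff) * (1 - leach_frac)
    yld <- yield_response(avail_mineral + avail_fym, soil, calib)
    soc <- soc_update(soc, plan$fym_amount,
                      calib$residue_c_per_t * yld, calib)
    yield_s[s] <- yld
    soc_s[s] <- soc
  }
  out <- data.frame(season = seq_len(ns),
                    yield_t_ha = yield_s, n2o_co2eq = n2o,
                    n_leached = n_leached, n_inputs = n_inputs,
                    n_outputs_grain_straw = calib$n_out_per_t * yield_s,
                    soc_end = soc_s)
  attr(out, "soc_init") <- soil$soc_init
  out
}
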