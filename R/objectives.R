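#' Objective names and optimization directions
#'
#' The single source of truth for the six objectives and their directions:
#' yield (t/ha), profit (GBP/ha/yr), N2O (10^3 kg CO2-eq/ha/yr), change in
#' SOC (%), NUE (ratio) are maximized except N2O; N surplus
#' (kg N/ha/yr) and N2O are minimized.
#'
#' @return named numeric vector, `+1` = maximize, `-1` = minimize.
#' @export
objective_directions <- function() {
  c(yield = 1, profit = 1, n2o = -1, delta_soc = 1, nue = 1, n_surplus = -1)
}

#' Default economic parameters
#'
#' Placeholder farm economics (feed-wheat price and fertiliser costs at
#' typical pre-2019 UK levels); every analysis in the package is either
#' invariant to them or fixes them explicitly.
#'
#' @param crop_price GBP per t grain.
#' @param n_price_mineral GBP per kg mineral N.
#' @param n_price_fym GBP per kg N in farm-yard manure.
#' @param p_cost_total fixed P-fertiliser cost, GBP/ha/yr.
#' @param application_cost GBP per application event (spreader pass).
#' @return named list of class `economic_params`.
#' @export
economic_params <- function(crop_price = 150, n_price_mineral = 0.79,
                            n_price_fym = 0.30, p_cost_total = 30,
                            application_cost = 10) {
  vals <- c(crop_price, n_price_mineral, n_price_fym, p_cost_total,
            application_cost)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("economic parameters must be non-negative")
  structure(list(crop_price = crop_price, n_price_mineral = n_price_mineral,
                 n_price_fym = n_price_fym, p_cost_total = p_cost_total,
                 application_cost = application_cost),
            class = "economic_params")
}

#' Average of a per-season series
#' @param values non-empty numeric vector.
#' @return arithmetic mean.
#' @export
mean_annual <- function(values) {
  if (!length(values)) stop("empty per-season series")
  mean(values)
}

#' Average annual profit of a plan
#'
#' Sum over years of yield times crop price, minus the total cost of N
#' fertiliser (mineral plus manure N), the total P-fertiliser cost and the
#' cost of applying N, divided by the number of years. The event count per
#' year is the number of non-zero mineral applications plus one manure
#' event when `fym_amount > 0`.
#'
#' @param yields per-year grain yields, t/ha (length `n_years`).
#' @param plan a [management_plan()].
#' @param econ an [economic_params()].
#' @param n_years number of years averaged over.
#' @param fym_n_content kg N per t of manure (from the calibration file).
#' @return GBP/ha/yr.
#' @export
profit <- function(yields, plan, econ, n_years = length(yields),
                   fym_n_content = read_calibration()$fym_n_content) {
  if (n_years < 1L) stop("n_years must be >= 1")
  if (length(yields) != n_years)
    stop("need one yield per year (", n_years, ")")
  revenue <- sum(yields) * econ$crop_price
  n_cost_yr <- sum(plan$n_rates) * econ$n_price_mineral +
    plan$fym_amount * fym_n_content * econ$n_price_fym
  n_events_yr <- sum(plan$n_rates > 0) + (plan$fym_amount > 0)
  (revenue - n_years * (n_cost_yr + n_events_yr * econ$application_cost) -
      econ$p_cost_total * n_years) / n_years
}

#' Nitrogen use efficiency and annualized N surplus
#'
#' N inputs and the N exported in grain and straw are summed over the whole
#' simulation; NUE is their ratio (outputs / inputs) and the surplus is the
#' difference (inputs - outputs), divided by the number of seasons so its
#' units (kg N/ha/yr) match the EU nitrogen panel threshold.
#'
#' @param season_results data.frame from [simulate_seasons()].
#' @return list with `nue` and `n_surplus` (kg N/ha/yr).
#' @export
nue_and_surplus <- function(season_results) {
  inputs <- sum(season_results$n_inputs)
  outputs <- sum(season_results$n_outputs_grain_straw)
  if (inputs <= 0) stop("total N inputs must be > 0")
  list(nue = outputs / inputs,
       n_surplus = (inputs - outputs) / nrow(season_results))
}

#' Change in soil organic carbon over the simulation
#'
#' Final-season SOC minus the initial SOC carried in the `soc_init`
#' attribute of the season results.
#'
#' @param season_results data.frame from [simulate_seasons()].
#' @return change in SOC, % mass.
#' @export
delta_soc <- function(season_results) {
  if (!nrow(season_results)) stop("need at least one season")
  soc0 <- attr(season_results, "soc_init")
  if (is.null(soc0)) stop("season_results lacks the soc_init attribute")
  season_results$soc_end[nrow(season_results)] - soc0
}

#' EU nitrogen panel compliance
#'
#' TRUE iff NUE lies in `[0.5, 0.9]` and the annual N surplus is strictly
#' below 80 kg N/ha/yr, the ranges recommended by the EU nitrogen expert
#' panel.
#'
#' @param obj a named objective vector containing `nue` and `n_surplus`.
#' @return logical.
#' @export
eu_panel_compliance <- function(obj) {
  unname(obj["nue"] >= 0.5 & obj["nue"] <= 0.9 & obj["n_surplus"] < 80)
}

#' Evaluate a management plan into the six-objective vector
#'
#' Runs the surrogate simulator and assembles the objective vector in the
#' fixed order of [objective_directions()]: mean yield, mean annual profit,
#' mean N2O, change in SOC, NUE, annual N surplus.
#'
#' @param plan a [management_plan()].
#' @param soil a [soil_profile()].
#' @param weather a [weather_series()].
#' @param econ an [economic_params()].
#' @param calib calibration list.
#' @return named numeric vector of length 6.
#' @export
evaluate_plan <- function(plan, soil, weather, econ = economic_params(),
                          calib = read_calibration()) {
  res <- simulate_seasons(plan, soil, weather, calib)
  ns <- nue_and_surplus(res)
  c(yield = mean_annual(res$yield_t_ha),
    profit = profit(res$yield_t_ha, plan, econ, nrow(res),
                    calib$fym_n_content),
    n2o = mean_annual(res$n2o_co2eq),
    delta_soc = delta_soc(res),
    nue = ns$nue,
    n_surplus = ns$n_surplus)
}
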