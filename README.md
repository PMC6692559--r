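# agroptim

Multi-objective optimization of arable land management across
contrasting soils.

## What it does, and for whom

Farms juggle objectives that pull in opposite directions: fertiliser
nitrogen raises wheat yield and profit but also nitrous oxide (N₂O)
emissions and nitrogen surplus, while manure builds soil organic carbon
(SOC) at the cost of extra emissions. `agroptim` is for agronomists and
land-use modellers who want to *map the trade-off frontier* between
these objectives rather than pick a single compromise, and to translate
that frontier into a handful of recognizable management strategies that
can be discussed with stakeholders.

The pipeline has four parts:

1. **Surrogate crop–soil simulator** — maps an 11-gene management plan
   (nine biweekly N rates from 1 March, each 0–100 kg N/ha, with
   rain-delayed application days; a farm-yard-manure dressing 0–3 t/ha;
   its timing 0–3 weeks before sowing) on a soil profile to nine seasons
   of yield, N₂O, leaching, N budget and SOC. Responses are the field's
   canonical shapes: Mitscherlich (saturating) yield
   `y = y_pot(1 − e^{−(N+n_b)/n_s})`, convex N₂O `∝ N^α (α > 1)` scaled
   up on fine textures, and a linear SOC gain/decay recurrence. All
   constants live in one documented calibration file.
2. **Hybrid optimizer** — NSGA-II non-dominated sorting and crowding
   selection with differential-evolution variation (rand/1/bin) over the
   numeric genome, seeded with current practice, extremes, and sparse
   plans (6–8 zero N rates). Six objectives: maximize yield, profit,
   ΔSOC, NUE; minimize N₂O, N surplus. Returns a ~100-point Pareto
   frontier per soil.
3. **Landscape combiner** — stage-2 categorical NSGA-II (population
   1000) that picks one frontier point per soil to optimize the
   equal-area arithmetic-mean objectives over the ~10⁶ combinations of
   three 100-point frontiers; an exhaustive oracle handles small
   instances exactly.
4. **Strategy clustering** — each optimal genome is summarized into
   total N, number of applications, first-application week and FYM
   amount; Ward minimum-variance clustering on standardized Euclidean
   distances partitions the frontier into strategies, ranked by mean
   profit, with the 30%-most-profitable points flagged.

See `vignettes/agroptim-methods.Rmd` for the model, its assumptions, and
every numerical choice.

## Worked example

```r
library(agroptim)

soils   <- read_soils()                                    # clay, sandy_clay, sandy_loam
weather <- weather_series(n_seasons = 9, seed = sub_seed(42, "weather"))

# a conventional three-split dressing with a tonne of manure
plan <- management_plan(c(0, 0, 60, 70, 60, 0, 0, 0, 0), fym_amount = 1,
                        fym_weeks_before_sowing = 2)
round(evaluate_plan(plan, soils$clay, weather), 3)
#>     yield    profit       n2o delta_soc       nue n_surplus
#>     7.982   975.466     7.499     0.077     0.795    45.386
```

7.98 t/ha mean yield, £975/ha/yr profit, 7.5 ×10³ kg CO₂-eq/ha/yr of
N₂O, SOC up 0.077 % over nine seasons, NUE 0.79 with a 45 kg N/ha/yr
surplus — this plan sits inside the EU nitrogen panel's recommended
envelope (`eu_panel_compliance()` returns `TRUE`).

```r
# a small demonstration frontier for the clay soil (larger budgets in practice)
opt   <- optimizer_config(pop_size = 60, n_generations = 120, seed = 42,
                          archive_size = 30)
front <- optimize_soil(soils$clay, weather, opt)
front
#> <frontier> 30 mutually non-dominated points, 6 objectives

res <- cluster_strategies(strategy_features(front), k = 4)
res
#> <cluster_result> 30 points in 4 clusters (sizes: 7, 12, 4, 7)
ranking <- rank_clusters_by_profit(res, front$objectives[, "profit"], top_m = 2)
round(ranking$mean_profit, 0)
#>   1   2   3   4
#> 649 686 806 767
ranking$profitable_cluster_ids
#> [1] 3 4
```

Clusters 3 and 4 are the profitable strategies on this small frontier
(mean £806 and £767/ha/yr); their feature histograms
(`cluster_histograms(res)`) describe *how* those profits are achieved —
total N, number and timing of dressings, and manure use.

The full pipeline (three soils → combined frontier → clusters →
projection tables, all as CSV plus a JSON manifest) is one call:

```r
run_pipeline(pipeline_config(seed = 1, out_dir = "run"))
```

or from the shell via the CLI (`inst/exec/agroptim`):

```sh
Rscript inst/exec/agroptim run-all --seed 1 --out run
```

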