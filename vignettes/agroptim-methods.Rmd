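---
title: "Methods: surrogate agroecosystem model, hybrid multi-objective search, and strategy clustering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surrogate agroecosystem model, hybrid multi-objective search, and strategy clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agroptim)
```

# The problem

Arable land provides food, income, and a set of environmental services
that often pull in opposite directions: fertiliser nitrogen raises wheat
yield and profit but also nitrous oxide (N2O) emission, nitrate leaching
and nitrogen surplus, while organic amendments build soil organic carbon
(SOC) at the cost of extra emissions. `agroptim` treats the question "how
should three contrasting soils be managed together?" as a multi-objective
optimization problem: find the set of management plans that are Pareto
optimal with respect to six objectives — mean yield (t/ha, maximized),
mean annual profit (GBP/ha/yr, maximized), mean N2O emission
(10^3 kg CO2-eq/ha/yr, minimized), change in SOC over the simulation (%,
maximized), nitrogen use efficiency (NUE, maximized), and annual nitrogen
surplus (kg N/ha/yr, minimized) — then describe the frontier in terms of
a small number of recognizable management *strategies*.

A management plan has 11 control variables: nine ammonium-nitrate
application rates (each 0–100 kg N/ha; the first slot falls on 1 March,
later slots at two-week intervals, and an application scheduled on a
rainy day slides to the next dry day), a farm-yard manure (FYM) dressing
(0–3 t/ha) and its timing (0–3 whole weeks before sowing, which we fix at
1 October). The same plan is applied in each of nine simulated seasons.

# The surrogate simulator: a stated world

The process-based crop–soil model that would normally supply yields and
emissions is not part of this package. In its place `agroptim` ships a
deliberately simple *surrogate* that reproduces the qualitative response
structure reported for such models, not their absolute numbers:

* **Yield** follows a Mitscherlich (saturating-exponential) response
  `y = y_pot (1 − exp(−(N_eff + n_background)/n_scale))`: strictly
  increasing, concave, asymptoting at the soil's potential yield
  `y_pot`. At high N, extra fertiliser buys only marginal yield.
* **N2O** is super-linear in total N input,
  `e = (tex0 + tex1·clay)(e0 + e1·N^α + e2·FYM)` with `α = 1.6 > 1`,
  and carries a texture multiplier increasing in clay content, so at
  matched management fine-textured soils emit more than coarse ones
  (clay > sandy clay > sandy loam for the shipped soil table).
* **SOC** follows a linear recurrence
  `soc' = soc + h_fym·FYM + h_res·residue_C − d·soc`; manure and
  residue carbon (proportional to yield) build SOC, a constant
  fractional decay removes it. Under a zero-input plan SOC declines.
* **Nitrogen accounting**: inputs are mineral N, manure N
  (`fym_n_content` kg N per tonne) and a constant atmospheric deposition
  (25 kg N/ha/yr — the paperwork behind national inventories typically
  puts UK arable deposition at 20–30); exports are `n_out_per_t` kg N per
  tonne of grain (grain plus straw). NUE and surplus are computed from
  whole-simulation sums; the surplus is divided by the number of seasons
  so its units (kg N/ha/yr) match the EU nitrogen panel's threshold.
* **Losses and timing**: a texture-dependent fraction
  `leach0 + leach1·sand` of applied N is leached before the crop sees
  it; later application slots get a mild uptake bonus
  (`eff_base + eff_slope·(slot−1)`) so late-starting fertiliser
  programmes can emerge as profitable; every day of rain delay costs
  `delay_penalty` of that application's efficiency.

Every constant lives in one plain-text DCF file
(`extdata/calibration.dcf`, read by `read_calibration()`). The potential
yields 8.7 / 7.0 / 7.5 t/ha for clay / sandy clay / sandy loam are
*calibrated to* the reference maxima for these three soils; they are
anchors, not predictions. Weather is a Bernoulli daily-rain grid
(P(rain) = 0.3) shared across soils and reproducible from one seed; it
exists only to drive the rain-delay rule. What a green test establishes
is therefore that the *pipeline* behaves correctly on a world with the
right response shapes — it says nothing about absolute yields, emissions
or profits on any real field, and the surrogate has no daily water or
carbon process model, no pH dynamics, no between-field nutrient flows
and no year-to-year N carry-over.

# Stage 1: hybrid NSGA-II / differential evolution

Management genomes are numeric, so variation uses differential evolution
(rand/1/bin: donor `x_r1 + F (x_r2 − x_r3)`, binomial crossover with one
guaranteed donor gene, `F = 0.8`, `CR = 0.9` — standard defaults, the
reference procedure names no values). Selection is NSGA-II: parents and
trials are pooled, fast non-dominated sorting partitions the pool into
fronts, and crowding-distance truncation fills the next population. This
makes the search elitist: the best value of every single objective never
worsens. Two details worth stating:

* **Dominance** is the standard Pareto definition (no worse everywhere,
  strictly better somewhere), direction-aware via one source of truth,
  `objective_directions()`.
* **Initialization** is seeded: a few plans representing current
  practice and extremes, plus up to half the population *sparse* — each
  sparse member has 6, 7 or 8 of its nine N genes set to zero. Uniform
  sampling would essentially never propose repeated exact zeros, yet
  optimal plans use few applications; sparse seeding is a convergence
  aid, not a constraint.

The generation budget defaults to 1500; the shipped demo configuration
uses 300 generations with population 100, which on this surrogate is
converged for practical purposes (the hypervolume log is flat over the
last half of the run). Convergence can also stop the run early via a
relative hypervolume-stagnation rule (window and tolerance configurable,
disabled by default, since the reference procedure judged convergence by
eye). The rank-0 set is returned as the frontier, deduplicated (a
frontier is a set of distinct (genome, objectives) points — which is why
a 100-member population typically yields 98–100 frontier points), and
trimmed to the archive size (100) by iteratively dropping the
lowest-crowding point; boundary points are never dropped while interior
points remain. Integer genes (FYM timing) are rounded after variation,
the simplest bound-respecting rule. Evaluation failures are logged and
penalized with worst-possible objectives rather than aborting a run.

# Stage 2: combining soils

For a landscape of equal-area units, combined objectives are arithmetic
means of the chosen per-unit points, and the search space is the product
of the per-unit frontiers (three 100-point frontiers, about 10^6
combinations). The control variables are now categorical frontier
*indices*, so differential evolution's directional moves are
meaningless: stage 2 runs plain NSGA-II with uniform crossover and
random-reset mutation (per-gene rate `1/n_units`), population 1000 —
large relative to the space because the aim is to *represent* the
combined frontier, not merely to find one good point. Sites are assumed
independent: a unit's outputs depend only on its own management.
Duplicate assignments may coexist in the population; the reported
frontier is deduplicated. `brute_force_combine()` enumerates small
instances exactly (capped at 10^6) and serves as the oracle in tests.

# Strategy clustering

Each frontier genome is summarized into four features: total N applied,
number of non-zero applications, week of the first application (sentinel
10 — one past the last slot — for zero-fertiliser plans, keeping the
feature numeric), and FYM amount. FYM timing is deliberately excluded.
Features are standardized by their sample standard deviation
("standardized Euclidean"; range scaling was rejected as less standard),
zero-variance features dropped with a warning, and Ward minimum-variance
linkage (`hclust(method = "ward.D2")`) is cut into exactly `k` clusters.
`k` is the user's choice — the reference analysis picked 9 for the clay
soil by inspecting the dendrogram — and `suggest_k()` reports the
largest merge-height gap as advice without ever auto-selecting. Clusters
are ranked by mean profit, the top two or three flagged as "profitable
strategies", and the per-point "profitable" flag marks the
`ceiling(0.3 n)` highest-profit points (stable tie-break by input
order). Whether standardization should precede or follow summarization
is moot here: clustering operates on the four summarized dimensions and
standardizes those.

# Numerical choices and degenerate inputs

* All randomness flows from one master seed through named, hashed
  sub-streams (`sub_seed()`), so weather, each soil's optimizer, and the
  combiner are independently reproducible; RNG state of the calling
  session is never disturbed.
* Crowding distance uses stable sorts, so duplicated objective values
  are handled deterministically; an all-identical front gets two
  boundary `Inf`s and zero interior distances.
* Hypervolume is exact (staircase) for two objectives and Monte Carlo
  with a fixed seed otherwise; comparisons in tests always share the
  reference point and sample stream, so the paired ratio is meaningful
  even though each estimate is stochastic.
* The texture fractions of a soil must sum to 1 within 1e-9; plans are
  validated gene-by-gene with the offending gene named; empty per-season
  series, empty frontiers, `k > n` and out-of-range seasons raise
  informative errors rather than propagating NAs.
* Profit counts one application event per non-zero mineral dressing plus
  one manure event; a rain delay merges nothing (per-application, not
  per-pass, costing — the cheaper-to-state of the two readings).

# Known limitations

The surrogate's seasons differ only through rain-delay timing noise, so
between-season variance is far smaller than in any process model driven
by real weather; NUE can exceed 1 under zero input (soil mining), which
is realistic but means the EU-panel NUE band cuts the frontier
differently than it would for a model with explicit soil-N depletion;
and absolute profits, emissions and SOC changes are artifacts of the
documented placeholder economics and calibration constants. The
acceptance machinery therefore checks response *shapes*, accounting
*identities*, oracle *equivalence* and structural *configuration* — all
quantities this package itself computes — and nothing else.
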