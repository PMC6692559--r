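Package: agroptim
Title: Multi-Objective Optimization of Agricultural Land Management
Version: 0.1.0
Authors@R: person("agroptim", "maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for exploring trade-offs between production,
    economic and environmental objectives in arable land management. A
    surrogate crop-soil simulator maps fertiliser and manure management
    plans on contrasting soil textures to yield, nitrous oxide emissions,
    nitrogen leaching, soil organic carbon change and nitrogen-budget
    indicators. A hybrid optimizer couples NSGA-II non-dominated sorting
    and crowding selection with differential-evolution variation to trace
    per-soil Pareto frontiers; a second-stage categorical NSGA-II combines
    several soils' frontiers under equal-area mean objectives; Ward
    hierarchical clustering of summarized management genes identifies
    named, profit-ranked management strategies on the frontiers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
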