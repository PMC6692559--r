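#' Pipeline configuration
#'
#' Everything a full run needs; a run is reproducible from the config plus
#' its master seed alone. Serializable to/from JSON with
#' [read_pipeline_config()] / [write_pipeline_config()].
#'
#' @param soils_file soil table path (NULL = packaged three-soil table).
#' @param calibration_file surrogate calibration path (NULL = packaged).
#' @param seed master seed; every component draws a named [sub_seed()].
#' @param n_seasons simulated seasons per evaluation.
#' @param pop_size,n_generations,archive_size,de_F,de_CR,sparse_seed_fraction
#'   stage-1 optimizer settings (see [optimizer_config()]).
#' @param combiner_pop,combiner_generations stage-2 settings.
#' @param cluster_k clusters per soil frontier (single value or named by
#'   soil).
#' @param top_m_profitable clusters flagged as profitable strategies.
#' @param profitable_fraction fraction for the per-point profitable flag.
#' @param economics named list overriding [economic_params()] defaults.
#' @param out_dir artifact directory.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(soils_file = NULL, calibration_file = NULL,
                            seed = 1L, n_seasons = 9L,
                            pop_size = 100L, n_generations = 300L,
                            archive_size = 100L, de_F = 0.8, de_CR = 0.9,
                            sparse_seed_fraction = 0.5,
                            combiner_pop = 1000L, combiner_generations = 50L,
                            cluster_k = 9L, top_m_profitable = 3L,
                            profitable_fraction = 0.3,
                            economics = list(), out_dir = "agroptim_run") {
  structure(list(soils_file = soils_file,
                 calibration_file = calibration_file,
                 seed = as.integer(seed), n_seasons = as.integer(n_seasons),
                 pop_size = as.integer(pop_size),
                 n_generations = as.integer(n_generations),
                 archive_size = as.integer(archive_size),
                 de_F = de_F, de_CR = de_CR,
                 sparse_seed_fraction = sparse_seed_fraction,
                 combiner_pop = as.integer(combiner_pop),
                 combiner_generations = as.integer(combiner_generations),
                 cluster_k = cluster_k,
                 top_m_profitable = as.integer(top_m_profitable),
                 profitable_fraction = profitable_fraction,
                 economics = economics, out_dir = out_dir),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param file JSON config path.
#' @export
read_pipeline_config <- function(file) {
  raw <- jsonlite::read_json(file, simplifyVector = TRUE)
  cfg <- pipeline_config()
  unknown <- setdiff(names(raw), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  for (nm in names(raw)) cfg[[nm]] <- raw[[nm]]
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, file) {
  jsonlite::write_json(unclass(config), file, auto_unbox = TRUE,
                       pretty = TRUE, null = "null", digits = NA)
  invisible(file)
}

validate_pipeline_config <- function(config) {
  if (!inherits(config, "pipeline_config")) stop("not a pipeline_config")
  soils <- tryCatch(load_soils(config),
                    error = function(e) stop("config field 'soils_file': ",
                                             conditionMessage(e)))
  if (!length(soils)) stop("config field 'soils_file': no soils defined")
  if (config$pop_size < 4L) stop("config field 'pop_size': must be >= 4")
  if (config$n_seasons < 1L) stop("config field 'n_seasons': must be >= 1")
  invisible(soils)
}

load_soils <- function(config) {
  if (is.null(config$soils_file)) read_soils() else read_soils(config$soils_file)
}

load_calibration <- function(config) {
  if (is.null(config$calibration_file)) read_calibration()
  else read_calibration(config$calibration_file)
}

config_economics <- function(config) {
  do.call(economic_params, config$economics)
}

#' Default seed plans for the initial population
#'
#' Strategies representing current practice and extremes: a conventional
#' three-split dressing (60/70/60 kg N/ha in slots 3-5), the zero-input
#' plan, and maximal input (all nine rates at 100 kg N/ha plus 3 t/ha FYM).
#'
#' @return list of [management_plan()]s.
#' @export
default_user_seeds <- function() {
  list(management_plan(c(0, 0, 60, 70, 60, 0, 0, 0, 0)),
       management_plan(rep(0, 9)),
       management_plan(rep(100, 9), fym_amount = 3,
                       fym_weeks_before_sowing = 1L))
}

#' Build an evaluator closure for one soil
#'
#' @param soil a [soil_profile()].
#' @param weather a [weather_series()].
#' @param econ an [economic_params()].
#' @param calib calibration list.
#' @return function(genome) -> named objective vector.
#' @export
make_evaluator <- function(soil, weather, econ = economic_params(),
                           calib = read_calibration()) {
  force(soil); force(weather); force(econ); force(calib)
  function(genome) evaluate_plan(plan_from_genome(genome), soil, weather,
                                 econ, calib)
}

#' Optimize management for one soil
#'
#' Convenience wrapper: seeds the initial population (user seeds + sparse
#' members), runs [evolve()] and trims the frontier to the archive size.
#'
#' @param soil a [soil_profile()].
#' @param weather a [weather_series()].
#' @param opt an [optimizer_config()].
#' @param econ an [economic_params()].
#' @param calib calibration list.
#' @param user_seeds list of seed [management_plan()]s.
#' @param log optional function(generation, front_size, hypervolume).
#' @return a trimmed `frontier`.
#' @export
optimize_soil <- function(soil, weather, opt = optimizer_config(),
                          econ = economic_params(),
                          calib = read_calibration(),
                          user_seeds = default_user_seeds(), log = NULL) {
  init <- with_preserved_rng(sub_seed(opt$seed, "init"),
                             seed_initial_population(opt, user_seeds))
  front <- evolve(make_evaluator(soil, weather, econ, calib), plan_bounds(),
                  opt, init = init, log = log)
  trim_frontier(front, opt$archive_size)
}

#' Long-format pairwise projections of a frontier
#'
#' Every unordered pair of objectives, with the point coordinates and
#' optional cluster / profitable labels, plus `minimized_x` / `minimized_y`
#' flags so plots can run minimized axes from right to left.
#'
#' @param objectives objective matrix or a `frontier`.
#' @param labels optional per-point cluster ids.
#' @param profitable optional per-point logical flags.
#' @return data.frame with one row per (pair, point).
#' @export
pairwise_projections <- function(objectives, labels = NULL,
                                 profitable = NULL) {
  if (inherits(objectives, "frontier")) objectives <- objectives$objectives
  obj <- as.matrix(objectives)
  if (ncol(obj) < 2L) stop("need at least two objectives")
  dirs <- objective_directions()
  nm <- colnames(obj)
  n <- nrow(obj)
  pairs <- utils::combn(nm, 2L)
  out <- lapply(seq_len(ncol(pairs)), function(p) {
    ox <- pairs[1L, p]; oy <- pairs[2L, p]
    data.frame(pair = paste(ox, oy, sep = ":"),
               objective_x = ox, objective_y = oy,
               point = seq_len(n), x = obj[, ox], y = obj[, oy],
               minimized_x = isTRUE(unname(dirs[ox] < 0)),
               minimized_y = isTRUE(unname(dirs[oy] < 0)),
               cluster = if (is.null(labels)) NA_integer_ else labels,
               profitable = if (is.null(profitable)) NA else profitable)
  })
  do.call(rbind, out)
}

#' Run the full pipeline
#'
#' Per-soil frontier optimization, stage-2 combination across the soils,
#' per-soil strategy clustering with profit ranking, pairwise projection
#' tables, a machine-readable manifest and a log. All CSV artifacts are
#' deterministic: a rerun with the same config is byte-identical.
#'
#' @param config a [pipeline_config()] or path to its JSON form.
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the in-memory artifacts (`frontiers`,
#'   `combined`, `clusters`, `manifest`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  soils <- validate_pipeline_config(config)
  calib <- load_calibration(config)
  econ <- config_economics(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  log_con <- file(log_path, "w")
  on.exit(close(log_con), add = TRUE)
  say <- function(...) {
    msg <- paste0(...)
    writeLines(msg, log_con)
    if (!quiet) message(msg)
  }

  manifest <- list(package = "agroptim",
                   version = as.character(utils::packageVersion("agroptim")),
                   r_version = paste(R.version$major, R.version$minor,
                                     sep = "."),
                   seed = config$seed,
                   config = unclass(config),
                   stages = list())
  finish_stage <- function(name, status) {
    manifest$stages[[name]] <<- status
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null",
                         digits = NA)
  }

  weather <- weather_series(n_seasons = config$n_seasons,
                            seed = sub_seed(config$seed, "weather"))
  frontiers <- list()
  clusters <- list()
  run_stage <- function(name, code) {
    finish_stage(name, "running")
    ok <- tryCatch({ force(code); TRUE },
                   error = function(e) {
                     finish_stage(name, paste0("failed: ",
                                               conditionMessage(e)))
                     stop("stage '", name, "' failed: ",
                          conditionMessage(e), call. = FALSE)
                   })
    finish_stage(name, "complete")
  }

  for (soil_name in names(soils)) {
    run_stage(paste0("optimize-", soil_name), {
      soil <- soils[[soil_name]]
      opt <- optimizer_config(
        pop_size = config$pop_size, n_generations = config$n_generations,
        de_F = config$de_F, de_CR = config$de_CR,
        seed = sub_seed(config$seed, paste0("soil-", soil_name)),
        archive_size = config$archive_size,
        sparse_seed_fraction = config$sparse_seed_fraction,
        hv_every = max(1L, config$n_generations %/% 20L))
      say("optimizing ", soil_name, ": pop ", opt$pop_size, ", ",
          opt$n_generations, " generations")
      front <- optimize_soil(soil, weather, opt, econ, calib,
                             log = function(gen, fs, hv)
                               say(sprintf("  [%s] gen %d front %d hv %.4g",
                                           soil_name, gen, fs, hv)))
      frontiers[[soil_name]] <- front
      write_frontier(front, file.path(config$out_dir,
                                      paste0("frontier_", soil_name, ".csv")))
      say("  frontier for ", soil_name, ": ", frontier_size(front),
          " points")
    })
  }

  combined <- NULL
  run_stage("combine", {
    say("combining ", length(frontiers), " frontiers (",
        format(combination_count(frontiers), big.mark = ","),
        " possible combinations)")
    combined <- run_combiner(frontiers, combiner_config(
      pop_size = config$combiner_pop,
      n_generations = config$combiner_generations,
      seed = sub_seed(config$seed, "combiner")))
    write_combined_frontier(combined,
                            file.path(config$out_dir,
                                      "combined_frontier.csv"))
    say("  combined frontier: ", nrow(combined$indices), " assignments")
  })

  run_stage("cluster", {
    for (soil_name in names(frontiers)) {
      front <- frontiers[[soil_name]]
      k <- cluster_k_for(config$cluster_k, soil_name)
      k <- min(k, frontier_size(front))
      feats <- strategy_features(front)
      res <- cluster_strategies(feats, k)
      profits <- front$objectives[, "profit"]
      ranking <- rank_clusters_by_profit(res, profits,
                                         config$top_m_profitable)
      flags <- flag_profitable_points(profits, config$profitable_fraction)
      clusters[[soil_name]] <- list(result = res, ranking = ranking,
                                     profitable = flags)
      utils::write.csv(
        data.frame(point = seq_along(res$labels), cluster = res$labels,
                   profitable_point = flags,
                   profitable_cluster = res$labels %in%
                     ranking$profitable_cluster_ids),
        file.path(config$out_dir, paste0("clusters_", soil_name, ".csv")),
        row.names = FALSE)
      utils::write.csv(
        data.frame(cluster = seq_len(res$k),
                   n_points = tabulate(res$labels, res$k),
                   mean_profit = ranking$mean_profit,
                   rank = order(ranking$order),
                   profitable = seq_len(res$k) %in%
                     ranking$profitable_cluster_ids),
        file.path(config$out_dir,
                  paste0("cluster_summary_", soil_name, ".csv")),
        row.names = FALSE)
      utils::write.csv(cluster_histograms(res),
                       file.path(config$out_dir,
                                 paste0("histograms_", soil_name, ".csv")),
                       row.names = FALSE)
      say("  clustered ", soil_name, " into ", res$k, " strategies; ",
          "profitable clusters: ",
          paste(ranking$profitable_cluster_ids, collapse = ", "))
    }
  })

  run_stage("report", {
    for (soil_name in names(frontiers)) {
      cl <- clusters[[soil_name]]
      utils::write.csv(
        pairwise_projections(frontiers[[soil_name]],
                             labels = cl$result$labels,
                             profitable = cl$profitable),
        file.path(config$out_dir,
                  paste0("projections_", soil_name, ".csv")),
        row.names = FALSE)
    }
    utils::write.csv(pairwise_projections(combined$objectives),
                     file.path(config$out_dir, "projections_combined.csv"),
                     row.names = FALSE)
    say("wrote projection tables")
  })

  invisible(list(frontiers = frontiers, combined = combined,
                 clusters = clusters, manifest = manifest))
}

cluster_k_for <- function(cluster_k, soil_name) {
  if (length(cluster_k) == 1L && is.null(names(cluster_k)))
    return(as.integer(cluster_k))
  if (!is.null(names(cluster_k)) && soil_name %in% names(cluster_k))
    return(as.integer(cluster_k[[soil_name]]))
  as.integer(cluster_k[[1L]])
}
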