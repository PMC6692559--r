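#' Optimizer configuration
#'
#' Settings for the hybrid NSGA-II / differential-evolution engine.
#' Defaults follow the package's standard run: the generation budget is
#' 1500 with convergence otherwise judged by the optional
#' hypervolume-stagnation early stop.
#'
#' @param pop_size population size (>= 4; differential evolution needs three
#'   distinct donors plus the target).
#' @param n_generations generation budget.
#' @param de_F differential weight F of the rand/1/bin scheme.
#' @param de_CR crossover rate CR.
#' @param seed integer seed for the engine's RNG stream.
#' @param archive_size frontier size handed to the second stage.
#' @param sparse_seed_fraction fraction (<= 0.5) of the initial population
#'   seeded with sparse fertiliser plans (6-8 zero N genes).
#' @param hv_every log hypervolume every this many generations (0 = off).
#' @param hv_ref reference point for hypervolume logging (named like the
#'   objectives); NULL picks a point slightly worse than the first
#'   generation's worst values.
#' @param stagnation_window,stagnation_tol early stop when the logged
#'   hypervolume improves by less than `stagnation_tol` (relative) over
#'   `stagnation_window` consecutive logs (window 0 disables; requires
#'   `hv_every > 0`).
#' @return list of class `optimizer_config`.
#' @export
optimizer_config <- function(pop_size = 100L, n_generations = 1500L,
                             de_F = 0.8, de_CR = 0.9, seed = 1L,
                             archive_size = 100L,
                             sparse_seed_fraction = 0.5,
                             hv_every = 0L, hv_ref = NULL,
                             stagnation_window = 0L,
                             stagnation_tol = 1e-4) {
  if (pop_size < 4L) stop("pop_size must be >= 4")
  if (sparse_seed_fraction < 0 || sparse_seed_fraction > 0.5)
    stop("sparse_seed_fraction must be in [0, 0.5]")
  structure(list(pop_size = as.integer(pop_size),
                 n_generations = as.integer(n_generations),
                 de_F = de_F, de_CR = de_CR, seed = as.integer(seed),
                 archive_size = as.integer(archive_size),
                 sparse_seed_fraction = sparse_seed_fraction,
                 hv_every = as.integer(hv_every), hv_ref = hv_ref,
                 stagnation_window = as.integer(stagnation_window),
                 stagnation_tol = stagnation_tol),
            class = "optimizer_config")
}

#' Pareto dominance
#'
#' Direction-aware standard dominance: `a` dominates `b` iff `a` is no
#' worse than `b` in every objective and strictly better in at least one.
#'
#' @param a,b numeric objective vectors of equal length.
#' @param directions `+1`/`-1` per objective (maximize / minimize).
#' @return logical.
#' @export
dominates <- function(a, b, directions = objective_directions()) {
  if (length(a) != length(b) || length(a) != length(directions))
    stop("objective vectors and directions must have equal length")
  da <- directions * a
  db <- directions * b
  all(da >= db) && any(da > db)
}

#' Fast non-dominated sorting
#'
#' Partitions a population's objective matrix into fronts F1, F2, ...:
#' every member of F1 is undominated in the population and each later
#' front's members are dominated only by earlier fronts. Vectorized
#' dominance-matrix formulation of the NSGA-II sort.
#'
#' @param obj numeric matrix, one row per individual, one column per
#'   objective.
#' @param directions `+1`/`-1` per objective.
#' @return list with `fronts` (list of integer index vectors) and `rank`
#'   (0-based integer vector: 0 = non-dominated).
#' @export
nd_sort <- function(obj, directions = objective_directions()) {
  obj <- as.matrix(obj)
  n <- nrow(obj)
  if (!n) stop("empty population")
  if (ncol(obj) != length(directions))
    stop("objective count does not match directions")
  o <- sweep(obj, 2L, directions, `*`)
  ge <- matrix(TRUE, n, n)
  gt <- matrix(FALSE, n, n)
  for (k in seq_len(ncol(o))) {
    ok <- o[, k]
    cmp <- outer(ok, ok, `-`)
    ge <- ge & (cmp >= 0)
    gt <- gt | (cmp > 0)
  }
  dom <- ge & gt                     # dom[i, j]: i dominates j
  n_dom <- colSums(dom)              # how many dominate j
  rank <- integer(n)
  assigned <- logical(n)
  fronts <- list()
  r <- 0L
  while (!all(assigned)) {
    front <- which(!assigned & n_dom == 0)
    if (!length(front)) stop("internal error: dominance cycle")
    rank[front] <- r
    assigned[front] <- TRUE
    fronts[[r + 1L]] <- front
    n_dom <- n_dom - colSums(dom[front, , drop = FALSE])
    r <- r + 1L
  }
  list(fronts = fronts, rank = rank)
}

#' Crowding distance of one front
#'
#' Per objective, boundary individuals receive `+Inf`; interior individuals
#' accumulate the normalized gap between their neighbours in the sorted
#' order. Objectives with zero range contribute nothing. Ties are resolved
#' by stable sorting, so the result is deterministic in input order.
#'
#' @param obj objective matrix of the front's members.
#' @return numeric vector of crowding distances.
#' @export
crowding_distance <- function(obj) {
  obj <- as.matrix(obj)
  n <- nrow(obj)
  if (!n) stop("empty front")
  d <- numeric(n)
  for (k in seq_len(ncol(obj))) {
    v <- obj[, k]
    ord <- order(v)                  # stable
    d[ord[1L]] <- Inf
    d[ord[n]] <- Inf
    rng <- v[ord[n]] - v[ord[1L]]
    if (n > 2L && rng > 0) {
      mid <- ord[2:(n - 1L)]
      d[mid] <- d[mid] + (v[ord[3:n]] - v[ord[1:(n - 2L)]]) / rng
    }
  }
  d
}

#' Differential-evolution trial genome (rand/1/bin)
#'
#' Donor `x_r1 + F * (x_r2 - x_r3)` from three distinct members different
#' from the target, binomial crossover at rate CR with one guaranteed donor
#' gene, then bound repair: clip to the box and round integer genes.
#' Consumes the session RNG stream.
#'
#' @param i target row index.
#' @param genomes population genome matrix.
#' @param de_F,de_CR DE parameters.
#' @param bounds list with `lower`, `upper`, `integer` (see [plan_bounds()]).
#' @return trial genome vector.
#' @export
de_trial <- function(i, genomes, de_F, de_CR, bounds) {
  n <- nrow(genomes)
  if (n < 4L) stop("differential evolution needs a population of >= 4")
  r <- sample(setdiff(seq_len(n), i), 3L)
  donor <- genomes[r[1L], ] + de_F * (genomes[r[2L], ] - genomes[r[3L], ])
  d <- ncol(genomes)
  cross <- stats::runif(d) < de_CR
  cross[sample.int(d, 1L)] <- TRUE
  trial <- ifelse(cross, donor, genomes[i, ])
  repair_genome(trial, bounds)
}

repair_genome <- function(g, bounds) {
  g <- pmin(pmax(g, bounds$lower), bounds$upper)
  g[bounds$integer] <- round(g[bounds$integer])
  g
}

#' Seed the initial population of management genomes
#'
#' User-supplied plans (current practice, extremes) come first; then a
#' fraction of sparse members, each with a uniformly chosen 6, 7 or 8 of
#' the nine N genes set to zero (remaining rates uniform on the rate
#' bounds); the rest fully random. Sparse seeding mirrors the expectation
#' that optimal plans use few applications, which uniform sampling would
#' essentially never propose. Consumes the session RNG stream.
#'
#' @param config an [optimizer_config()].
#' @param user_seeds list of [management_plan()]s (validated; must respect
#'   bounds).
#' @param bounds genome bounds, [plan_bounds()] by default.
#' @return genome matrix `pop_size x 11`.
#' @export
seed_initial_population <- function(config, user_seeds = list(),
                                    bounds = plan_bounds()) {
  pop <- config$pop_size
  if (length(user_seeds) > pop)
    stop("more user seeds than population slots")
  seeds <- lapply(user_seeds, function(p) plan_genome(validate_plan(p)))
  n_sparse <- min(floor(config$sparse_seed_fraction * pop),
                  pop - length(seeds))
  n_rand <- pop - length(seeds) - n_sparse
  rand_genome <- function() {
    g <- stats::runif(length(bounds$lower), bounds$lower, bounds$upper)
    repair_genome(g, bounds)
  }
  sparse_genome <- function() {
    g <- rand_genome()
    nz <- sample(6:8, 1L)
    g[sample.int(9L, nz)] <- 0
    g
  }
  rows <- c(seeds,
            replicate(n_sparse, sparse_genome(), simplify = FALSE),
            replicate(n_rand, rand_genome(), simplify = FALSE))
  m <- do.call(rbind, rows)
  colnames(m) <- bounds$names
  m
}

# NSGA-II environmental selection: keep `size` rows from pooled objectives.
nsga2_select <- function(obj, directions, size) {
  srt <- nd_sort(obj, directions)
  keep <- integer(0)
  for (front in srt$fronts) {
    if (length(keep) + length(front) <= size) {
      keep <- c(keep, front)
    } else {
      cd <- crowding_distance(obj[front, , drop = FALSE])
      take <- front[order(-cd)][seq_len(size - length(keep))]
      keep <- c(keep, take)
      break
    }
  }
  keep
}

#' Evolve a Pareto frontier with hybrid NSGA-II / differential evolution
#'
#' Generational loop: a rand/1/bin trial is built for every member, trials
#' are evaluated, parents and trials are pooled, and NSGA-II non-dominated
#' sorting with crowding truncation selects the next population. After the
#' generation budget (or hypervolume stagnation, if enabled) the rank-0 set
#' is returned as a [frontier]. An evaluation error is logged and the
#' member is assigned the worst possible objectives.
#'
#' @param evaluate function(genome) -> named numeric objective vector;
#'   must be deterministic.
#' @param bounds genome box bounds (see [plan_bounds()]).
#' @param config an [optimizer_config()].
#' @param directions objective directions; defaults to the package's six.
#' @param init optional initial genome matrix (e.g. from
#'   [seed_initial_population()]); uniform random within bounds otherwise.
#' @param log optional function(generation, front_size, hypervolume) used
#'   for per-generation progress records.
#' @return object of class `frontier`: list with `genomes`, `objectives`,
#'   `directions`, `crowding`, and the hypervolume log `hv_log`.
#' @export
evolve <- function(evaluate, bounds, config, directions = objective_directions(),
                   init = NULL, log = NULL) {
  with_preserved_rng(config$seed, {
    pop <- config$pop_size
    d <- length(bounds$lower)
    if (is.null(init)) {
      init <- do.call(rbind, lapply(seq_len(pop), function(i)
        repair_genome(stats::runif(d, bounds$lower, bounds$upper), bounds)))
      colnames(init) <- bounds$names
    }
    if (nrow(init) != pop) stop("init must have pop_size rows")
    genomes <- init
    obj <- eval_rows(genomes, evaluate, directions)
    hv_log <- data.frame(generation = integer(), front_size = integer(),
                         hypervolume = numeric())
    hv_ref <- config$hv_ref
    if (config$hv_every > 0L && is.null(hv_ref)) {
      worst <- apply(sweep(obj, 2L, directions, `*`), 2L, min)
      hv_ref <- directions * (worst - 0.05 * pmax(abs(worst), 1))
    }
    for (gen in seq_len(config$n_generations)) {
      trials <- do.call(rbind, lapply(seq_len(pop), function(i)
        de_trial(i, genomes, config$de_F, config$de_CR, bounds)))
      tobj <- eval_rows(trials, evaluate, directions)
      pool_g <- rbind(genomes, trials)
      pool_o <- rbind(obj, tobj)
      keep <- nsga2_select(pool_o, directions, pop)
      genomes <- pool_g[keep, , drop = FALSE]
      obj <- pool_o[keep, , drop = FALSE]
      if (config$hv_every > 0L && gen %% config$hv_every == 0L) {
        srt <- nd_sort(obj, directions)
        f0 <- srt$fronts[[1L]]
        hv <- hypervolume(obj[f0, , drop = FALSE], directions, hv_ref,
                          nsamples = 2000L, seed = config$seed + gen)
        hv_log <- rbind(hv_log, data.frame(
          generation = gen, front_size = length(f0), hypervolume = hv))
        if (!is.null(log)) log(gen, length(f0), hv)
        w <- config$stagnation_window
        if (w > 0L && nrow(hv_log) > w) {
          prev <- hv_log$hypervolume[nrow(hv_log) - w]
          if (is.finite(prev) && prev > 0 &&
              (hv - prev) / prev < config$stagnation_tol) break
        }
      }
    }
    srt <- nd_sort(obj, directions)
    f0 <- srt$fronts[[1L]]
    new_frontier(genomes[f0, , drop = FALSE], obj[f0, , drop = FALSE],
                 directions, hv_log)
  })
}

eval_rows <- function(genomes, evaluate, directions) {
  out <- do.call(rbind, lapply(seq_len(nrow(genomes)), function(i)
    safe_eval(evaluate, genomes[i, ], directions)))
  colnames(out) <- names(directions)
  out
}

safe_eval <- function(evaluate, genome, directions) {
  out <- tryCatch(evaluate(genome), error = function(e) {
    message("evaluation failed (", conditionMessage(e),
            "); assigning worst objectives")
    NULL
  })
  if (is.null(out) || any(!is.finite(out))) {
    out <- -directions * 1e12      # worst value in every direction
    names(out) <- names(directions)
  }
  out
}

#' Construct a frontier from genomes and objectives
#'
#' Duplicate genomes are dropped. The points are expected to be mutually
#' non-dominated (as produced by [evolve()] or an exhaustive filter); set
#' `check = TRUE` to verify.
#'
#' @param genomes matrix, one genome per row.
#' @param objectives matrix, one named objective row per genome.
#' @param directions `+1`/`-1` per objective.
#' @param check verify mutual non-domination.
#' @return object of class `frontier`.
#' @export
frontier <- function(genomes, objectives, directions = objective_directions(),
                     check = FALSE) {
  genomes <- as.matrix(genomes)
  objectives <- as.matrix(objectives)
  if (nrow(genomes) != nrow(objectives))
    stop("genomes and objectives must have the same number of rows")
  if (check) {
    srt <- nd_sort(objectives, directions)
    if (length(srt$fronts) > 1L)
      stop("points are not mutually non-dominated")
  }
  new_frontier(genomes, objectives, directions)
}

new_frontier <- function(genomes, objectives, directions, hv_log = NULL) {
  dedup <- !duplicated(genomes)
  genomes <- genomes[dedup, , drop = FALSE]
  objectives <- objectives[dedup, , drop = FALSE]
  structure(list(genomes = genomes, objectives = objectives,
                 directions = directions,
                 crowding = crowding_distance(objectives),
                 hv_log = hv_log),
            class = "frontier")
}

#' @export
print.frontier <- function(x, ...) {
  cat(sprintf("<frontier> %d mutually non-dominated points, %d objectives\n",
              nrow(x$objectives), ncol(x$objectives)))
  invisible(x)
}

#' Number of points on a frontier
#' @param x a `frontier`.
#' @return integer count.
#' @export
frontier_size <- function(x) nrow(x$objectives)

#' Trim a frontier to an archive size by crowding
#'
#' Iteratively drops the point with the lowest crowding distance until
#' `archive_size` points remain. Boundary points (infinite crowding) are
#' never dropped while more points than boundary points remain; once only
#' boundary points are left, the highest row index is dropped (stable,
#' documented tie rule).
#'
#' @param frontier a `frontier`.
#' @param archive_size target size.
#' @return trimmed `frontier`.
#' @export
trim_frontier <- function(frontier, archive_size) {
  g <- frontier$genomes
  o <- frontier$objectives
  while (nrow(o) > archive_size) {
    cd <- crowding_distance(o)
    fin <- which(is.finite(cd))
    drop <- if (length(fin)) fin[which.min(cd[fin])] else nrow(o)
    g <- g[-drop, , drop = FALSE]
    o <- o[-drop, , drop = FALSE]
  }
  new_frontier(g, o, frontier$directions, frontier$hv_log)
}

#' Hypervolume of a point set
#'
#' Volume of objective space dominated by the set relative to a reference
#' point (in original units; the reference must be weakly worse than every
#' point counted). Two objectives use the exact staircase sum; more use
#' Monte Carlo sampling of the box between the reference and the
#' componentwise ideal, with a fixed seed for reproducibility.
#'
#' @param obj objective matrix (rows = points).
#' @param directions `+1`/`-1` per objective.
#' @param ref reference point, original units.
#' @param nsamples Monte Carlo samples (ignored for 2 objectives).
#' @param seed Monte Carlo seed.
#' @return hypervolume (original units' product scale).
#' @export
hypervolume <- function(obj, directions, ref, nsamples = 20000L, seed = 1L) {
  obj <- as.matrix(obj)
  v <- sweep(obj, 2L, directions, `*`)       # maximize all
  r <- directions * ref
  keep <- apply(v, 1L, function(p) all(p >= r))
  v <- v[keep, , drop = FALSE]
  if (!nrow(v)) return(0)
  if (ncol(v) == 2L) {
    ord <- order(-v[, 1L], -v[, 2L])
    v <- v[ord, , drop = FALSE]
    best2 <- r[2L]
    hv <- 0
    for (i in seq_len(nrow(v))) {
      if (v[i, 2L] > best2) {
        hv <- hv + (v[i, 1L] - r[1L]) * (v[i, 2L] - best2)
        best2 <- v[i, 2L]
      }
    }
    return(hv)
  }
  ideal <- apply(v, 2L, max)
  widths <- ideal - r
  if (any(widths <= 0)) return(0)
  with_preserved_rng(seed, {
    m <- length(r)
    s <- matrix(stats::runif(nsamples * m), nsamples, m)
    s <- sweep(sweep(s, 2L, widths, `*`), 2L, r, `+`)
    hit <- rep(FALSE, nsamples)
    for (i in seq_len(nrow(v))) {
      cand <- which(!hit)
      if (!length(cand)) break
      dom <- rep(TRUE, length(cand))
      for (k in seq_len(m))
        dom <- dom & (v[i, k] >= s[cand, k])
      hit[cand[dom]] <- TRUE
    }
    mean(hit) * prod(widths)
  })
}

#' Write / read a frontier as CSV
#'
#' One row per point: genome columns, objective columns (prefixed
#' `obj_`), rank and crowding. Rows are ordered lexicographically by the
#' objective columns so output is deterministic.
#'
#' @param frontier a `frontier`.
#' @param file path.
#' @return `write_frontier`: the path, invisibly. `read_frontier`: a
#'   `frontier`.
#' @export
write_frontier <- function(frontier, file) {
  df <- as.data.frame(frontier)
  ord <- do.call(order, as.list(df[, grep("^obj_", names(df)), drop = FALSE]))
  utils::write.csv(df[ord, , drop = FALSE], file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_frontier
#' @param directions objective directions matching the stored columns.
#' @export
read_frontier <- function(file, directions = objective_directions()) {
  df <- utils::read.csv(file)
  oc <- grep("^obj_", names(df))
  obj <- as.matrix(df[, oc, drop = FALSE])
  colnames(obj) <- sub("^obj_", "", colnames(obj))
  gcols <- setdiff(names(df), c(names(df)[oc], "rank", "crowding"))
  new_frontier(as.matrix(df[, gcols, drop = FALSE]), obj, directions)
}

#' @export
as.data.frame.frontier <- function(x, ...) {
  obj <- x$objectives
  colnames(obj) <- paste0("obj_", colnames(obj))
  data.frame(x$genomes, obj, rank = 0L, crowding = x$crowding,
             check.names = FALSE)
}
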