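#' Equal-area mean combination of per-unit objective vectors
#'
#' With equal areas of each land unit, landscape objectives are the
#' elementwise arithmetic means of the per-unit objective vectors.
#'
#' @param points matrix (one row per unit) or list of equally named
#'   objective vectors.
#' @return combined named objective vector.
#' @export
mean_combine <- function(points) {
  if (is.list(points) && !is.data.frame(points)) {
    nm <- lapply(points, names)
    if (length(unique(vapply(nm, paste, "", collapse = ","))) != 1L)
      stop("objective vectors must share the same objective set")
    points <- do.call(rbind, points)
  }
  points <- as.matrix(points)
  colMeans(points)
}

#' Number of stage-2 combinations
#'
#' Product of the per-unit frontier sizes: the size of the categorical
#' search space the combiner explores (three 100-point frontiers give a
#' million combinations).
#'
#' @param frontiers list of `frontier` objects.
#' @return numeric count.
#' @export
combination_count <- function(frontiers) {
  prod(vapply(frontiers, frontier_size, numeric(1)))
}

#' Exhaustively combine frontiers (oracle)
#'
#' Enumerates the full Cartesian product of per-unit frontier indices,
#' mean-combines each assignment and returns the exact non-dominated set.
#' Refuses when the product exceeds `cap`.
#'
#' @param frontiers list of >= 1 non-empty `frontier` objects sharing one
#'   objective set.
#' @param cap maximum product size enumerated (default 1e6).
#' @return object of class `combined_frontier`: list with `indices`
#'   (matrix, one column per unit), `objectives`, `directions` and
#'   `n_combinations`.
#' @export
brute_force_combine <- function(frontiers, cap = 1e6) {
  check_frontiers(frontiers)
  size <- combination_count(frontiers)
  if (size > cap)
    stop("product size ", format(size, big.mark = ","),
         " exceeds the enumeration cap of ", format(cap, big.mark = ","))
  grid <- as.matrix(expand.grid(lapply(frontiers, function(f)
    seq_len(frontier_size(f)))))
  colnames(grid) <- paste0("unit", seq_along(frontiers))
  obj <- combined_objectives(grid, frontiers)
  dirs <- frontiers[[1L]]$directions
  srt <- nd_sort(obj, dirs)
  f0 <- srt$fronts[[1L]]
  structure(list(indices = grid[f0, , drop = FALSE],
                 objectives = obj[f0, , drop = FALSE],
                 directions = dirs, n_combinations = size),
            class = "combined_frontier")
}

check_frontiers <- function(frontiers) {
  if (!length(frontiers)) stop("need at least one frontier")
  for (f in frontiers) {
    if (!inherits(f, "frontier")) stop("inputs must be frontier objects")
    if (!frontier_size(f)) stop("empty frontier")
  }
  nm <- vapply(frontiers, function(f)
    paste(colnames(f$objectives), collapse = ","), "")
  if (length(unique(nm)) != 1L)
    stop("frontiers must share the same objective set")
  invisible(frontiers)
}

combined_objectives <- function(indices, frontiers) {
  acc <- 0
  for (u in seq_along(frontiers))
    acc <- acc + frontiers[[u]]$objectives[indices[, u], , drop = FALSE]
  acc / length(frontiers)
}

#' Combiner configuration
#'
#' @param pop_size genetic population (default 1000, chosen to represent
#'   the combined frontier's more complex surface well).
#' @param n_generations stage-2 generation budget.
#' @param p_crossover per-mating probability of uniform crossover.
#' @param mutation_rate per-gene probability of a random index reset;
#'   NULL means `1 / n_units`.
#' @param seed RNG seed.
#' @return list of class `combiner_config`.
#' @export
combiner_config <- function(pop_size = 1000L, n_generations = 50L,
                            p_crossover = 0.9, mutation_rate = NULL,
                            seed = 1L) {
  structure(list(pop_size = as.integer(pop_size),
                 n_generations = as.integer(n_generations),
                 p_crossover = p_crossover, mutation_rate = mutation_rate,
                 seed = as.integer(seed)),
            class = "combiner_config")
}

#' Combine per-unit frontiers with categorical NSGA-II
#'
#' Stage-2 search: one integer control variable per land unit indexes a
#' point on that unit's frontier; combined objectives are equal-area
#' means. Because indices are categorical (no gradient between frontier
#' points), variation is uniform crossover plus random-reset mutation
#' rather than differential evolution. Binary tournaments on
#' (rank, crowding) pick parents; parents and offspring are pooled and
#' truncated by non-dominated sorting and crowding each generation.
#' Duplicate assignments may coexist in the population; the reported
#' frontier is deduplicated.
#'
#' A single land unit needs no search: its own frontier is returned
#' unchanged as assignments.
#'
#' @param frontiers list of non-empty `frontier` objects.
#' @param config a [combiner_config()].
#' @return a `combined_frontier` (see [brute_force_combine()]).
#' @export
run_combiner <- function(frontiers, config = combiner_config()) {
  check_frontiers(frontiers)
  dirs <- frontiers[[1L]]$directions
  sizes <- vapply(frontiers, frontier_size, integer(1))
  u <- length(frontiers)
  if (u == 1L) {
    idx <- matrix(seq_len(sizes[1L]), ncol = 1L,
                  dimnames = list(NULL, "unit1"))
    return(structure(list(indices = idx,
                          objectives = frontiers[[1L]]$objectives,
                          directions = dirs,
                          n_combinations = sizes[1L]),
                     class = "combined_frontier"))
  }
  mut <- if (is.null(config$mutation_rate)) 1 / u else config$mutation_rate
  with_preserved_rng(config$seed, {
    n <- config$pop_size
    pop <- vapply(sizes, function(s) sample.int(s, n, replace = TRUE),
                  integer(n))
    obj <- combined_objectives(pop, frontiers)
    for (gen in seq_len(config$n_generations)) {
      srt <- nd_sort(obj, dirs)
      cd <- numeric(n)
      for (front in srt$fronts)
        cd[front] <- crowding_distance(obj[front, , drop = FALSE])
      pick <- function(k) {
        a <- sample.int(n, k, replace = TRUE)
        b <- sample.int(n, k, replace = TRUE)
        better <- srt$rank[a] < srt$rank[b] |
          (srt$rank[a] == srt$rank[b] & cd[a] >= cd[b])
        ifelse(better, a, b)
      }
      p1 <- pop[pick(n), , drop = FALSE]
      p2 <- pop[pick(n), , drop = FALSE]
      do_cx <- stats::runif(n) < config$p_crossover
      swap <- matrix(stats::runif(n * u) < 0.5, n, u) & do_cx
      child <- ifelse(swap, p2, p1)
      mut_mask <- matrix(stats::runif(n * u) < mut, n, u)
      if (any(mut_mask)) {
        for (col in seq_len(u)) {
          hit <- which(mut_mask[, col])
          if (length(hit))
            child[hit, col] <- sample.int(sizes[col], length(hit),
                                          replace = TRUE)
        }
      }
      cobj <- combined_objectives(child, frontiers)
      pool <- rbind(pop, child)
      pobj <- rbind(obj, cobj)
      keep <- nsga2_select(pobj, dirs, n)
      pop <- pool[keep, , drop = FALSE]
      obj <- pobj[keep, , drop = FALSE]
    }
    srt <- nd_sort(obj, dirs)
    f0 <- srt$fronts[[1L]]
    idx <- pop[f0, , drop = FALSE]
    dedup <- !duplicated(idx)
    colnames(idx) <- paste0("unit", seq_len(u))
    structure(list(indices = idx[dedup, , drop = FALSE],
                   objectives = obj[f0, , drop = FALSE][dedup, , drop = FALSE],
                   directions = dirs,
                   n_combinations = prod(sizes)),
              class = "combined_frontier")
  })
}

#' @export
print.combined_frontier <- function(x, ...) {
  cat(sprintf(
    "<combined_frontier> %d assignments over %d units (%s combinations searched)\n",
    nrow(x$indices), ncol(x$indices),
    format(x$n_combinations, big.mark = ",")))
  invisible(x)
}

#' Write a combined frontier as CSV
#'
#' Per-unit index columns plus combined objective columns (prefixed
#' `obj_`), rows ordered lexicographically by objectives.
#'
#' @param cf a `combined_frontier`.
#' @param file path.
#' @return the path, invisibly.
#' @export
write_combined_frontier <- function(cf, file) {
  obj <- cf$objectives
  colnames(obj) <- paste0("obj_", colnames(obj))
  df <- data.frame(cf$indices, obj, check.names = FALSE)
  ord <- do.call(order, as.list(df[, grep("^obj_", names(df)), drop = FALSE]))
  utils::write.csv(df[ord, , drop = FALSE], file, row.names = FALSE)
  invisible(file)
}
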