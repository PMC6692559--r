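#' Summarize a management plan into strategy features
#'
#' The nine fertiliser genes are summarized into three values — total N
#' applied, number of non-zero applications, and the slot index (1-9) of
#' the first non-zero application — joined by the FYM amount. Plans with
#' no fertiliser get the sentinel first-application week 10 (one past the
#' last possible date) so the feature stays numeric. FYM timing is not a
#' clustering feature.
#'
#' @param plan a [management_plan()].
#' @return named numeric vector `(total_n, n_apps, first_app_week,
#'   fym_amount)`.
#' @export
summarize_plan <- function(plan) {
  validate_plan(plan)
  nz <- which(plan$n_rates > 0)
  c(total_n = sum(plan$n_rates),
    n_apps = length(nz),
    first_app_week = if (length(nz)) nz[1L] else 10,
    fym_amount = plan$fym_amount)
}

#' Strategy features of every point on a frontier
#'
#' @param frontier a `frontier` whose genomes are management genomes.
#' @return matrix, one row per point, columns as in [summarize_plan()].
#' @export
strategy_features <- function(frontier) {
  t(apply(frontier$genomes, 1L, function(g) summarize_plan(plan_from_genome(g))))
}

#' Ward clustering of strategy features
#'
#' Features are standardized per dimension (divided by the sample standard
#' deviation; zero-variance dimensions are dropped with a warning), Ward
#' minimum-variance linkage is built on the standardized Euclidean
#' distance, and the tree is cut into exactly `k` clusters. Deterministic
#' given input order (`hclust`'s tie handling is stable).
#'
#' @param features numeric matrix, one row per point.
#' @param k number of clusters (1 <= k <= n). The choice is the user's
#'   (typically by inspecting the dendrogram); [suggest_k()] reports a
#'   merge-height-gap suggestion but nothing is auto-selected.
#' @return object of class `cluster_result`: list with `labels`, `k`,
#'   `linkage` (an `hclust`), `features`, `dropped` (zero-variance
#'   columns).
#' @export
cluster_strategies <- function(features, k) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (k < 1L || k > n) stop("k must be between 1 and the number of points")
  sds <- apply(features, 2L, stats::sd)
  drop <- which(sds == 0 | is.na(sds))
  if (length(drop) == ncol(features))
    stop("all features have zero variance; nothing to cluster")
  if (length(drop))
    warning("dropping zero-variance feature(s): ",
            paste(colnames(features)[drop], collapse = ", "))
  use <- if (length(drop)) features[, -drop, drop = FALSE] else features
  x <- sweep(use, 2L, apply(use, 2L, stats::sd), `/`)
  hc <- stats::hclust(stats::dist(x), method = "ward.D2")
  labels <- stats::cutree(hc, k = k)
  structure(list(labels = labels, k = as.integer(k), linkage = hc,
                 features = features, dropped = drop),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d points in %d clusters (sizes: %s)\n",
              length(x$labels), x$k,
              paste(tabulate(x$labels, x$k), collapse = ", ")))
  invisible(x)
}

#' Suggest a cluster count from the dendrogram
#'
#' Returns the cut that precedes the largest gap in merge heights (among
#' cuts from 2 to `k_max`) — a numeric rendering of "look for the tall
#' stem in the dendrogram". Advisory only.
#'
#' @param result a `cluster_result`.
#' @param k_max largest k considered.
#' @return integer suggestion.
#' @export
suggest_k <- function(result, k_max = 12L) {
  h <- rev(result$linkage$height)      # tallest merge first
  k_max <- min(k_max, length(h))
  if (k_max < 2L) return(1L)
  gaps <- h[seq_len(k_max - 1L)] - h[2:k_max]
  which.max(gaps) + 1L
}

#' Rank clusters by mean profitability
#'
#' @param result a `cluster_result`.
#' @param profits per-point profit vector aligned with the labels.
#' @param top_m how many clusters to flag as "profitable strategies"
#'   (2-3 in a typical per-soil analysis).
#' @return list: `order` (cluster ids, most profitable first),
#'   `mean_profit` (named by cluster id), `profitable_cluster_ids`.
#' @export
rank_clusters_by_profit <- function(result, profits, top_m = 3L) {
  if (length(profits) != length(result$labels))
    stop("profits must align with cluster labels")
  mp <- vapply(seq_len(result$k), function(cl)
    mean(profits[result$labels == cl]), numeric(1))
  names(mp) <- seq_len(result$k)
  ord <- order(-mp)
  list(order = ord, mean_profit = mp,
       profitable_cluster_ids = ord[seq_len(min(top_m, result$k))])
}

#' Flag the most profitable fraction of points
#'
#' TRUE for the `ceiling(fraction * n)` highest-profit points. Ties are
#' broken by stable order: among equal profits, earlier points win.
#'
#' @param profits per-point profits.
#' @param fraction fraction in (0, 1]; default 0.3 (the "30% most
#'   profitable" rule).
#' @return logical vector.
#' @export
flag_profitable_points <- function(profits, fraction = 0.3) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  n <- length(profits)
  m <- ceiling(fraction * n)
  flag <- logical(n)
  flag[order(-profits)[seq_len(m)]] <- TRUE   # order() is stable
  flag
}

#' Default histogram bin edges for the strategy features
#' @return named list of numeric break vectors.
#' @export
default_feature_breaks <- function() {
  list(total_n = seq(0, 900, by = 100),
       n_apps = seq(-0.5, 9.5, by = 1),
       first_app_week = seq(0.5, 10.5, by = 1),
       fym_amount = seq(0, 3, by = 0.5))
}

#' Per-cluster feature histograms
#'
#' For each cluster and feature, the fraction of the cluster's points in
#' each bin (fractions sum to 1). Matches the histogram panels used to
#' describe management strategies.
#'
#' @param result a `cluster_result`.
#' @param features feature matrix (defaults to the one stored in
#'   `result`).
#' @param breaks named list of bin edges; see [default_feature_breaks()].
#' @return data.frame with columns `cluster`, `feature`, `bin_lo`,
#'   `bin_hi`, `fraction`.
#' @export
cluster_histograms <- function(result, features = result$features,
                               breaks = default_feature_breaks()) {
  features <- as.matrix(features)
  out <- list()
  for (cl in seq_len(result$k)) {
    rows <- result$labels == cl
    for (f in colnames(features)) {
      br <- breaks[[f]]
      if (is.null(br)) {
        rng <- range(features[, f])
        br <- seq(rng[1L], rng[2L] + 1e-9, length.out = 11L)
      }
      v <- pmin(pmax(features[rows, f], br[1L]), br[length(br)])
      counts <- graphics::hist(v, breaks = br, plot = FALSE)$counts
      out[[length(out) + 1L]] <- data.frame(
        cluster = cl, feature = f,
        bin_lo = br[-length(br)], bin_hi = br[-1L],
        fraction = counts / sum(counts))
    }
  }
  do.call(rbind, out)
}
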