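# Statistical k-NN outlier filter: remove points whose mean distance to their
# k nearest neighbours exceeds the global mean plus sigma standard deviations.

#' Statistical filter parameters
#'
#' @param k neighbour count (>= 1, must be smaller than the cloud).
#' @param sigma threshold multiplier applied to the standard deviation of the
#'   per-point mean neighbour distances (non-negative).
#' @return list of class `filter_params`.
#' @export
filter_params <- function(k = 30L, sigma = 2) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L)
    pigback_error("k must be a positive integer", "pigback_param_error")
  if (!is.finite(sigma) || sigma < 0)
    pigback_error("sigma must be non-negative", "pigback_param_error")
  structure(list(k = k, sigma = sigma), class = "filter_params")
}

#' Mean distance to the k nearest neighbours
#'
#' For each point, the mean Euclidean distance to its `k` nearest other
#' points (the query point itself is excluded). A k-d tree provides the
#' neighbour searches; equidistant neighbours are ordered by point index so
#' the result is independent of point order up to permutation.
#'
#' @param cloud a [point_cloud()].
#' @param k neighbour count, `1 <= k < n_points(cloud)`.
#' @return numeric vector of per-point mean neighbour distances (m).
#' @export
knn_mean_distances <- function(cloud, k) {
  stopifnot(inherits(cloud, "point_cloud"))
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k >= n_points(cloud))
    pigback_error("cloud must contain more than k points",
                  "pigback_param_error")
  cpp_knn_mean_dist(cloud$points, k)
}

#' Global distance statistics and removal threshold
#'
#' Aggregates per-point mean neighbour distances into the global mean, the
#' sample standard deviation (n - 1 denominator) and the removal threshold
#' `L = mean + sigma * sd`.
#'
#' @param mean_dists per-point mean k-NN distances, length >= 2.
#' @param sigma threshold multiplier.
#' @return list of class `filter_stats` with `mean_knn_dist`, `global_mean`,
#'   `global_std` and `threshold`.
#' @export
filter_stats <- function(mean_dists, sigma) {
  if (length(mean_dists) < 2L)
    pigback_error(
      "need at least two distances: standard deviation is undefined",
      "pigback_param_error")
  if (!is.finite(sigma) || sigma < 0)
    pigback_error("sigma must be non-negative", "pigback_param_error")
  m <- mean(mean_dists)
  s <- sd(mean_dists)
  structure(list(mean_knn_dist = mean_dists, global_mean = m,
                 global_std = s, threshold = m + sigma * s),
            class = "filter_stats")
}

#' @export
print.filter_stats <- function(x, ...) {
  cat(sprintf(
    "<filter_stats: n = %d, mean = %.6g m, sd = %.6g m, threshold = %.6g m>\n",
    length(x$mean_knn_dist), x$global_mean, x$global_std, x$threshold))
  invisible(x)
}

#' Remove large-scale outliers by k-NN distance statistics
#'
#' A point is deleted when its mean k-nearest-neighbour distance strictly
#' exceeds the threshold `L = mean + sigma * sd`; a point exactly at the
#' threshold is retained (the least destructive reading of the deletion
#' rule). Survivors keep their input order and labels.
#'
#' @param cloud a [point_cloud()] with more than `params$k` points.
#' @param params a [filter_params()].
#' @return list with `kept` (filtered cloud), `removed` (logical mask over
#'   the input) and `stats` (the [filter_stats()] used).
#' @export
statistical_filter <- function(cloud, params = filter_params()) {
  stopifnot(inherits(cloud, "point_cloud"), inherits(params, "filter_params"))
  d <- knn_mean_distances(cloud, params$k)
  st <- filter_stats(d, params$sigma)
  removed <- d > st$threshold
  list(kept = cloud_subset(cloud, !removed), removed = removed, stats = st)
}
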