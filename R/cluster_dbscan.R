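# DBSCAN density clustering: strip small-scale noise and isolate the pig.

#' DBSCAN parameters
#'
#' @param eps neighbourhood radius in metres (> 0).
#' @param min_pts minimum number of points (including the point itself) an
#'   eps-neighbourhood must contain for a core point.
#' @return list of class `dbscan_params`.
#' @export
dbscan_params <- function(eps = 0.02, min_pts = 10L) {
  if (!is.finite(eps) || eps <= 0)
    pigback_error("eps must be positive", "pigback_param_error")
  min_pts <- as.integer(min_pts)
  if (is.na(min_pts) || min_pts < 1L)
    pigback_error("min_pts must be >= 1", "pigback_param_error")
  structure(list(eps = eps, min_pts = min_pts), class = "dbscan_params")
}

#' Epsilon-neighbourhood query
#'
#' All points (including the query point itself) within Euclidean distance
#' `eps` of point `index`, in ascending index order.
#'
#' @param cloud a [point_cloud()].
#' @param index 1-based point index.
#' @param eps radius in metres.
#' @return integer vector of point indices.
#' @export
region_query <- function(cloud, index, eps) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (!is.numeric(index) || length(index) != 1L || is.na(index) ||
      index < 1 || index > n_points(cloud))
    pigback_error("invalid point index", "pigback_param_error")
  if (!is.finite(eps) || eps <= 0)
    pigback_error("eps must be positive", "pigback_param_error")
  as.integer(cpp_region_query(cloud$points, as.integer(index), eps))
}

#' Density-based clustering with noise
#'
#' Clusters are maximal density-connected sets: a core point has at least
#' `min_pts` points in its eps-neighbourhood (itself included); border points
#' fall inside a core point's neighbourhood without being core themselves;
#' everything else is noise (cluster id 0). Cluster ids 1..K are assigned in
#' order of seed discovery by point index, and a point first marked noise may
#' later be claimed as a border point by a cluster grown from a later seed.
#'
#' @param cloud a non-empty [point_cloud()].
#' @param params a [dbscan_params()].
#' @return list of class `cluster_labeling` with integer `cluster_id`
#'   (0 = noise) and character `role` (`"core"`, `"border"`, `"noise"`).
#' @export
dbscan <- function(cloud, params = dbscan_params()) {
  stopifnot(inherits(cloud, "point_cloud"), inherits(params, "dbscan_params"))
  if (n_points(cloud) == 0L)
    pigback_error("cannot cluster an empty cloud", "pigback_param_error")
  res <- cpp_dbscan(cloud$points, params$eps, params$min_pts)
  role <- ifelse(res$core, "core",
                 ifelse(res$cluster_id > 0L, "border", "noise"))
  structure(list(cluster_id = as.integer(res$cluster_id), role = role,
                 n_clusters = res$n_clusters, params = params),
            class = "cluster_labeling")
}

#' @export
print.cluster_labeling <- function(x, ...) {
  cat(sprintf("<cluster_labeling: %d clusters, %d noise points of %d>\n",
              x$n_clusters, sum(x$cluster_id == 0L), length(x$cluster_id)))
  invisible(x)
}

#' Select the pig cluster from a labelling
#'
#' In an overhead scene the floor is usually the largest cluster, so the pig
#' is selected by elevation rather than size: among clusters of at least
#' `min_size` points whose mean height exceeds the estimated floor level by
#' `floor_margin`, the one with the greatest mean height is returned. The
#' floor level is the modal height of the largest cluster when that cluster
#' is flat (height range below `floor_margin`); otherwise the 1st percentile
#' of all heights.
#'
#' @param cloud the clustered [point_cloud()].
#' @param labeling the [dbscan()] result for `cloud`.
#' @param min_size minimum cluster size considered (filters out small noise
#'   blobs, which are tens of points, while a pig is thousands).
#' @param floor_margin required elevation above the floor, m.
#' @return the selected cluster as a [point_cloud()].
#' @export
select_pig_cluster <- function(cloud, labeling, min_size = 100L,
                               floor_margin = 0.1) {
  stopifnot(inherits(cloud, "point_cloud"),
            inherits(labeling, "cluster_labeling"))
  if (length(labeling$cluster_id) != n_points(cloud))
    pigback_error("labeling does not match the cloud", "pigback_param_error")
  cl <- labeling$cluster_id
  if (all(cl == 0L))
    pigback_error("no clusters found: segmentation failed",
                  "pigback_segmentation_error")
  z <- cloud$points[, 3L]
  sizes <- tabulate(cl, nbins = max(cl))
  largest <- which.max(sizes)
  zl <- z[cl == largest]
  floor_z <- if (diff(range(zl)) < floor_margin) {
    # modal height of the flat dominant cluster
    br <- seq(min(zl) - 1e-9, max(zl) + 1e-9, length.out = 64L)
    h <- findInterval(zl, br)
    mid <- (br[-1] + br[-length(br)]) / 2
    mid[which.max(tabulate(h, nbins = length(mid)))]
  } else {
    quantile(z, 0.01, names = FALSE)
  }
  best <- 0L
  best_mz <- -Inf
  for (k in which(sizes >= min_size)) {
    mz <- mean(z[cl == k])
    if (mz > floor_z + floor_margin && mz > best_mz) {
      best <- k
      best_mz <- mz
    }
  }
  if (best == 0L)
    pigback_error(
      "no elevated cluster of sufficient size: segmentation failed",
      "pigback_segmentation_error")
  cloud_subset(cloud, cl == best)
}
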