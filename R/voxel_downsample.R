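# Voxel-grid downsampling: regular cubes of side r, one centroid per
# occupied cube, output ordered by ascending flat voxel index.

#' Voxel grid geometry for a cloud
#'
#' The grid origin is at the coordinate minima and each axis is divided into
#' `ceil((max - min) / r)` cells (one cell for a degenerate extent).
#'
#' @param cloud a non-empty [point_cloud()].
#' @param r cube side, m (> 0).
#' @return object of class `voxel_grid` with `r`, `mins` and integer `dims`.
#' @export
voxel_grid_dims <- function(cloud, r) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (n_points(cloud) == 0L)
    pigback_error("cannot grid an empty cloud", "pigback_param_error")
  if (!is.finite(r) || r <= 0)
    pigback_error("voxel size r must be positive", "pigback_param_error")
  mins <- apply(cloud$points, 2L, min)
  maxs <- apply(cloud$points, 2L, max)
  dims <- pmax(1L, as.integer(ceiling((maxs - mins) / r - 1e-12)))
  structure(list(r = r, mins = mins, dims = dims), class = "voxel_grid")
}

#' Flat voxel index of points
#'
#' Cells are half-open `[min + i r, min + (i + 1) r)` with 0-based per-axis
#' indices `h_x, h_y, h_z`; a point on the exact upper boundary is clamped
#' into the last cell. The flat index is
#' `h = h_x + h_y * D_x + h_z * D_x * D_y`.
#'
#' @param point numeric vector (x, y, z) or an n x 3 matrix.
#' @param grid a [voxel_grid_dims()] result.
#' @return integer (vector of) flat indices, 0-based.
#' @export
voxel_index <- function(point, grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  p <- if (is.matrix(point)) point else matrix(point, ncol = 3L)
  hi <- grid$mins + grid$dims * grid$r
  tol <- 1e-9 * max(grid$r, 1)
  for (ax in 1:3) {
    if (any(p[, ax] < grid$mins[ax] - tol) || any(p[, ax] > hi[ax] + tol))
      pigback_error("point lies outside the voxel grid",
                    "pigback_param_error")
  }
  h <- sapply(1:3, function(ax) {
    pmin(grid$dims[ax] - 1L,
         pmax(0L, floor((p[, ax] - grid$mins[ax]) / grid$r)))
  })
  h <- matrix(h, ncol = 3L)
  as.integer(h[, 1] + h[, 2] * grid$dims[1] +
               h[, 3] * grid$dims[1] * grid$dims[2])
}

#' Downsample a cloud on a regular voxel grid
#'
#' Each occupied voxel is replaced by the arithmetic centroid of its points;
#' the output is ordered by ascending flat voxel index, making the result
#' independent of input point order. When labels are present each centroid
#' carries the voxel's majority label (`"unknown"` on ties).
#'
#' @param cloud a non-empty [point_cloud()].
#' @param r cube side, m.
#' @return the downsampled [point_cloud()].
#' @export
voxel_downsample <- function(cloud, r) {
  grid <- voxel_grid_dims(cloud, r)
  h <- voxel_index(cloud$points, grid)
  f <- factor(h, levels = sort(unique(h)))
  sums <- rowsum(cloud$points, f)
  counts <- tabulate(f, nbins = nlevels(f))
  centroids <- sums / counts
  labels <- NULL
  if (!is.null(cloud$labels)) {
    lv <- sort(unique(cloud$labels))
    tb <- table(f, factor(cloud$labels, levels = lv))
    top <- max.col(tb, ties.method = "first")
    winner <- tb[cbind(seq_len(nrow(tb)), top)]
    tied <- rowSums(tb == winner) > 1L
    labels <- ifelse(tied, "unknown", lv[top])
  }
  point_cloud(unname(centroids), labels)
}
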