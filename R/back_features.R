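# Back body-size features: keypoint widths, projection area, 3D convex
# envelope, and feature correlation.

#' Extract six keypoints from an aligned outline
#'
#' The outline's x range is split into three equal thirds; within each third
#' the keypoint pair is the maximum-y and minimum-y outline vertex. Pairs are
#' reported anterior (head end, +x) to posterior.
#'
#' @param outline an [extract_outline()] result of an aligned back (long
#'   axis along x, head towards +x).
#' @return object of class `keypoints`: list of 2 x 2 matrices `anterior`,
#'   `middle`, `posterior` (rows: max-y point, min-y point).
#' @export
extract_keypoints <- function(outline) {
  stopifnot(inherits(outline, "outline2d"))
  v <- outline$vertices
  if (length(unique(v[, 1])) < 3L)
    pigback_error("outline spans fewer than 3 distinct x positions",
                  "pigback_geometry_error")
  xr <- range(v[, 1])
  br <- seq(xr[1], xr[2], length.out = 4L)
  third <- pmin(3L, pmax(1L, findInterval(v[, 1], br, rightmost.closed = TRUE)))
  pick <- function(t) {
    w <- which(third == t)
    sel <- v[w, , drop = FALSE]
    rbind(sel[which.max(sel[, 2]), ], sel[which.min(sel[, 2]), ])
  }
  # thirds indexed low-x..high-x; anterior is the +x (head) end
  structure(list(anterior = pick(3L), middle = pick(2L), posterior = pick(1L)),
            class = "keypoints")
}

#' Keypoint pair widths
#'
#' Euclidean separations of the three keypoint pairs, mapped anterior ->
#' shoulder, middle -> belly, posterior -> hip.
#'
#' @param kp a [extract_keypoints()] result.
#' @return named numeric vector (shoulder_width, belly_width, hip_width), m.
#' @export
widths <- function(kp) {
  stopifnot(inherits(kp, "keypoints"))
  d <- function(m) sqrt(sum((m[1, ] - m[2, ]) ^ 2))
  c(shoulder_width = d(kp$anterior), belly_width = d(kp$middle),
    hip_width = d(kp$posterior))
}

# shoelace area of a polygon given as a CCW vertex matrix
shoelace_area <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1L)
  sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2]) / 2
}

# do any two non-adjacent edges of the closed polygon intersect?
polygon_self_intersects <- function(v) {
  cpp_polygon_self_intersects(v)
}

#' Planar projection area of an outline
#'
#' Shoelace area of the (possibly concave) outline polygon, so that notch
#' trimming is reflected in the area.
#'
#' @param outline an [extract_outline()] result or a CCW vertex matrix.
#' @return area in m^2.
#' @export
projection_area <- function(outline) {
  v <- if (inherits(outline, "outline2d")) outline$vertices else
    as.matrix(outline)
  if (nrow(v) < 3L)
    pigback_error("polygon needs at least three vertices",
                  "pigback_geometry_error")
  if (polygon_self_intersects(v))
    pigback_error("outline polygon is self-intersecting",
                  "pigback_geometry_error")
  abs(shoelace_area(v))
}

#' 3D convex envelope volume and surface area
#'
#' Builds the minimal convex hull of the cloud (quickhull); the volume comes
#' from a signed-tetrahedron decomposition of the outward-oriented facets and
#' the surface area from the triangle-facet sum.
#'
#' @param cloud a [point_cloud()] with at least 4 affinely independent
#'   points.
#' @return list with `volume` (m^3) and `area` (m^2).
#' @export
envelope_3d <- function(cloud) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (n_points(cloud) < 4L)
    pigback_error("need at least 4 points for a 3D envelope",
                  "pigback_geometry_error")
  res <- tryCatch(cpp_hull3d(cloud$points), error = function(e)
    pigback_error(paste0("degenerate cloud: ", conditionMessage(e)),
                  "pigback_geometry_error"))
  list(volume = res$volume, area = res$area)
}

#' Extract the six back features from a trimmed, aligned back cloud
#'
#' Composition of [extract_outline()], [extract_keypoints()], [widths()],
#' [projection_area()] and [envelope_3d()] into one record. Deterministic.
#'
#' @param cloud trimmed aligned back [point_cloud()].
#' @param alpha outline probe radius, see [extract_outline()].
#' @return a [back_features()] record.
#' @export
extract_back_features <- function(cloud, alpha = NULL) {
  stopifnot(inherits(cloud, "point_cloud"))
  outline <- extract_outline(project_xy(cloud), alpha)
  kp <- extract_keypoints(outline)
  w <- widths(kp)
  env <- envelope_3d(cloud)
  back_features(envelope_volume = env$volume, envelope_area = env$area,
                projection_area = projection_area(outline),
                shoulder_width = unname(w["shoulder_width"]),
                belly_width = unname(w["belly_width"]),
                hip_width = unname(w["hip_width"]))
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length >= 3 with non-zero variance.
#' @return correlation in `[-1, 1]`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    pigback_error("x and y must have equal length >= 3",
                  "pigback_param_error")
  dx <- x - mean(x)
  dy <- y - mean(y)
  sx <- sum(dx ^ 2)
  sy <- sum(dy ^ 2)
  if (sx == 0 || sy == 0)
    pigback_error("correlation undefined: zero variance",
                  "pigback_param_error")
  sum(dx * dy) / sqrt(sx * sy)
}

#' Pairwise Pearson correlations of the six back features
#'
#' @param records data frame or matrix whose columns include the six feature
#'   columns, with at least 3 rows.
#' @return symmetric 6 x 6 correlation matrix with unit diagonal.
#' @export
correlation_table <- function(records) {
  m <- as.matrix(as.data.frame(records)[, FEATURE_COLS])
  if (nrow(m) < 3L)
    pigback_error("need at least 3 records", "pigback_param_error")
  if (any(apply(m, 2L, sd) == 0))
    pigback_error("correlation undefined: a feature has zero variance",
                  "pigback_param_error")
  stats::cor(m)
}
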