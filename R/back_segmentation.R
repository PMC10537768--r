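# Planar projection, horizontal alignment, concave outline, sag analysis and
# head/tail trimming.

#' Project a cloud onto the horizontal plane
#'
#' @param cloud a non-empty [point_cloud()].
#' @return numeric matrix with columns x, y.
#' @export
project_xy <- function(cloud) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (n_points(cloud) == 0L)
    pigback_error("cannot project an empty cloud", "pigback_param_error")
  cloud$points[, 1:2, drop = FALSE]
}

# minimum-area enclosing rectangle over hull-edge orientations; returns the
# rotation (radians, CCW) that makes the rectangle axis-parallel, plus area
min_area_rect <- function(xy) {
  h <- chull(xy)
  if (length(h) < 3L)
    pigback_error("degenerate projection: points are collinear",
                  "pigback_geometry_error")
  hp <- xy[h, , drop = FALSE]
  nh <- nrow(hp)
  best <- list(area = Inf, theta = 0)
  for (i in seq_len(nh)) {
    j <- if (i == nh) 1L else i + 1L
    e <- unname(hp[j, ] - hp[i, ])
    len <- sqrt(sum(e ^ 2))
    if (len == 0) next
    theta <- -atan2(e[2], e[1])      # rotate edge onto the x axis
    ct <- cos(theta); st <- sin(theta)
    rx <- hp[, 1] * ct - hp[, 2] * st
    ry <- hp[, 1] * st + hp[, 2] * ct
    area <- diff(range(rx)) * diff(range(ry))
    if (!is.finite(best$area) || area < best$area * (1 - 1e-12)) {
      best <- list(area = area, theta = theta,
                   wx = diff(range(rx)), wy = diff(range(ry)))
    }
  }
  if (!is.finite(best$area))
    pigback_error("degenerate projection: points are collinear",
                  "pigback_geometry_error")
  best
}

#' Rotate a cloud so its footprint is axis-parallel, long side along x
#'
#' Finds the minimum-area enclosing rectangle of the horizontal projection
#' (its orientation is attained on a convex-hull edge) and rotates the cloud
#' about the z axis so that rectangle becomes axis-parallel with its long
#' side along x. The rotation is rigid: pairwise distances are preserved.
#'
#' @param cloud a [point_cloud()] with at least three non-collinear projected
#'   points.
#' @return list with `cloud` (rotated) and `angle_deg` (applied rotation
#'   about z, counter-clockwise, in (-90, 90]).
#' @export
align_horizontal <- function(cloud) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (n_points(cloud) < 3L)
    pigback_error("need at least three points to align",
                  "pigback_geometry_error")
  xy <- project_xy(cloud)
  best <- min_area_rect(xy)
  theta <- best$theta
  if (best$wx < best$wy) theta <- theta + pi / 2   # long side along x
  # normalise to (-pi/2, pi/2]
  while (theta <= -pi / 2) theta <- theta + pi
  while (theta > pi / 2) theta <- theta - pi
  ct <- cos(theta); st <- sin(theta)
  p <- cloud$points
  rotated <- cbind(p[, 1] * ct - p[, 2] * st,
                   p[, 1] * st + p[, 2] * ct,
                   p[, 3])
  list(cloud = point_cloud(rotated, cloud$labels),
       angle_deg = theta * 180 / pi)
}

#' Extract a concave outline of a planar point set
#'
#' Builds the alpha-shape boundary: an edge between two points at most
#' `2 * alpha` apart lies on the boundary when one of the two radius-`alpha`
#' disks through them contains no other point. The outer loop is returned as
#' a simple counter-clockwise polygon whose vertices are input points; it
#' follows concavities at scales of `alpha` and above and degrades to the
#' convex hull for convex dense sets.
#'
#' @param points2d numeric matrix (x, y) with at least 10 points.
#' @param alpha probe radius in metres; default 3 x the median
#'   nearest-neighbour spacing.
#' @return object of class `outline2d` with `vertices` (CCW coordinate
#'   matrix), `indices` (into `points2d`) and `alpha`.
#' @export
extract_outline <- function(points2d, alpha = NULL) {
  points2d <- as.matrix(points2d)
  if (nrow(points2d) < 10L)
    pigback_error("need at least 10 points for an outline",
                  "pigback_geometry_error")
  dup <- duplicated(points2d)
  uniq <- points2d[!dup, , drop = FALSE]
  if (is.null(alpha)) {
    p3 <- cbind(uniq, 0)
    alpha <- 3 * median(cpp_self_nn_dist(p3))
  }
  if (!is.finite(alpha) || alpha <= 0)
    pigback_error("alpha must be positive", "pigback_geometry_error")
  res <- tryCatch(cpp_alpha_outline(uniq, alpha), error = function(e)
    pigback_error(paste0("outline extraction failed (", conditionMessage(e),
                         "); try a larger alpha"), "pigback_geometry_error"))
  idx <- res$indices
  verts <- uniq[idx, , drop = FALSE]
  inside <- cpp_count_in_polygon(verts, uniq)
  if (inside < 0.99 * nrow(uniq))
    pigback_error(sprintf(
      "outline contains only %.1f%% of the points; try a larger alpha",
      100 * inside / nrow(uniq)), "pigback_geometry_error")
  orig_idx <- which(!dup)[idx]
  structure(list(vertices = verts, indices = orig_idx, alpha = alpha),
            class = "outline2d")
}

#' @export
print.outline2d <- function(x, ...) {
  cat(sprintf("<outline2d: %d vertices, alpha = %.4g m>\n",
              nrow(x$vertices), x$alpha))
  invisible(x)
}

#' Convex hull of a planar point set
#'
#' @param points2d numeric matrix (x, y) with at least three non-collinear
#'   points.
#' @return object of class `convex_polygon`: `vertices` (CCW, collinear
#'   boundary points removed) and `indices` into `points2d`.
#' @export
convex_hull_2d <- function(points2d) {
  points2d <- as.matrix(points2d)
  if (nrow(points2d) < 3L)
    pigback_error("need at least three points for a hull",
                  "pigback_geometry_error")
  h <- rev(chull(points2d))            # chull returns clockwise order
  if (length(h) < 3L)
    pigback_error("all points are collinear", "pigback_geometry_error")
  v <- points2d[h, , drop = FALSE]
  # drop collinear vertices
  scale2 <- max(apply(v, 2L, function(cc) diff(range(cc)))) ^ 2
  keep <- rep(TRUE, nrow(v))
  for (i in seq_len(nrow(v))) {
    a <- v[if (i == 1L) nrow(v) else i - 1L, ]
    b <- v[i, ]
    cc <- v[if (i == nrow(v)) 1L else i + 1L, ]
    cr <- (b[1] - a[1]) * (cc[2] - a[2]) - (b[2] - a[2]) * (cc[1] - a[1])
    if (abs(cr) <= 1e-12 * scale2) keep[i] <- FALSE
  }
  if (sum(keep) < 3L)
    pigback_error("all points are collinear", "pigback_geometry_error")
  structure(list(vertices = v[keep, , drop = FALSE], indices = h[keep]),
            class = "convex_polygon")
}

#' Sag depth of each outline vertex below its spanning hull edge
#'
#' For every outline vertex, the perpendicular distance to the convex-hull
#' edge joining the two hull vertices that bracket it in outline traversal
#' order. Hull vertices have sag 0.
#'
#' @param outline an [extract_outline()] result.
#' @param hull a [convex_hull_2d()] of the outline's vertices.
#' @return object of class `sag_profile`: numeric `sag` per outline vertex
#'   and integer `hull_edge` (index of the spanning edge, NA at hull
#'   vertices).
#' @export
sag_depths <- function(outline, hull) {
  stopifnot(inherits(outline, "outline2d"), inherits(hull, "convex_polygon"))
  ov <- outline$vertices
  hv <- hull$vertices
  # locate hull vertices along the outline
  pos <- integer(nrow(hv))
  for (i in seq_len(nrow(hv))) {
    hit <- which(ov[, 1] == hv[i, 1] & ov[, 2] == hv[i, 2])
    if (length(hit) == 0L)
      pigback_error("hull was not computed from this outline",
                    "pigback_param_error")
    pos[i] <- hit[1]
  }
  n <- nrow(ov)
  sag <- numeric(n)
  edge <- rep(NA_integer_, n)
  ord <- order(pos)
  pos_sorted <- pos[ord]
  for (e in seq_along(pos_sorted)) {
    i1 <- pos_sorted[e]
    i2 <- pos_sorted[if (e == length(pos_sorted)) 1L else e + 1L]
    a <- ov[i1, ]
    b <- ov[i2, ]
    ab <- b - a
    len <- sqrt(sum(ab ^ 2))
    run <- if (i2 > i1) seq(i1, i2) else c(seq(i1, n), seq_len(i2))
    mids <- run[-c(1L, length(run))]
    if (length(mids) && len > 0) {
      d <- abs((ov[mids, 1] - a[1]) * ab[2] - (ov[mids, 2] - a[2]) * ab[1]) /
        len
      sag[mids] <- d
      edge[mids] <- e
    }
  }
  structure(list(sag = sag, hull_edge = edge), class = "sag_profile")
}

#' Split off head and tail at deep outline concavities
#'
#' Candidate split points are outline vertices at local maxima of the sag
#' profile with depth at least `sag_min`. With the reference axis at the
#' centroid x of the projection, the tail split is the candidate farthest
#' from the axis on the tail side and the head split the candidate closest
#' to the axis on the head side; the cloud is cut by planes perpendicular to
#' the body axis at those x positions. A side without candidates is left
#' uncut and a warning recorded.
#'
#' @param cloud an aligned [point_cloud()] (long axis along x).
#' @param sag_min minimum concavity depth for a split candidate, m.
#' @param head_direction `"+x"` (default) or `"-x"`.
#' @param alpha outline probe radius, see [extract_outline()].
#' @return object of class `split_result`: `cloud` (trimmed), `head_cut_x`,
#'   `tail_cut_x` (NA when that side was not cut), `warnings` (character).
#' @export
split_head_tail <- function(cloud, sag_min = 0.03,
                            head_direction = c("+x", "-x"), alpha = NULL) {
  stopifnot(inherits(cloud, "point_cloud"))
  head_direction <- match.arg(head_direction)
  if (!is.finite(sag_min) || sag_min <= 0)
    pigback_error("sag_min must be positive", "pigback_param_error")
  xy <- project_xy(cloud)
  outline <- extract_outline(xy, alpha)
  hull <- convex_hull_2d(outline$vertices)
  prof <- sag_depths(outline, hull)

  s <- prof$sag
  n <- length(s)
  nxt <- c(2:n, 1L)
  prv <- c(n, 1:(n - 1L))
  local_max <- s >= sag_min & s >= s[nxt] & s >= s[prv] &
    (s > s[nxt] | s > s[prv])
  cand_x <- outline$vertices[local_max, 1L]

  cx <- mean(xy[, 1L])
  hsign <- if (head_direction == "+x") 1 else -1
  head_cand <- cand_x[(cand_x - cx) * hsign > 0]
  tail_cand <- cand_x[(cand_x - cx) * hsign < 0]

  warnings <- character()
  head_cut <- NA_real_
  tail_cut <- NA_real_
  if (length(head_cand)) {
    head_cut <- head_cand[which.min(abs(head_cand - cx))]
  } else {
    warnings <- c(warnings, "no split candidate on the head side; left uncut")
  }
  if (length(tail_cand)) {
    tail_cut <- tail_cand[which.max(abs(tail_cand - cx))]
  } else {
    warnings <- c(warnings, "no split candidate on the tail side; left uncut")
  }
  for (w in warnings) warning(w, call. = FALSE)

  x <- cloud$points[, 1L]
  keep <- rep(TRUE, length(x))
  lo <- if (hsign > 0) tail_cut else head_cut
  hi <- if (hsign > 0) head_cut else tail_cut
  if (!is.na(lo)) keep <- keep & x > lo
  if (!is.na(hi)) keep <- keep & x < hi
  if (!any(keep))
    pigback_error("head/tail trimming removed every point",
                  "pigback_segmentation_error")
  structure(list(cloud = cloud_subset(cloud, keep), head_cut_x = head_cut,
                 tail_cut_x = tail_cut, warnings = warnings,
                 outline = outline, sag = prof),
            class = "split_result")
}
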