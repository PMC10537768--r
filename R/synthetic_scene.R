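# Synthetic overhead pig scenes with labelled noise and known weight.

# Allometric calibration: the default dimension ranges are mapped onto the
# 190-300 kg herd weight range by a power law in body volume L*W*H, anchored
# so the smallest and largest default configurations land exactly on the
# range endpoints.
.wt_vmin <- 1.5 * 0.45 * 0.50
.wt_vmax <- 1.9 * 0.60 * 0.65
.wt_exponent <- log(300 / 190) / log(.wt_vmax / .wt_vmin)
.wt_coef <- 190 / .wt_vmin ^ .wt_exponent

#' Allometric weight rule
#'
#' Maps body dimensions to mass by the power law
#' `W = coef * (length * width * height)^exponent`. The default coefficient
#' and exponent are calibrated so that the extreme default dimension ranges
#' (1.5 x 0.45 x 0.50 m and 1.9 x 0.60 x 0.65 m) map to exactly 190 and
#' 300 kg.
#'
#' @param body_length,body_width,body_height metres.
#' @param coef coefficient (kg), default `r round(.wt_coef, 4)`.
#' @param exponent volume exponent, default `r round(.wt_exponent, 4)`.
#' @return weight in kg.
#' @export
allometric_weight <- function(body_length, body_width, body_height,
                              coef = .wt_coef, exponent = .wt_exponent) {
  coef * (body_length * body_width * body_height) ^ exponent
}

#' Parameters of the synthetic scene generator
#'
#' Defaults emulate the recording setup the pipeline targets: a 1.7 m wide
#' passage (floor patch 2.5 m x 1.7 m, body axis along the long side), a
#' depth camera 2.5 m overhead whose 640x480 grid corresponds to roughly a
#' 7 mm ground sampling pitch, sows of 190-300 kg, and the two noise classes
#' the denoising stages target: sparse large-scale outliers hovering above
#' and around the body, and small dense clusters offset from it.
#'
#' @param body_length,body_width,body_height length-2 ranges (m) from which a
#'   scene's dimensions are drawn uniformly; scalars are treated as fixed.
#' @param floor_extent floor patch (length, width) in m; the body axis runs
#'   along the first element.
#' @param pitch ground sampling pitch of the camera grid, m.
#' @param n_outliers_large number of sparse large-scale outlier points.
#' @param n_small_clusters,cluster_size small dense noise blobs and their size.
#' @param small_cluster_sd standard deviation of each blob, m.
#' @param small_cluster_offset minimum blob-centre distance from the body, m.
#' @param noise_sd Gaussian coordinate jitter applied to surface points, m.
#' @param head_length,tail_length protrusion lengths beyond the torso, m.
#' @param weight_coef,weight_exponent allometric rule, see
#'   [allometric_weight()].
#' @param weight_cv coefficient of variation of the multiplicative weight
#'   noise (0 disables it).
#' @param max_slope_deg surfaces steeper than this (degrees from horizontal)
#'   return no depth samples, emulating grazing-angle dropout.
#' @param seed integer seed; scenes are fully deterministic given the seed.
#' @return a validated list of class `scene_params`.
#' @export
scene_params <- function(body_length = c(1.5, 1.9),
                         body_width = c(0.45, 0.60),
                         body_height = c(0.50, 0.65),
                         floor_extent = c(2.5, 1.7),
                         pitch = 0.007,
                         n_outliers_large = 300L,
                         n_small_clusters = 5L,
                         cluster_size = 40L,
                         small_cluster_sd = 0.01,
                         small_cluster_offset = 0.1,
                         noise_sd = 0.003,
                         head_length = 0.25,
                         tail_length = 0.12,
                         weight_coef = .wt_coef,
                         weight_exponent = .wt_exponent,
                         weight_cv = 0.03,
                         max_slope_deg = 75,
                         seed = 1L) {
  rng2 <- function(x) if (length(x) == 1L) c(x, x) else as.numeric(x)
  p <- list(body_length = rng2(body_length), body_width = rng2(body_width),
            body_height = rng2(body_height),
            floor_extent = as.numeric(floor_extent), pitch = pitch,
            n_outliers_large = as.integer(n_outliers_large),
            n_small_clusters = as.integer(n_small_clusters),
            cluster_size = as.integer(cluster_size),
            small_cluster_sd = small_cluster_sd,
            small_cluster_offset = small_cluster_offset,
            noise_sd = noise_sd, head_length = head_length,
            tail_length = tail_length, weight_coef = weight_coef,
            weight_exponent = weight_exponent, weight_cv = weight_cv,
            max_slope_deg = max_slope_deg, seed = as.integer(seed))
  lens <- c(p$body_length, p$body_width, p$body_height, p$floor_extent,
            p$pitch, p$head_length, p$tail_length)
  if (any(!is.finite(lens)) || any(lens <= 0))
    pigback_error("all lengths must be positive", "pigback_param_error")
  if (diff(p$body_length) < 0 || diff(p$body_width) < 0 ||
      diff(p$body_height) < 0)
    pigback_error("dimension ranges must be increasing", "pigback_param_error")
  if (p$pitch >= min(p$body_width) / 10)
    pigback_error("pitch must be smaller than body_width / 10",
                  "pigback_param_error")
  if (p$weight_cv < 0)
    pigback_error("weight_cv must be non-negative", "pigback_param_error")
  if (p$n_outliers_large < 0 || p$n_small_clusters < 0 || p$cluster_size < 1)
    pigback_error("noise counts out of range", "pigback_param_error")
  if (max(p$body_length) + p$head_length + p$tail_length >= p$floor_extent[1])
    pigback_error("body plus protrusions must fit inside the floor extent",
                  "pigback_param_error")
  if (max(p$body_width) >= p$floor_extent[2])
    pigback_error("body width must fit inside the floor extent",
                  "pigback_param_error")
  structure(p, class = "scene_params")
}

# evaluate seed-scoped code without touching the caller's RNG stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# height and slope of one body part over grid coordinates (NA outside its
# footprint); parts are upper shells z = z0 + c * sqrt(s(x, y))
.part_field <- function(x, y, s, ds_dx, ds_dy, z0, c0) {
  z <- rep(NA_real_, length(x))
  g <- rep(NA_real_, length(x))
  m <- s > 1e-12
  rt <- sqrt(s[m])
  z[m] <- z0 + c0 * rt
  # dz/dx = c * s_x / (2 sqrt(s))
  gx <- c0 * ds_dx[m] / (2 * rt)
  gy <- c0 * ds_dy[m] / (2 * rt)
  g[m] <- sqrt(gx ^ 2 + gy ^ 2)
  list(z = z, grad = g)
}

#' Generate one labelled overhead pig scene
#'
#' The scene is sampled as a single overhead heightfield on the camera grid:
#' a planar floor patch at z = 0 (occluded beneath the body), an upper
#' superellipsoidal torso shell with apex at `body_height`, a head protrusion
#' beyond the +x torso end and a tail protrusion beyond the -x end (both
#' overlapping the torso so the pig is one connected surface, and both
#' producing concave neck/tail notches in the planar outline), plus the two
#' noise classes: `n_outliers_large` sparse points uniform in the body
#' bounding box dilated by 0.3 m and at least 5 x pitch away from every
#' surface point, and `n_small_clusters` dense Gaussian blobs centred at
#' least `small_cluster_offset` from the body. True weight follows
#' [allometric_weight()] with multiplicative Gaussian noise of CV
#' `weight_cv`.
#'
#' @param params a [scene_params()].
#' @return list with elements `cloud` (a labelled [point_cloud()]) and
#'   `truth` (a [scene_truth()]).
#' @export
generate_pig_scene <- function(params = scene_params()) {
  stopifnot(inherits(params, "scene_params"))
  with_seed(params$seed, {
    L <- runif(1, params$body_length[1], params$body_length[2])
    W <- runif(1, params$body_width[1], params$body_width[2])
    H <- runif(1, params$body_height[1], params$body_height[2])
    .generate_scene_dims(params, L, W, H)
  })
}

.generate_scene_dims <- function(params, L, W, H) {
  fx <- params$floor_extent[1]
  fy <- params$floor_extent[2]
  pitch <- params$pitch
  a <- L / 2
  b <- W / 2

  gx <- seq(0, fx, by = pitch) - fx / 2
  gy <- seq(0, fy, by = pitch) - fy / 2
  x <- rep(gx, times = length(gy))
  y <- rep(gy, each = length(gx))

  # torso: blunt-ended superellipsoidal shell, equator at 0.6 H
  s_t <- 1 - (x / a) ^ 4 - (y / b) ^ 2
  torso <- .part_field(x, y, s_t, -4 * x ^ 3 / a ^ 4, -2 * y / b ^ 2,
                       0.6 * H, 0.4 * H)

  # head: half-ellipsoid overlapping the +x torso end; raised so the union
  # surface steps down smoothly across the neck seam (gap << eps)
  overlap_h <- 0.10
  ah <- (params$head_length + overlap_h) / 2
  xh <- a + params$head_length - ah
  bh <- 0.42 * b
  s_h <- 1 - ((x - xh) / ah) ^ 2 - (y / bh) ^ 2
  head <- .part_field(x, y, s_h, -2 * (x - xh) / ah ^ 2, -2 * y / bh ^ 2,
                      0.37 * H, 0.35 * H)

  # tail: thin half-ellipsoid on the rump at the -x end
  overlap_t <- 0.06
  at <- (params$tail_length + overlap_t) / 2
  xt <- -(a + params$tail_length - at)
  bt <- 0.035
  s_l <- 1 - ((x - xt) / at) ^ 2 - (y / bt) ^ 2
  tailp <- .part_field(x, y, s_l, -2 * (x - xt) / at ^ 2, -2 * y / bt ^ 2,
                       0.55 * H, 0.18 * H)

  zs <- cbind(torso$z, head$z, tailp$z)
  gs <- cbind(torso$grad, head$grad, tailp$grad)
  part <- max.col(replace(zs, is.na(zs), -Inf), ties.method = "first")
  idx <- cbind(seq_along(x), part)
  z_body <- zs[idx]
  grad <- gs[idx]
  in_body <- !is.na(z_body)

  max_grad <- tan(params$max_slope_deg * pi / 180)
  visible_body <- in_body & grad <= max_grad
  keep <- visible_body | !in_body   # floor under the body is occluded

  lab <- ifelse(in_body, c("pig_torso", "pig_head", "pig_tail")[part],
                "floor")[keep]
  zk <- ifelse(in_body, z_body, 0)[keep]
  surf <- cbind(x = x[keep], y = y[keep], z = zk)
  surf <- surf + matrix(rnorm(length(surf), 0, params$noise_sd), ncol = 3L)

  body_pts <- surf[lab != "floor", , drop = FALSE]

  # small dense blobs offset from the body
  small <- matrix(numeric(0), ncol = 3L)
  if (params$n_small_clusters > 0L) {
    centres <- matrix(NA_real_, params$n_small_clusters, 3L)
    got <- 0L
    for (it in seq_len(1000L)) {
      if (got >= params$n_small_clusters) break
      cand <- c(runif(1, -fx / 2, fx / 2), runif(1, -fy / 2, fy / 2),
                runif(1, 0.05, H + 0.3))
      if (cpp_nn_dist(body_pts, matrix(cand, 1L)) >=
          params$small_cluster_offset) {
        got <- got + 1L
        centres[got, ] <- cand
      }
    }
    if (got < params$n_small_clusters)
      pigback_error("could not place small noise clusters off the body",
                    "pigback_param_error")
    small <- do.call(rbind, lapply(seq_len(params$n_small_clusters),
      function(i) {
        matrix(rnorm(3L * params$cluster_size, 0, params$small_cluster_sd),
               ncol = 3L, byrow = TRUE) +
          matrix(centres[i, ], params$cluster_size, 3L, byrow = TRUE)
      }))
  }

  # sparse large-scale outliers: uniform in the dilated body bounding box,
  # kept at >= 5 x pitch from every surface point
  large <- matrix(numeric(0), ncol = 3L)
  if (params$n_outliers_large > 0L) {
    lo <- apply(body_pts, 2L, min) - 0.3
    hi <- apply(body_pts, 2L, max) + 0.3
    lo[3] <- max(lo[3], 0)
    rows <- list()
    got <- 0L
    for (it in seq_len(1000L)) {
      if (got >= params$n_outliers_large) break
      m <- 2L * params$n_outliers_large
      cand <- cbind(runif(m, lo[1], hi[1]), runif(m, lo[2], hi[2]),
                    runif(m, lo[3], hi[3]))
      ok <- cpp_nn_dist(surf, cand) >= 5 * pitch
      cand <- cand[ok, , drop = FALSE]
      if (nrow(cand)) {
        rows[[length(rows) + 1L]] <- cand
        got <- got + nrow(cand)
      }
    }
    if (got < params$n_outliers_large)
      pigback_error("could not place large outliers off the surface",
                    "pigback_param_error")
    large <- do.call(rbind, rows)[seq_len(params$n_outliers_large), ,
                                  drop = FALSE]
  }

  pts <- rbind(surf, small, large)
  labels <- c(lab, rep("outlier_small", nrow(small)),
              rep("outlier_large", nrow(large)))
  cloud <- point_cloud(pts, labels)

  w <- allometric_weight(L, W, H, params$weight_coef, params$weight_exponent)
  if (params$weight_cv > 0) w <- w * (1 + rnorm(1, 0, params$weight_cv))
  counts <- table(factor(labels, levels = POINT_LABELS))
  truth <- scene_truth(w, L, W, H, setNames(as.integer(counts),
                                            names(counts)))
  list(cloud = cloud, truth = truth)
}

#' Generate a herd of synthetic pigs
#'
#' Draws each pig's body dimensions uniformly from the ranges in
#' `params_base` and generates one scene per pig. Deterministic given `seed`.
#'
#' @param n_pigs number of pigs (>= 1).
#' @param seed integer seed for the herd.
#' @param params_base a [scene_params()] supplying ranges and noise settings.
#' @return list of `n_pigs` elements, each a `list(cloud, truth)`.
#' @export
generate_herd <- function(n_pigs, seed = 1L, params_base = scene_params()) {
  if (!is.numeric(n_pigs) || n_pigs < 1)
    pigback_error("n_pigs must be >= 1", "pigback_param_error")
  n_pigs <- as.integer(n_pigs)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max, n_pigs))
  lapply(seq_len(n_pigs), function(i) {
    p <- params_base
    p$seed <- seeds[i]
    generate_pig_scene(p)
  })
}
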