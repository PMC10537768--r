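# Brute-force oracles and fixture builders shared across the suite.
# Every oracle is an independent O(n^2)-style implementation; none calls the
# code path it checks.

# full pairwise distance matrix
bf_dist <- function(pts) as.matrix(dist(pts))

# mean distance to the k nearest other points, by sorting each distance row
bf_knn_mean <- function(pts, k) {
  D <- bf_dist(pts)
  vapply(seq_len(nrow(pts)), function(i) {
    d <- sort(D[i, -i])[seq_len(k)]
    mean(d)
  }, numeric(1))
}

# removal mask of the statistical filter from first principles
bf_filter_removed <- function(pts, k, sigma) {
  db <- bf_knn_mean(pts, k)
  L <- mean(db) + sigma * sd(db)
  db > L
}

# DBSCAN by explicit density-reachability closure: cluster the core points
# by connected components of the (dist <= eps) graph, then attach border
# points to any adjacent core's component.
bf_dbscan <- function(pts, eps, min_pts) {
  n <- nrow(pts)
  D <- bf_dist(pts)
  nb_count <- rowSums(D <= eps)           # includes the point itself
  core <- nb_count >= min_pts
  comp <- rep(0L, n)
  cl <- 0L
  for (i in which(core)) {
    if (comp[i] > 0L) next
    cl <- cl + 1L
    queue <- i
    comp[i] <- cl
    while (length(queue)) {
      cur <- queue[1]
      queue <- queue[-1]
      nbrs <- which(core & D[cur, ] <= eps & comp == 0L)
      comp[nbrs] <- cl
      queue <- c(queue, nbrs)
    }
  }
  border_opts <- lapply(seq_len(n), function(i) {
    if (core[i]) return(comp[i])
    sort(unique(comp[core & D[i, ] <= eps]))
  })
  list(core = core, comp = comp, border_opts = border_opts)
}

# check a dbscan() labelling against the closure oracle:
# - identical noise sets
# - identical core partitions up to relabelling
# - each border point assigned to one of its density-reachable clusters
expect_dbscan_matches_oracle <- function(cloud, labeling, eps, min_pts) {
  or <- bf_dbscan(cloud$points, eps, min_pts)
  got_noise <- labeling$cluster_id == 0L
  exp_noise <- vapply(or$border_opts, function(x)
    length(x) == 0L || identical(x, 0L), logical(1)) & !or$core
  expect_identical(got_noise, unname(exp_noise))
  expect_identical(labeling$role == "core", unname(or$core))
  # core partition up to relabelling: the map oracle-comp -> cluster_id must
  # be a bijection over core points
  map <- table(or$comp[or$core], labeling$cluster_id[or$core])
  expect_true(all(rowSums(map > 0) == 1), label = "core partition split")
  expect_true(all(colSums(map > 0) == 1), label = "core partition merged")
  # translate and check borders
  trans <- apply(map, 1L, function(r) as.integer(colnames(map)[which(r > 0)]))
  border <- !or$core & !got_noise
  for (i in which(border)) {
    allowed <- trans[as.character(or$border_opts[[i]])]
    expect_true(labeling$cluster_id[i] %in% allowed,
                label = sprintf("border point %d cluster membership", i))
  }
  invisible(TRUE)
}

# gift-wrapping convex hull (indices, CCW starting from the lowest point)
bf_hull2d <- function(xy) {
  n <- nrow(xy)
  start <- order(xy[, 2], xy[, 1])[1]
  hull <- start
  cur <- start
  repeat {
    cand <- setdiff(seq_len(n), cur)
    nxt <- cand[1]
    for (j in cand[-1]) {
      cr <- (xy[nxt, 1] - xy[cur, 1]) * (xy[j, 2] - xy[cur, 2]) -
        (xy[nxt, 2] - xy[cur, 2]) * (xy[j, 1] - xy[cur, 1])
      d_n <- sum((xy[nxt, ] - xy[cur, ]) ^ 2)
      d_j <- sum((xy[j, ] - xy[cur, ]) ^ 2)
      if (cr < 0 || (abs(cr) < 1e-12 && d_j > d_n)) nxt <- j
    }
    if (nxt == start) break
    hull <- c(hull, nxt)
    cur <- nxt
    if (length(hull) > n) stop("gift wrapping failed")
  }
  hull
}

# exhaustive minimum-area enclosing rectangle over hull-edge orientations
bf_min_rect_area <- function(xy) {
  h <- bf_hull2d(xy)
  hp <- xy[h, , drop = FALSE]
  nh <- nrow(hp)
  best <- Inf
  for (i in seq_len(nh)) {
    j <- if (i == nh) 1L else i + 1L
    e <- hp[j, ] - hp[i, ]
    th <- -atan2(e[2], e[1])
    rx <- hp[, 1] * cos(th) - hp[, 2] * sin(th)
    ry <- hp[, 1] * sin(th) + hp[, 2] * cos(th)
    best <- min(best, diff(range(rx)) * diff(range(ry)))
  }
  best
}

# dense jittered samples of an axis-aligned rectangle
sample_rect <- function(x0, x1, y0, y1, pitch = 0.02, jitter = pitch / 20,
                        seed = 1) {
  set.seed(seed)
  g <- expand.grid(x = seq(x0, x1, by = pitch), y = seq(y0, y1, by = pitch))
  as.matrix(g) + matrix(rnorm(nrow(g) * 2, 0, jitter), ncol = 2)
}

# label-based precision/recall scoring of a selected cluster
score_selection <- function(full_cloud, selected) {
  pig <- c("pig_torso", "pig_head", "pig_tail")
  n_all <- sum(full_cloud$labels %in% pig)
  prec <- mean(selected$labels %in% pig)
  rec <- sum(selected$labels %in% pig) / n_all
  c(precision = prec, recall = rec)
}

pig_scene_cached <- local({
  cache <- list()
  function(seed) {
    key <- as.character(seed)
    if (is.null(cache[[key]]))
      cache[[key]] <<- generate_pig_scene(scene_params(seed = seed))
    cache[[key]]
  }
})
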