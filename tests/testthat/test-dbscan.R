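# DBSCAN clustering and pig-cluster selection.

cloud1d <- function(x) point_cloud(cbind(x, 0, 0))

test_that("region_query returns the inclusive eps-neighbourhood", {
  cl <- cloud1d(c(0, 0.1, 0.2, 5))
  expect_identical(region_query(cl, 4, 0.5), 4L)
  expect_identical(region_query(cl, 2, 0.15), c(1L, 2L, 3L))
  set.seed(1)
  pts <- matrix(runif(600), ncol = 3)
  cl2 <- point_cloud(pts)
  for (i in c(1, 57, 200)) {
    got <- region_query(cl2, i, 0.2)
    want <- which(sqrt(colSums((t(pts) - pts[i, ]) ^ 2)) <= 0.2)
    expect_identical(got, want)
  }
  expect_error(region_query(cl, 0, 0.1), class = "pigback_param_error")
  expect_error(region_query(cl, 1, -1), class = "pigback_param_error")
})

test_that("the worked one-dimensional example clusters as expected", {
  cl <- cloud1d(c(0, 0.1, 0.2, 5, 5.1, 9))
  lab <- dbscan(cl, dbscan_params(eps = 0.15, min_pts = 2))
  expect_equal(lab$cluster_id, c(1L, 1L, 1L, 2L, 2L, 0L))
  expect_equal(lab$role, c(rep("core", 5), "noise"))
  expect_equal(lab$n_clusters, 2L)
})

test_that("degenerate configurations behave per the density definitions", {
  cl <- cloud1d(c(0, 1, 2, 3))
  lab <- dbscan(cl, dbscan_params(eps = 0.5, min_pts = 2))
  expect_true(all(lab$cluster_id == 0L))
  co <- point_cloud(matrix(1, 5, 3))
  lab2 <- dbscan(co, dbscan_params(eps = 0.1, min_pts = 5))
  expect_true(all(lab2$cluster_id == 1L))
  expect_true(all(lab2$role == "core"))
  expect_error(dbscan(point_cloud(matrix(0, 0, 3))),
               class = "pigback_param_error")
})

test_that("partitions match the density-reachability closure oracle", {
  for (case in 1:8) {
    set.seed(case)
    k <- sample(2:4, 1)
    centers <- matrix(runif(k * 3, 0, 4), ncol = 3)
    pts <- do.call(rbind, lapply(seq_len(k), function(i)
      matrix(rnorm(3 * 40, centers[i, ], 0.15), ncol = 3, byrow = TRUE)))
    pts <- rbind(pts, matrix(runif(60, -1, 5), ncol = 3))
    cl <- point_cloud(pts)
    eps <- runif(1, 0.2, 0.4)
    mp <- sample(4:10, 1)
    lab <- dbscan(cl, dbscan_params(eps, mp))
    expect_dbscan_matches_oracle(cl, lab, eps, mp)
  }
})

test_that("clustering is invariant to point permutation", {
  set.seed(11)
  pts <- rbind(matrix(rnorm(150, 0, 0.1), ncol = 3),
               matrix(rnorm(150, 3, 0.1), ncol = 3))
  cl <- point_cloud(pts)
  lab <- dbscan(cl, dbscan_params(0.3, 5))
  perm <- sample(nrow(pts))
  lab_p <- dbscan(point_cloud(pts[perm, ]), dbscan_params(0.3, 5))
  # same noise set and same partition (clusters may be renumbered)
  expect_identical(lab_p$cluster_id[order(perm)] == 0L,
                   lab$cluster_id == 0L)
  tab <- table(lab$cluster_id, lab_p$cluster_id[order(perm)])
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
})

test_that("labelling satisfies the core/border/noise invariants", {
  set.seed(12)
  pts <- rbind(matrix(rnorm(240, 0, 0.2), ncol = 3),
               matrix(runif(90, -2, 2), ncol = 3))
  cl <- point_cloud(pts)
  p <- dbscan_params(0.25, 6)
  lab <- dbscan(cl, p)
  D <- bf_dist(pts)
  nbc <- rowSums(D <= p$eps)
  expect_true(all(nbc[lab$role == "core"] >= p$min_pts))
  expect_true(all(nbc[lab$role != "core"] < p$min_pts))
  for (i in which(lab$role == "border")) {
    same <- lab$cluster_id == lab$cluster_id[i] & lab$role == "core"
    expect_true(any(D[i, same] <= p$eps))
  }
  for (i in which(lab$role == "noise")) {
    expect_false(any(D[i, lab$role == "core"] <= p$eps))
  }
})

test_that("pig-cluster selection picks the elevated cluster by mean height", {
  set.seed(13)
  floor_pts <- cbind(runif(800, 0, 2), runif(800, 0, 2), rnorm(800, 0, 0.003))
  high <- cbind(runif(300, 0.5, 1.0), runif(300, 0.5, 1.0),
                rnorm(300, 0.5, 0.01))
  tiny_high <- cbind(runif(30, 1.6, 1.65), runif(30, 1.6, 1.65),
                     rnorm(30, 0.9, 0.005))
  cl <- point_cloud(rbind(floor_pts, high, tiny_high),
                    labels = c(rep("floor", 800), rep("pig_torso", 300),
                               rep("outlier_small", 30)))
  lab <- dbscan(cl, dbscan_params(0.1, 5))
  sel <- select_pig_cluster(cl, lab, min_size = 100, floor_margin = 0.1)
  expect_true(all(sel$labels == "pig_torso"))
  expect_equal(n_points(sel), 300L)
  # without the elevated cluster selection fails
  cl2 <- point_cloud(rbind(floor_pts, tiny_high))
  lab2 <- dbscan(cl2, dbscan_params(0.1, 5))
  expect_error(select_pig_cluster(cl2, lab2, min_size = 100),
               class = "pigback_segmentation_error")
})
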