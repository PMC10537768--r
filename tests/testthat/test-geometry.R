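# Projection, alignment, concave outline, convex hull, sag and splitting.

test_that("projection drops z and keeps multiplicity", {
  expect_equal(unname(project_xy(point_cloud(matrix(c(1, 2, 3), 1)))),
               matrix(c(1, 2), 1))
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  pr <- project_xy(point_cloud(cube))
  expect_equal(nrow(pr), 8L)
  expect_equal(nrow(unique(pr)), 4L)
})

test_that("alignment recovers an axis-parallel rectangle at any rotation", {
  rect <- as.matrix(expand.grid(x = seq(0, 2, by = 0.1),
                                y = seq(0, 1, by = 0.1)))
  cl0 <- point_cloud(cbind(rect, 0))
  al0 <- align_horizontal(cl0)
  expect_equal(al0$angle_deg, 0, tolerance = 1e-9)
  th <- 30 * pi / 180
  rot <- cbind(rect[, 1] * cos(th) - rect[, 2] * sin(th),
               rect[, 1] * sin(th) + rect[, 2] * cos(th), 0)
  al <- align_horizontal(point_cloud(rot))
  p <- al$cloud$points
  expect_equal(diff(range(p[, 1])) * diff(range(p[, 2])), 2,
               tolerance = 1e-9)
  expect_gt(diff(range(p[, 1])), diff(range(p[, 2])))  # long side along x
})

test_that("alignment is a rigid isometry and matches the exhaustive rectangle",
{
  for (case in 1:5) {
    set.seed(case)
    pts <- cbind(matrix(rnorm(80), ncol = 2) %*%
                   matrix(c(2, 0.7, 0, 0.4), 2), rnorm(40, 1, 0.1))
    cl <- point_cloud(pts)
    al <- align_horizontal(cl)
    p <- al$cloud$points
    expect_equal(diff(range(p[, 1])) * diff(range(p[, 2])),
                 bf_min_rect_area(pts[, 1:2]), tolerance = 1e-9)
    d0 <- dist(pts[1:10, ])
    d1 <- dist(p[1:10, ])
    expect_equal(as.vector(d1), as.vector(d0), tolerance = 1e-9)
    expect_true(al$angle_deg > -90 - 1e-9 && al$angle_deg <= 90 + 1e-9)
  }
  expect_error(align_horizontal(point_cloud(cbind(1:5, 2 * (1:5), 0))),
               class = "pigback_geometry_error")
})

test_that("outline area matches analytic areas for square and notched square",
{
  sq <- sample_rect(0, 1, 0, 1, pitch = 0.02, seed = 1)
  o <- extract_outline(sq)
  expect_equal(projection_area(o), 1, tolerance = 0.02)

  # square with a rectangular notch: concave outline sees the notch, the
  # convex hull does not
  notch <- sq[!(sq[, 1] > 0.4 & sq[, 1] < 0.6 & sq[, 2] > 0.5), ]
  on <- extract_outline(notch)
  expect_equal(projection_area(on), 1 - 0.2 * 0.5, tolerance = 0.035)
  hull <- convex_hull_2d(on$vertices)
  expect_equal(projection_area(hull$vertices), 1, tolerance = 0.02)
})

test_that("a convex dense disk has outline close to its hull", {
  set.seed(2)
  g <- as.matrix(expand.grid(x = seq(-1, 1, by = 0.015),
                             y = seq(-1, 1, by = 0.015)))
  disk <- g[rowSums(g ^ 2) <= 1, ] + matrix(rnorm(2 * sum(rowSums(g ^ 2) <= 1),
                                                  0, 0.001), ncol = 2)
  o <- extract_outline(disk)
  hull <- convex_hull_2d(o$vertices)
  prof <- sag_depths(o, hull)
  expect_lt(max(prof$sag), 2 * o$alpha)
  expect_equal(projection_area(o), pi, tolerance = 0.02)
})

test_that("convex hull matches closed forms and the gift-wrapping oracle", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0.5, 0.5))
  h <- convex_hull_2d(sq)
  expect_equal(nrow(h$vertices), 4L)
  expect_equal(projection_area(h$vertices), 1)
  tri <- rbind(c(0, 0), c(1, 0), c(0, 1))
  expect_equal(projection_area(convex_hull_2d(tri)$vertices), 0.5)
  for (case in 1:6) {
    set.seed(case)
    xy <- matrix(rnorm(2 * sample(10:50, 1)), ncol = 2)
    got <- sort(convex_hull_2d(xy)$indices)
    expect_equal(got, sort(bf_hull2d(xy)))
  }
  expect_error(convex_hull_2d(cbind(1:5, 1:5)),
               class = "pigback_geometry_error")
})

test_that("sag depths are the distances to the spanning hull edges", {
  # square outline: no concavity, all sags zero
  sqo <- structure(list(vertices = rbind(c(0, 0), c(4, 0), c(4, 4), c(0, 4)),
                        indices = 1:4, alpha = 1), class = "outline2d")
  hull <- convex_hull_2d(sqo$vertices)
  expect_equal(sag_depths(sqo, hull)$sag, rep(0, 4))

  # notch through (2,2): perpendicular distance to the top edge y = 4 is 2
  no <- structure(list(vertices = rbind(c(0, 0), c(4, 0), c(4, 4), c(2, 2),
                                        c(0, 4)),
                       indices = 1:5, alpha = 1), class = "outline2d")
  hn <- convex_hull_2d(no$vertices)
  prof <- sag_depths(no, hn)
  expect_equal(prof$sag, c(0, 0, 0, 2, 0))

  # similarity: scaling the outline scales every sag
  s <- 2.5
  ns <- structure(list(vertices = no$vertices * s, indices = 1:5, alpha = 1),
                  class = "outline2d")
  profs <- sag_depths(ns, convex_hull_2d(ns$vertices))
  expect_equal(profs$sag, prof$sag * s)

  # hull not derived from the outline is rejected
  expect_error(sag_depths(no, convex_hull_2d(sqo$vertices + 10)),
               class = "pigback_param_error")
})

test_that("head/tail splitting cuts at the deepest notches of a dumbbell", {
  # bar [0,4]x[0,1] with V-notches in the top edge, deepest at x = 1 and
  # x = 3 (depth 0.4): the head cut is the candidate nearest the centroid
  # axis on the head side, the tail cut the farthest on the tail side; the
  # cut positions match the notch positions to within the outline sampling
  # resolution (the alpha boundary smooths the last few samples of a sharp
  # tip)
  pitch <- 0.02
  g <- as.matrix(expand.grid(x = seq(0, 4, by = pitch),
                             y = seq(0, 1, by = pitch)))
  top <- function(x) {
    d <- pmax(0, 0.4 * (1 - abs(x - 1) / 0.4))
    d2 <- pmax(0, 0.4 * (1 - abs(x - 3) / 0.4))
    1 - pmax(d, d2)
  }
  keep <- g[, 2] <= top(g[, 1]) + 1e-9
  cl <- point_cloud(cbind(g[keep, ], 0))
  res <- suppressWarnings(split_head_tail(cl, sag_min = 0.1, alpha = 0.05))
  expect_lt(abs(res$head_cut_x - 3), 3 * pitch)
  expect_lt(abs(res$tail_cut_x - 1), 3 * pitch)
  x <- res$cloud$points[, 1]
  expect_true(all(x > res$tail_cut_x & x < res$head_cut_x))
  # trimmed extent strictly shorter than the input extent
  expect_lt(diff(range(x)), 4)
  expect_length(res$warnings, 0L)
})

test_that("a capsule with no deep concavity is returned unchanged", {
  th <- seq(0, pi, length.out = 40)
  g <- as.matrix(expand.grid(x = seq(-1, 1, by = 0.04),
                             y = seq(-0.3, 0.3, by = 0.04)))
  inside <- abs(g[, 1]) <= 0.7 | sqrt((abs(g[, 1]) - 0.7) ^ 2 + g[, 2] ^ 2) <=
    0.3
  cl <- point_cloud(cbind(g[inside & abs(g[, 2]) <= 0.3, ], 0))
  expect_warning(expect_warning(
    res <- split_head_tail(cl, sag_min = 0.05, alpha = 0.1),
    "head side"), "tail side")
  expect_equal(n_points(res$cloud), n_points(cl))
  expect_true(is.na(res$head_cut_x) && is.na(res$tail_cut_x))
})

test_that("head/tail trimming recovers the labelled protrusions of a scene", {
  sc <- pig_scene_cached(1)
  f <- statistical_filter(sc$cloud)
  pig <- select_pig_cluster(f$kept, dbscan(f$kept))
  al <- align_horizontal(pig)$cloud
  res <- suppressWarnings(split_head_tail(al))
  ht_before <- sum(pig$labels %in% c("pig_head", "pig_tail"))
  ht_after <- sum(res$cloud$labels %in% c("pig_head", "pig_tail"))
  torso_keep <- sum(res$cloud$labels == "pig_torso") /
    sum(pig$labels == "pig_torso")
  expect_gte(1 - ht_after / ht_before, 0.8)
  expect_gte(torso_keep, 0.95)
  expect_lt(diff(range(res$cloud$points[, 1])),
            diff(range(al$points[, 1])))
})
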