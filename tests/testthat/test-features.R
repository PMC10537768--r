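# Back body-size features.

mk_outline <- function(v) structure(list(vertices = v,
                                         indices = seq_len(nrow(v)),
                                         alpha = 1), class = "outline2d")

test_that("keypoints are the extremal-y pairs of each body third", {
  # octagonal 3 x 1 slab whose y extremes sit at one x per third: every
  # third is exactly 1.0 wide
  rect <- mk_outline(rbind(c(0, 0.5), c(0.5, 0), c(1.5, 0), c(2.5, 0),
                           c(3, 0.5), c(2.5, 1), c(1.5, 1), c(0.5, 1)))
  kp <- extract_keypoints(rect)
  w <- widths(kp)
  expect_equal(unname(w), c(1, 1, 1))

  # hexagonal body with one dominant width pair per third (anterior at +x):
  # anterior 0.4, middle 0.5, posterior 0.45
  hexo <- mk_outline(rbind(
    c(0.05, -0.1), c(0.5, -0.225), c(1.5, -0.25), c(2.5, -0.2),
    c(2.95, -0.1), c(2.95, 0.1), c(2.5, 0.2), c(1.5, 0.25),
    c(0.5, 0.225), c(0.05, 0.1)))
  w2 <- widths(extract_keypoints(hexo))
  expect_equal(unname(w2), c(0.4, 0.5, 0.45))
  expect_equal(names(w2), c("shoulder_width", "belly_width", "hip_width"))

  # invariance to the starting vertex of the outline traversal
  v <- hexo$vertices
  rot <- mk_outline(v[c(4:nrow(v), 1:3), ])
  expect_equal(widths(extract_keypoints(rot)), w2)

  expect_error(extract_keypoints(mk_outline(rbind(c(0, 0), c(0, 1),
                                                  c(1, 0.5)))),
               class = "pigback_geometry_error")
})

test_that("pair widths are Euclidean distances", {
  kp <- structure(list(anterior = rbind(c(0, 0), c(0, 3)),
                       middle = rbind(c(1, 1), c(4, 5)),
                       posterior = rbind(c(2, 2), c(2, 2))),
                  class = "keypoints")
  expect_equal(unname(widths(kp)), c(3, 5, 0))
})

test_that("projection area is the shoelace area of the outline", {
  expect_equal(projection_area(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))), 1)
  expect_equal(projection_area(rbind(c(0, 0), c(1, 0), c(0, 1))), 0.5)
  expect_error(projection_area(rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))),
               class = "pigback_geometry_error")  # bowtie
})

test_that("3D envelope matches closed forms to 1e-9", {
  cube <- point_cloud(as.matrix(expand.grid(0:1, 0:1, 0:1)))
  env <- envelope_3d(cube)
  expect_equal(env$volume, 1, tolerance = 1e-9)
  expect_equal(env$area, 6, tolerance = 1e-9)

  tet <- point_cloud(rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
                           c(0.5, sqrt(3) / 6, sqrt(2 / 3))))
  envt <- envelope_3d(tet)
  expect_equal(envt$volume, 1 / (6 * sqrt(2)), tolerance = 1e-9)
  expect_equal(envt$area, sqrt(3), tolerance = 1e-9)

  expect_error(envelope_3d(point_cloud(cbind(runif(10), runif(10), 1))),
               class = "pigback_geometry_error")
})

test_that("the envelope ignores interior points and converges on a sphere", {
  set.seed(3)
  shell <- matrix(rnorm(3 * 800), ncol = 3)
  shell <- shell / sqrt(rowSums(shell ^ 2))
  inner <- matrix(rnorm(3 * 200, 0, 0.15), ncol = 3)
  e1 <- envelope_3d(point_cloud(shell))
  e2 <- envelope_3d(point_cloud(rbind(shell, inner)))
  expect_equal(e2$volume, e1$volume, tolerance = 1e-12)
  expect_equal(e2$area, e1$area, tolerance = 1e-12)
  expect_equal(e1$volume, 4 / 3 * pi, tolerance = 0.03)
  expect_equal(e1$area, 4 * pi, tolerance = 0.03)
})

test_that("features of a half-ellipsoid shell match the analytic values", {
  a <- 0.8; b <- 0.3; c0 <- 0.25
  g <- as.matrix(expand.grid(x = seq(-a, a, by = 0.01),
                             y = seq(-b, b, by = 0.01)))
  s <- 1 - (g[, 1] / a) ^ 2 - (g[, 2] / b) ^ 2
  keep <- s > 0
  cl <- point_cloud(cbind(g[keep, ], c0 * sqrt(s[keep])))
  ft <- extract_back_features(cl)
  expect_equal(unname(ft["envelope_volume"]), 2 / 3 * pi * a * b * c0,
               tolerance = 0.05)
  expect_equal(unname(ft["projection_area"]), pi * a * b, tolerance = 0.03)

  # dimensional scaling: s, s^2, s^3
  sc <- 2
  cl2 <- point_cloud(cl$points * sc)
  ft2 <- extract_back_features(cl2)
  expect_equal(unname(ft2["envelope_volume"]),
               unname(ft["envelope_volume"]) * sc ^ 3, tolerance = 1e-6)
  expect_equal(unname(ft2["envelope_area"]),
               unname(ft["envelope_area"]) * sc ^ 2, tolerance = 1e-6)
  expect_equal(unname(ft2["projection_area"]),
               unname(ft["projection_area"]) * sc ^ 2, tolerance = 1e-6)
  expect_equal(unname(ft2[4:6]), unname(ft[4:6]) * sc, tolerance = 1e-6)

  # determinism
  expect_identical(extract_back_features(cl), ft)
})

test_that("pearson matches hand computation and rejects degenerate input", {
  expect_equal(pearson(1:10, 1:10), 1)
  expect_equal(pearson(1:10, -(1:10)), -1)
  expect_equal(pearson(c(1, 2, 3), c(1, 2, 4)), 9 / sqrt(84),
               tolerance = 1e-12)
  expect_error(pearson(c(1, 1, 1), 1:3), class = "pigback_param_error")
  expect_error(pearson(1:3, 1:4), class = "pigback_param_error")
})

test_that("the correlation table is symmetric, unit-diagonal and consistent
           with element-wise pearson", {
  set.seed(4)
  base <- runif(30, 0.8, 1.2)
  df <- data.frame(envelope_volume = base * runif(30, 0.95, 1.05),
                   envelope_area = base * runif(30, 0.9, 1.1),
                   projection_area = base * runif(30, 0.9, 1.1),
                   shoulder_width = sqrt(base) * runif(30, 0.95, 1.05),
                   belly_width = sqrt(base) * runif(30, 0.95, 1.05),
                   hip_width = sqrt(base) * runif(30, 0.95, 1.05))
  ct <- correlation_table(df)
  expect_equal(dim(ct), c(6L, 6L))
  expect_equal(unname(diag(ct)), rep(1, 6))
  expect_lt(max(abs(ct - t(ct))), 1e-12)
  for (i in 1:6) for (j in 1:6) {
    if (i == j) next
    expect_equal(ct[i, j], pearson(df[[i]], df[[j]]), tolerance = 1e-12)
  }
  # shoulder width moves with projection area on a size-driven herd
  expect_gt(ct["shoulder_width", "projection_area"], 0)
  expect_error(correlation_table(df[1:2, ]), class = "pigback_param_error")
})
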