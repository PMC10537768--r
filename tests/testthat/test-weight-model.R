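# Rasterisation, CNN regressor, RBF baseline and evaluation metrics.

test_that("rasterisation bins mean relative heights", {
  # single point: the occupied cell holds 0 (height relative to itself)
  r1 <- rasterize_back(point_cloud(matrix(c(0.5, 0.5, 1.2), 1)), 4, 4)
  expect_equal(sum(r1 != 0), 0)
  expect_equal(dim(unclass(r1)), c(4L, 4L))

  # two points in one cell average their relative heights
  cl <- point_cloud(rbind(c(0.05, 0.05, 0.5), c(0.1, 0.08, 0.7),
                          c(0.95, 0.95, 0.1)))
  r <- rasterize_back(cl, 4, 4)
  expect_equal(r[1, 1], mean(c(0.4, 0.6)))
  expect_equal(r[4, 4], 0)
  expect_error(rasterize_back(cl, 3, 8), class = "pigback_param_error")
})

test_that("occupied raster cells match brute-force binning", {
  set.seed(5)
  pts <- cbind(runif(500, 0, 2), runif(500, 0, 1), runif(500))
  cl <- point_cloud(pts)
  H <- 16L; W <- 16L
  r <- rasterize_back(cl, H, W)
  bx <- pmin(W, pmax(1L, ceiling((pts[, 1] - min(pts[, 1])) /
                                   diff(range(pts[, 1])) * W)))
  by <- pmin(H, pmax(1L, ceiling((pts[, 2] - min(pts[, 2])) /
                                   diff(range(pts[, 2])) * H)))
  want <- matrix(0, H, W)
  z <- pts[, 3] - min(pts[, 3])
  for (i in seq_len(nrow(pts))) {
    sel <- by == by[i] & bx == bx[i]
    want[by[i], bx[i]] <- mean(z[sel])
  }
  expect_equal(unclass(r), want, tolerance = 1e-12)
})

test_that("the raw forward pass matches hand computation", {
  feats <- c(0.2, -0.1, 0.3, 0, 0.5, -0.2)
  cfg <- cnn_config(conv = list(list(filters = 1L, kernel = 1L)),
                    fc_widths = integer(0), activation = "linear")
  raster <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 9), 3, 3)
  shapes <- pigback:::cnn_shapes(cfg, 3L, 3L, 6L)
  wts <- pigback:::cnn_init_weights(cfg, shapes)
  # all-zero weights: output 0 for any input
  w0 <- wts
  w0$conv[[1]]$W[] <- 0; w0$conv[[1]]$b[] <- 0
  w0$conv[[1]]$beta[] <- 0; w0$conv[[1]]$B[] <- 0
  w0$fc[[1]]$W[] <- 0; w0$fc[[1]]$b[] <- 0
  expect_equal(cnn_forward(raster, feats, cfg, w0), 0)

  # identity 1x1 conv, beta 1, B 0: pooled value = mean of the top-left
  # 2x2 block; output = fc weights applied to [pooled, features]
  w1 <- w0
  w1$conv[[1]]$W[] <- 2; w1$conv[[1]]$b[] <- 0.5
  w1$conv[[1]]$beta[] <- 1
  fcw <- c(0.7, 1, -1, 2, 0.3, -0.5, 1.1)
  w1$fc[[1]]$W <- matrix(fcw, ncol = 1)
  w1$fc[[1]]$b <- 0.25
  pooled <- mean(2 * raster[1:2, 1:2] + 0.5)
  by_hand <- 0.7 * pooled + sum(fcw[-1] * feats) + 0.25
  expect_equal(cnn_forward(raster, feats, cfg, w1), by_hand,
               tolerance = 1e-12)

  # doubling beta doubles the pooled activations (linear, zero biases)
  w2 <- w1
  w2$conv[[1]]$b[] <- 0; w2$fc[[1]]$b <- 0
  base <- cnn_forward(raster, feats * 0, cfg, w2)
  w2$conv[[1]]$beta <- 2 * w2$conv[[1]]$beta
  expect_equal(cnn_forward(raster, feats * 0, cfg, w2), 2 * base,
               tolerance = 1e-12)
})

test_that("training fits a constant target to within 1%", {
  set.seed(6)
  ds <- lapply(1:12, function(i)
    list(raster = matrix(runif(64), 8, 8), features = runif(6),
         weight = 250))
  m <- train_cnn(ds, cnn_config(conv = list(), fc_widths = 8L, lr = 0.05,
                                epochs = 200, seed = 2))
  expect_lt(max(abs(predict(m, ds) - 250) / 250), 0.01)
})

test_that("a features-only model recovers a noiseless linear weight rule", {
  set.seed(1)
  mkrec <- function() {
    f <- runif(6, 0.5, 1.5)
    list(raster = matrix(0, 8, 8), features = f, weight = 300 * f[1])
  }
  ds <- replicate(200, mkrec(), simplify = FALSE)
  m <- train_cnn(ds[1:150], cnn_config(conv = list(), fc_widths = 16L,
                                       lr = 0.1, epochs = 2000, seed = 1))
  ev <- evaluate(predict(m, ds[151:200]),
                 sapply(ds[151:200], function(r) r$weight))
  expect_lt(ev$mape, 2)
  expect_lt(tail(m$loss_history, 1), m$loss_history[1])
})

test_that("training is deterministic given the seed", {
  set.seed(7)
  ds <- lapply(1:10, function(i)
    list(raster = matrix(runif(100), 10, 10), features = runif(6),
         weight = 200 + runif(1, 0, 50)))
  cfg <- cnn_config(conv = list(list(filters = 2L, kernel = 3L)),
                    fc_widths = 4L, lr = 0.01, epochs = 30, seed = 3)
  m1 <- train_cnn(ds, cfg)
  m2 <- train_cnn(ds, cfg)
  expect_identical(m1$loss_history, m2$loss_history)
  expect_identical(m1$weights, m2$weights)
  cfg2 <- cfg; cfg2$seed <- 4L
  m3 <- train_cnn(ds, cfg2)
  expect_false(identical(m1$loss_history, m3$loss_history))
})

test_that("divergence raises an error naming the learning rate", {
  set.seed(8)
  ds <- lapply(1:8, function(i)
    list(raster = matrix(runif(64), 8, 8), features = runif(6),
         weight = runif(1, 190, 300)))
  expect_error(
    train_cnn(ds, cnn_config(conv = list(), fc_widths = 8L, lr = 1e6,
                             epochs = 50, seed = 1)),
    "learning rate", class = "pigback_divergence_error")
})

test_that("the RBF baseline interpolates a 1D toy function", {
  set.seed(9)
  x <- seq(0, 2 * pi, length.out = 50)
  ds <- lapply(x, function(xi) list(features = xi, weight = sin(xi)))
  # 1D Gaussian design matrices are ill-conditioned enough to exercise the
  # documented ridge fallback, which warns
  expect_warning(m <- train_rbf(ds, n_centers = 10, seed = 1), "ridge")
  dense <- seq(0, 2 * pi, length.out = 400)
  pred <- predict(m, lapply(dense, function(xi) list(features = xi)))
  expect_lt(max(abs(pred - sin(dense))), 0.1)

  # interpolation limit: as many centres as records fits almost exactly
  m2 <- suppressWarnings(train_rbf(ds, n_centers = 50, seed = 1))
  pred2 <- predict(m2, ds)
  expect_lt(max(abs(pred2 - sin(x))), 1e-3)

  # seeded centre draw is reproducible
  m3 <- suppressWarnings(train_rbf(ds, n_centers = 10, seed = 1))
  expect_identical(m3$centers, m$centers)
  expect_error(train_rbf(ds[1:5], n_centers = 10),
               class = "pigback_param_error")
})

test_that("evaluation metrics match their definitions", {
  m <- evaluate(c(110, 190), c(100, 200))
  expect_equal(m$mae, 10)
  expect_equal(m$mape, 7.5)
  expect_equal(m$rmse, 10)
  m0 <- evaluate(c(5, 6), c(5, 6))
  expect_equal(unlist(m0[c("mae", "mape", "rmse")]),
               c(mae = 0, mape = 0, rmse = 0))
  set.seed(10)
  for (i in 1:5) {
    p <- runif(20, 150, 350); a <- runif(20, 150, 350)
    mm <- evaluate(p, a)
    expect_gte(mm$rmse, mm$mae)
  }
  expect_error(evaluate(1, c(1, 2)), class = "pigback_param_error")
  expect_error(evaluate(c(1, 2), c(0, 2)), class = "pigback_param_error")
})

test_that("checkpoints round-trip CNN and RBF models exactly", {
  set.seed(11)
  ds <- lapply(1:10, function(i)
    list(raster = matrix(runif(64), 8, 8), features = runif(6),
         weight = runif(1, 190, 300)))
  m <- train_cnn(ds, cnn_config(conv = list(list(filters = 2L, kernel = 3L)),
                                fc_widths = 4L, lr = 0.01, epochs = 20,
                                seed = 5))
  tmp <- tempfile(fileext = ".json")
  save_model(m, tmp)
  m2 <- load_model(tmp)
  expect_equal(predict(m2, ds), predict(m, ds), tolerance = 1e-12)

  rb <- train_rbf(ds, n_centers = 5, seed = 2)
  save_model(rb, tmp)
  rb2 <- load_model(tmp)
  expect_equal(predict(rb2, ds), predict(rb, ds), tolerance = 1e-12)
})
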