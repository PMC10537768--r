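# Weight regression: back height raster + feature vector into a small CNN
# trained by plain gradient descent, with an RBF-network baseline and the
# MAE / MAPE / RMSE evaluation metrics.

#' Rasterize an aligned back cloud into a height grid
#'
#' The x-y bounding rectangle of the cloud is divided into `H` x `W` cells;
#' each cell holds the mean height of its points relative to the cloud's
#' minimum z, and empty cells are 0.
#'
#' @param cloud trimmed aligned [point_cloud()].
#' @param H,W grid size (>= 4 each; default 64 x 64).
#' @return `H` x `W` numeric matrix of class `back_raster` (rows index y,
#'   columns x).
#' @export
rasterize_back <- function(cloud, H = 64L, W = 64L) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (n_points(cloud) == 0L)
    pigback_error("cannot rasterize an empty cloud", "pigback_param_error")
  H <- as.integer(H); W <- as.integer(W)
  if (is.na(H) || is.na(W) || H < 4L || W < 4L)
    pigback_error("raster dimensions must be at least 4 x 4",
                  "pigback_param_error")
  p <- cloud$points
  z <- p[, 3] - min(p[, 3])
  xr <- range(p[, 1]); yr <- range(p[, 2])
  bx <- if (diff(xr) > 0) pmin(W, pmax(1L, ceiling((p[, 1] - xr[1]) /
    diff(xr) * W))) else rep(1L, nrow(p))
  by <- if (diff(yr) > 0) pmin(H, pmax(1L, ceiling((p[, 2] - yr[1]) /
    diff(yr) * H))) else rep(1L, nrow(p))
  bx[p[, 1] == xr[1]] <- 1L
  by[p[, 2] == yr[1]] <- 1L
  cell <- by + (bx - 1L) * H
  f <- factor(cell, levels = sort(unique(cell)))
  means <- rowsum(z, f) / tabulate(f, nbins = nlevels(f))
  m <- matrix(0, H, W)
  m[as.integer(levels(f))] <- means
  structure(m, class = c("back_raster", "matrix"))
}

# ---------------------------------------------------------------------------
# CNN configuration and engine

#' CNN configuration
#'
#' The network applies, per conv block, a valid convolution with bias and
#' activation followed by a non-overlapping 2 x 2 mean pool scaled by a
#' learnable per-channel weight `beta` and bias `B` (then activated); the
#' final maps are flattened, concatenated with the six back features and
#' passed through fully connected layers to a single linear output. With
#' `conv = list()` the model degenerates to a features-only fully connected
#' network.
#'
#' @param conv list of conv layer specs `list(filters =, kernel =)`.
#' @param fc_widths integer vector of hidden fully connected widths (the
#'   final 1-unit linear output layer is implicit).
#' @param activation `"relu"` or `"linear"`.
#' @param lr learning rate of plain gradient descent.
#' @param epochs training epochs (>= 1).
#' @param batch_size minibatch size; `NULL` (default) trains full-batch.
#' @param seed integer seed for weight initialisation (and minibatch
#'   shuffling when used).
#' @return list of class `cnn_config`.
#' @export
cnn_config <- function(conv = list(list(filters = 8L, kernel = 3L),
                                   list(filters = 16L, kernel = 3L)),
                       fc_widths = 64L,
                       activation = c("relu", "linear"),
                       lr = 0.005, epochs = 300L, batch_size = NULL,
                       seed = 1L) {
  activation <- match.arg(activation)
  epochs <- as.integer(epochs)
  if (is.na(epochs) || epochs < 1L)
    pigback_error("epochs must be >= 1", "pigback_param_error")
  if (!is.finite(lr) || lr <= 0)
    pigback_error("learning rate must be positive", "pigback_param_error")
  for (cv in conv) {
    if (!all(c("filters", "kernel") %in% names(cv)) ||
        cv$filters < 1L || cv$kernel < 1L)
      pigback_error("conv specs need positive filters and kernel",
                    "pigback_param_error")
  }
  structure(list(conv = conv, fc_widths = as.integer(fc_widths),
                 activation = activation, lr = lr, epochs = epochs,
                 batch_size = if (is.null(batch_size)) NULL else
                   as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "cnn_config")
}

.act <- function(u, kind) if (kind == "relu") pmax(u, 0) else u
.act_grad <- function(u, kind) if (kind == "relu") (u > 0) * 1 else
  array(1, dim(u))

# spatial bookkeeping: per conv block the im2col gather index (P x k^2*C,
# 1-based into an H*W*C sample) and the 2x2 mean-pool gather (Po x 4 into P)
cnn_shapes <- function(config, H, W, n_feat) {
  shapes <- list()
  h <- H; w <- W; cin <- 1L
  for (li in seq_along(config$conv)) {
    k <- as.integer(config$conv[[li]]$kernel)
    f <- as.integer(config$conv[[li]]$filters)
    ph <- h - k + 1L; pw <- w - k + 1L
    if (ph < 1L || pw < 1L)
      pigback_error("raster too small for the configured conv stack",
                    "pigback_config_error")
    # position (i, j) of the output map, offsets (di, dj), channel c
    pos_i <- rep(seq_len(ph), times = pw)
    pos_j <- rep(seq_len(pw), each = ph)
    fidx <- matrix(0L, ph * pw, k * k * cin)
    q <- 0L
    for (cc in seq_len(cin)) for (dj in seq_len(k)) for (di in seq_len(k)) {
      q <- q + 1L
      fidx[, q] <- (pos_i + di - 1L) + ((pos_j + dj - 1L) - 1L) * h +
        (cc - 1L) * h * w
    }
    oh <- ph %/% 2L; ow <- pw %/% 2L
    if (oh < 1L || ow < 1L)
      pigback_error("raster too small for the configured pooling",
                    "pigback_config_error")
    oi <- rep(seq_len(oh), times = ow)
    oj <- rep(seq_len(ow), each = oh)
    pool <- cbind((2L * oi - 1L) + (2L * oj - 2L) * ph,
                  (2L * oi) + (2L * oj - 2L) * ph,
                  (2L * oi - 1L) + (2L * oj - 1L) * ph,
                  (2L * oi) + (2L * oj - 1L) * ph)
    shapes[[li]] <- list(k = k, filters = f, cin = cin, conv_h = ph,
                         conv_w = pw, out_h = oh, out_w = ow,
                         fidx = fidx, pool = pool)
    h <- oh; w <- ow; cin <- f
  }
  flat <- if (length(config$conv)) h * w * cin else 0L
  list(conv = shapes, flat = flat, n_input = flat + n_feat,
       raster_h = H, raster_w = W, n_feat = n_feat)
}

cnn_init_weights <- function(config, shapes) {
  with_seed(config$seed, {
    conv <- lapply(shapes$conv, function(s) {
      fan_in <- s$k ^ 2 * s$cin
      list(W = matrix(rnorm(fan_in * s$filters, 0, sqrt(2 / fan_in)),
                      fan_in, s$filters),
           b = numeric(s$filters),
           beta = rep(1, s$filters), B = numeric(s$filters))
    })
    widths <- c(shapes$n_input, config$fc_widths, 1L)
    fc <- lapply(seq_len(length(widths) - 1L), function(i) {
      list(W = matrix(rnorm(widths[i] * widths[i + 1L], 0,
                            sqrt(2 / widths[i])), widths[i], widths[i + 1L]),
           b = numeric(widths[i + 1L]))
    })
    list(conv = conv, fc = fc)
  })
}

# forward pass over a batch; rasters as N x (H*W), features as N x n_feat
cnn_forward_batch <- function(rasters, feats, config, weights, shapes,
                              cache = FALSE) {
  N <- nrow(feats)
  act <- config$activation
  caches <- list()
  A <- rasters
  for (li in seq_along(shapes$conv)) {
    s <- shapes$conv[[li]]
    w <- weights$conv[[li]]
    P <- s$conv_h * s$conv_w
    X <- A[, as.vector(s$fidx), drop = FALSE]
    dim(X) <- c(N * P, ncol(s$fidx))
    U <- X %*% w$W
    U <- sweep(U, 2L, w$b, "+")
    Achv <- .act(U, act)                       # (N*P) x F
    M <- array(Achv, c(N, P, s$filters))
    Po <- s$out_h * s$out_w
    pool_raw <- (M[, s$pool[, 1], , drop = FALSE] +
                 M[, s$pool[, 2], , drop = FALSE] +
                 M[, s$pool[, 3], , drop = FALSE] +
                 M[, s$pool[, 4], , drop = FALSE]) / 4
    Upool <- sweep(sweep(pool_raw, 3L, w$beta, "*"), 3L, w$B, "+")
    Apool <- .act(Upool, act)
    if (cache)
      caches[[li]] <- list(X = X, U = U, pool_raw = pool_raw, Upool = Upool,
                           P = P, Po = Po)
    A <- matrix(Apool, N, Po * s$filters)
  }
  z <- if (length(shapes$conv)) cbind(A, feats) else feats
  fc_caches <- list()
  nl <- length(weights$fc)
  for (i in seq_len(nl)) {
    w <- weights$fc[[i]]
    u <- sweep(z %*% w$W, 2L, w$b, "+")
    a <- if (i < nl) .act(u, act) else u       # final layer linear
    if (cache) fc_caches[[i]] <- list(z = z, u = u)
    z <- a
  }
  out <- as.vector(z)
  if (cache) list(out = out, conv = caches, fc = fc_caches) else out
}

cnn_backward_batch <- function(rasters, feats, y, config, weights, shapes) {
  N <- nrow(feats)
  act <- config$activation
  fw <- cnn_forward_batch(rasters, feats, config, weights, shapes,
                          cache = TRUE)
  pred <- fw$out
  loss <- mean((pred - y) ^ 2)
  grads <- list(conv = vector("list", length(weights$conv)),
                fc = vector("list", length(weights$fc)))
  dz <- matrix(2 * (pred - y) / N, N, 1L)
  for (i in rev(seq_along(weights$fc))) {
    cc <- fw$fc[[i]]
    du <- if (i < length(weights$fc)) dz * .act_grad(cc$u, act) else dz
    grads$fc[[i]] <- list(W = crossprod(cc$z, du), b = colSums(du))
    dz <- du %*% t(weights$fc[[i]]$W)
  }
  if (length(weights$conv)) {
    s_last <- shapes$conv[[length(shapes$conv)]]
    flat <- s_last$out_h * s_last$out_w * s_last$filters
    dA <- dz[, seq_len(flat), drop = FALSE]     # gradient w.r.t. pooled maps
    for (li in rev(seq_along(weights$conv))) {
      s <- shapes$conv[[li]]
      w <- weights$conv[[li]]
      cc <- fw$conv[[li]]
      dApool <- array(dA, c(N, cc$Po, s$filters))
      dUpool <- dApool * .act_grad(cc$Upool, act)
      gbeta <- apply(dUpool * cc$pool_raw, 3L, sum)
      gB <- apply(dUpool, 3L, sum)
      dpool <- sweep(dUpool, 3L, w$beta, "*")
      dM <- array(0, c(N, cc$P, s$filters))
      for (j in 1:4)
        dM[, s$pool[, j], ] <- dM[, s$pool[, j], , drop = FALSE] + dpool / 4
      dAchv <- matrix(dM, N * cc$P, s$filters)
      dU <- dAchv * .act_grad(cc$U, act)
      gW <- crossprod(cc$X, dU)
      gb <- colSums(dU)
      grads$conv[[li]] <- list(W = gW, b = gb, beta = gbeta, B = gB)
      if (li > 1L) {
        dX <- dU %*% t(w$W)                     # (N*P) x k^2*C
        dim(dX) <- c(N, cc$P * ncol(cc$X))
        grp <- as.vector(shapes$conv[[li]]$fidx)
        acc <- rowsum(t(dX), group = grp)       # sums duplicate gathers
        s_prev <- shapes$conv[[li - 1L]]
        full <- s_prev$out_h * s_prev$out_w * s_prev$filters
        dA_prev <- matrix(0, N, full)
        dA_prev[, as.integer(rownames(acc))] <- t(acc)
        dA <- dA_prev
      }
    }
  }
  list(loss = loss, grads = grads)
}

cnn_apply_grads <- function(weights, grads, lr) {
  for (li in seq_along(weights$conv)) {
    g <- grads$conv[[li]]
    weights$conv[[li]]$W <- weights$conv[[li]]$W - lr * g$W
    weights$conv[[li]]$b <- weights$conv[[li]]$b - lr * g$b
    weights$conv[[li]]$beta <- weights$conv[[li]]$beta - lr * g$beta
    weights$conv[[li]]$B <- weights$conv[[li]]$B - lr * g$B
  }
  for (i in seq_along(weights$fc)) {
    g <- grads$fc[[i]]
    weights$fc[[i]]$W <- weights$fc[[i]]$W - lr * g$W
    weights$fc[[i]]$b <- weights$fc[[i]]$b - lr * g$b
  }
  weights
}

#' Raw CNN forward pass for one sample
#'
#' Applies the network defined by `config` and `weights` to one raster and
#' feature vector without any input or output normalisation (the trained
#' model's [predict()] method handles normalisation). With all-zero weights
#' the output is 0 for any input.
#'
#' @param raster `H` x `W` height raster.
#' @param features numeric vector of the six back features.
#' @param config a [cnn_config()].
#' @param weights weight list shaped as produced during training.
#' @return scalar network output.
#' @export
cnn_forward <- function(raster, features, config, weights) {
  stopifnot(inherits(config, "cnn_config"))
  features <- as.numeric(features)
  shapes <- cnn_shapes(config, nrow(raster), ncol(raster), length(features))
  .check_weight_shapes(weights, shapes)
  cnn_forward_batch(matrix(as.numeric(raster), 1L),
                    matrix(features, 1L), config, weights, shapes)
}

.check_weight_shapes <- function(weights, shapes) {
  if (length(weights$conv) != length(shapes$conv))
    pigback_error("weights do not match the configured conv stack",
                  "pigback_config_error")
  for (li in seq_along(shapes$conv)) {
    s <- shapes$conv[[li]]
    if (!all(dim(weights$conv[[li]]$W) == c(s$k ^ 2 * s$cin, s$filters)))
      pigback_error(sprintf("conv layer %d weight shape mismatch", li),
                    "pigback_config_error")
  }
  if (nrow(weights$fc[[1]]$W) != shapes$n_input)
    pigback_error("fully connected input width mismatch",
                  "pigback_config_error")
  invisible(TRUE)
}

#' Train the CNN weight regressor
#'
#' Rasters (globally) and features (per column) are z-score standardised, as
#' is the target weight; all are restored at prediction. Optimisation is
#' plain gradient descent on the mean-squared error at the configured rate,
#' deterministic given the config seed.
#'
#' @param dataset list of records `list(raster =, features =, weight =)`,
#'   at least 2.
#' @param config a [cnn_config()].
#' @return object of class `pigback_cnn` with the learned weights,
#'   normalisation constants and per-epoch `loss_history`.
#' @export
train_cnn <- function(dataset, config = cnn_config()) {
  stopifnot(inherits(config, "cnn_config"))
  if (length(dataset) < 2L)
    pigback_error("need at least 2 training records", "pigback_param_error")
  H <- nrow(dataset[[1]]$raster); W <- ncol(dataset[[1]]$raster)
  rasters <- t(vapply(dataset, function(r) as.numeric(r$raster),
                      numeric(H * W)))
  nf <- length(dataset[[1]]$features)
  feats <- matrix(vapply(dataset, function(r) as.numeric(r$features),
                         numeric(nf)), ncol = nf, byrow = TRUE)
  y <- vapply(dataset, function(r) as.numeric(r$weight), numeric(1L))

  rm_ <- mean(rasters); rs_ <- sd(as.vector(rasters)); if (rs_ == 0) rs_ <- 1
  fm_ <- colMeans(feats)
  fs_ <- apply(feats, 2L, sd); fs_[fs_ == 0] <- 1
  ym_ <- mean(y); ys_ <- sd(y); if (ys_ == 0) ys_ <- 1
  rn <- (rasters - rm_) / rs_
  fn <- sweep(sweep(feats, 2L, fm_), 2L, fs_, "/")
  yn <- (y - ym_) / ys_

  shapes <- cnn_shapes(config, H, W, ncol(feats))
  weights <- cnn_init_weights(config, shapes)
  N <- length(y)
  bs <- if (is.null(config$batch_size)) N else min(config$batch_size, N)
  loss_history <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- if (bs < N)
      with_seed(config$seed + ep, sample.int(N)) else seq_len(N)
    ep_loss <- 0
    for (start in seq(1L, N, by = bs)) {
      sel <- ord[start:min(start + bs - 1L, N)]
      bw <- cnn_backward_batch(rn[sel, , drop = FALSE],
                               fn[sel, , drop = FALSE], yn[sel],
                               config, weights, shapes)
      if (!is.finite(bw$loss))
        pigback_error(sprintf(
          "training diverged (non-finite loss); lower the learning rate %g",
          config$lr), "pigback_divergence_error")
      weights <- cnn_apply_grads(weights, bw$grads, config$lr)
      ep_loss <- ep_loss + bw$loss * length(sel)
    }
    loss_history[ep] <- ep_loss / N
  }
  structure(list(config = config, weights = weights, shapes = shapes,
                 norms = list(raster_mean = rm_, raster_sd = rs_,
                              feat_mean = fm_, feat_sd = fs_,
                              y_mean = ym_, y_sd = ys_),
                 loss_history = loss_history),
            class = "pigback_cnn")
}

#' Predict weights with a trained CNN
#'
#' @param object a [train_cnn()] model.
#' @param newdata list of records with `raster` and `features`.
#' @param ... unused.
#' @return numeric vector of predicted weights, kg.
#' @export
predict.pigback_cnn <- function(object, newdata, ...) {
  H <- object$shapes$raster_h; W <- object$shapes$raster_w
  rasters <- t(vapply(newdata, function(r) as.numeric(r$raster),
                      numeric(H * W)))
  nf <- object$shapes$n_feat
  feats <- matrix(vapply(newdata, function(r) as.numeric(r$features),
                         numeric(nf)), ncol = nf, byrow = TRUE)
  nm <- object$norms
  rn <- (rasters - nm$raster_mean) / nm$raster_sd
  fn <- sweep(sweep(feats, 2L, nm$feat_mean), 2L, nm$feat_sd, "/")
  out <- cnn_forward_batch(rn, fn, object$config, object$weights,
                           object$shapes)
  out * nm$y_sd + nm$y_mean
}

#' @export
print.pigback_cnn <- function(x, ...) {
  cat(sprintf(
    "<pigback_cnn: %d conv block(s), fc widths %s, final loss %.4g>\n",
    length(x$config$conv), paste(x$config$fc_widths, collapse = "/"),
    tail(x$loss_history, 1L)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# RBF baseline

#' Train the RBF-network baseline
#'
#' Gaussian hidden units with centres drawn (seeded) from the training
#' feature vectors, unit width set to the median pairwise centre distance,
#' and output weights fitted by linear least squares (ridge fallback with a
#' warning when the system is singular).
#'
#' @param dataset list of records `list(features =, weight =)`.
#' @param n_centers number of hidden units (<= number of records).
#' @param seed integer seed for the centre draw.
#' @return object of class `pigback_rbf`.
#' @export
train_rbf <- function(dataset, n_centers = 20L, seed = 1L) {
  n_centers <- as.integer(n_centers)
  if (length(dataset) < n_centers)
    pigback_error("need at least n_centers training records",
                  "pigback_param_error")
  nf <- length(dataset[[1]]$features)
  feats <- matrix(vapply(dataset, function(r) as.numeric(r$features),
                         numeric(nf)), ncol = nf, byrow = TRUE)
  y <- vapply(dataset, function(r) as.numeric(r$weight), numeric(1L))
  fm_ <- colMeans(feats)
  fs_ <- apply(feats, 2L, sd); fs_[fs_ == 0] <- 1
  fn <- sweep(sweep(feats, 2L, fm_), 2L, fs_, "/")
  idx <- with_seed(seed, sample.int(nrow(fn), n_centers))
  centers <- fn[idx, , drop = FALSE]
  dd <- as.vector(dist(centers))
  width <- if (length(dd) && median(dd) > 0) median(dd) else 1
  Phi <- cbind(1, .rbf_design(fn, centers, width))
  coefs <- tryCatch({
    qr_ <- qr(Phi)
    if (qr_$rank < ncol(Phi)) stop("rank deficient")
    qr.coef(qr_, y)
  }, error = function(e) {
    warning("singular least-squares system; using ridge fallback",
            call. = FALSE)
    solve(crossprod(Phi) + 1e-8 * diag(ncol(Phi)), crossprod(Phi, y))
  })
  structure(list(centers = centers, width = width,
                 coefs = as.numeric(coefs),
                 norms = list(feat_mean = fm_, feat_sd = fs_)),
            class = "pigback_rbf")
}

.rbf_design <- function(fn, centers, width) {
  d2 <- outer(rowSums(fn ^ 2), rowSums(centers ^ 2), "+") -
    2 * fn %*% t(centers)
  exp(-pmax(d2, 0) / (2 * width ^ 2))
}

#' Predict weights with a trained RBF network
#'
#' @param object a [train_rbf()] model.
#' @param newdata list of records with `features`.
#' @param ... unused.
#' @return numeric vector of predicted weights, kg.
#' @export
predict.pigback_rbf <- function(object, newdata, ...) {
  nf <- ncol(object$centers)
  feats <- matrix(vapply(newdata, function(r) as.numeric(r$features),
                         numeric(nf)), ncol = nf, byrow = TRUE)
  fn <- sweep(sweep(feats, 2L, object$norms$feat_mean), 2L,
              object$norms$feat_sd, "/")
  Phi <- cbind(1, .rbf_design(fn, object$centers, object$width))
  as.vector(Phi %*% object$coefs)
}

# ---------------------------------------------------------------------------
# evaluation metrics

#' Weight-estimation error metrics
#'
#' Mean absolute error, mean absolute percentage error and root mean square
#' error between estimated and actual weights.
#'
#' @param estimates,actuals equal-length numeric vectors, kg; actuals must be
#'   strictly positive (the percentage error is otherwise undefined).
#' @return list of class `eval_metrics` with `mae` (kg), `mape` (%) and
#'   `rmse` (kg).
#' @export
evaluate <- function(estimates, actuals) {
  if (length(estimates) != length(actuals) || length(actuals) == 0L)
    pigback_error("estimates and actuals must have equal non-zero length",
                  "pigback_param_error")
  if (any(actuals == 0))
    pigback_error("actual weight of 0: percentage error undefined",
                  "pigback_param_error")
  err <- estimates - actuals
  structure(list(mae = mean(abs(err)),
                 mape = mean(abs(err) / actuals) * 100,
                 rmse = sqrt(mean(err ^ 2))),
            class = "eval_metrics")
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf("MAE %.3f kg | MAPE %.3f%% | RMSE %.3f kg\n",
              x$mae, x$mape, x$rmse))
  invisible(x)
}

# ---------------------------------------------------------------------------
# checkpoints

#' Save a trained model to a JSON checkpoint
#'
#' The checkpoint echoes the configuration and stores all weight arrays and
#' normalisation constants at full precision.
#'
#' @param model a `pigback_cnn` or `pigback_rbf` model.
#' @param path output path.
#' @export
save_model <- function(model, path) {
  ser_mat <- function(m) list(data = as.numeric(m), dim = dim(m))
  if (inherits(model, "pigback_cnn")) {
    payload <- list(
      type = "cnn",
      config = list(conv = model$config$conv,
                    fc_widths = model$config$fc_widths,
                    activation = model$config$activation,
                    lr = model$config$lr, epochs = model$config$epochs,
                    seed = model$config$seed),
      raster = list(H = model$shapes$raster_h, W = model$shapes$raster_w),
      norms = model$norms,
      conv = lapply(model$weights$conv, function(w)
        list(W = ser_mat(w$W), b = w$b, beta = w$beta, B = w$B)),
      fc = lapply(model$weights$fc, function(w)
        list(W = ser_mat(w$W), b = w$b)),
      loss_history = model$loss_history)
  } else if (inherits(model, "pigback_rbf")) {
    payload <- list(type = "rbf", centers = ser_mat(model$centers),
                    width = model$width, coefs = model$coefs,
                    norms = model$norms)
  } else stop("unknown model type")
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model checkpoint written by [save_model()]
#'
#' @param path checkpoint path.
#' @return a `pigback_cnn` or `pigback_rbf` model.
#' @export
load_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  num <- function(v) as.numeric(unlist(v))
  de_mat <- function(m) matrix(num(m$data), m$dim[[1]], m$dim[[2]])
  if (identical(x$type, "cnn")) {
    conv_spec <- lapply(x$config$conv, function(cv)
      list(filters = as.integer(cv$filters), kernel = as.integer(cv$kernel)))
    config <- cnn_config(conv = conv_spec,
                         fc_widths = as.integer(unlist(x$config$fc_widths)),
                         activation = x$config$activation,
                         lr = x$config$lr,
                         epochs = x$config$epochs, seed = x$config$seed)
    weights <- list(
      conv = lapply(x$conv, function(w)
        list(W = de_mat(w$W), b = num(w$b), beta = num(w$beta),
             B = num(w$B))),
      fc = lapply(x$fc, function(w) list(W = de_mat(w$W), b = num(w$b))))
    norms <- lapply(x$norms, num)
    shapes <- cnn_shapes(config, as.integer(x$raster$H),
                         as.integer(x$raster$W), length(norms$feat_mean))
    structure(list(config = config, weights = weights, shapes = shapes,
                   norms = norms, loss_history = num(x$loss_history)),
              class = "pigback_cnn")
  } else if (identical(x$type, "rbf")) {
    structure(list(centers = de_mat(x$centers), width = num(x$width),
                   coefs = num(x$coefs),
                   norms = lapply(x$norms, num)),
              class = "pigback_rbf")
  } else stop("unknown checkpoint type")
}
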