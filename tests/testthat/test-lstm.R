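zero_weights <- function(input_dim, units) {
  z <- function(r, c) matrix(0, r, c)
  list(W_i = z(input_dim, units), W_f = z(input_dim, units),
       W_o = z(input_dim, units), W_c = z(input_dim, units),
       U_i = z(units, units), U_f = z(units, units),
       U_o = z(units, units), U_c = z(units, units),
       b_i = rep(0, units), b_f = rep(0, units), b_o = rep(0, units),
       b_c = rep(0, units))
}

test_that("cell step with zero weights keeps zero state", {
  w <- zero_weights(3, 2)
  st <- lstm_cell_step(c(1, -2, 5), list(c = c(0, 0), h = c(0, 0)), w)
  expect_equal(st$c, c(0, 0))   # gates are 0.5 but candidate tanh(0) = 0
  expect_equal(st$h, c(0, 0))
})

test_that("scalar cell with saturated candidate matches the hand calculation", {
  w <- zero_weights(1, 1)
  w$b_c <- 20  # candidate tanh(20) ~ 1; gates stay at sigmoid(0) = 0.5
  st <- lstm_cell_step(0.3, list(c = 0, h = 0), w)
  expect_equal(st$c, 0.5, tolerance = 1e-6)
  expect_equal(st$h, 0.5 * tanh(0.5), tolerance = 1e-6)
})

test_that("compiled forward equals the naive recurrence on random instances", {
  set.seed(21)
  for (rep in seq_len(100)) {
    nf <- sample(2:5, 1)
    cfg <- lstm_config(n_layers = sample(1:3, 1), units = sample(2:6, 1),
                       seed = rep)
    p <- lstm_init(nf, cfg)
    x <- matrix(rnorm(sample(2:8, 1) * nf, sd = 1.5), ncol = nf)
    expect_equal(
      lstm_forward(list(params = p, n_features = nf, config = cfg), x),
      lstm_forward_naive(x, p, cfg),
      tolerance = 1e-10
    )
  }
})

test_that("a zero-weight stack outputs probability one half at every hour", {
  cfg <- lstm_config(n_layers = 2, units = 4, seed = 1)
  p <- numeric(length(lstm_init(6, cfg)))
  probs <- lstm_forward(list(params = p, n_features = 6, config = cfg),
                        matrix(rnorm(30), 5, 6))
  expect_equal(probs, rep(0.5, 5))
})

test_that("outputs are causal: future inputs never change past outputs", {
  set.seed(5)
  cfg <- lstm_config(n_layers = 2, units = 8, seed = 5)
  p <- lstm_init(4, cfg)
  model <- list(params = p, n_features = 4, config = cfg)
  x <- matrix(rnorm(40), 10, 4)
  base <- lstm_forward(model, x)
  for (cut in c(3, 6, 9)) {
    y <- x
    y[(cut + 1):10, ] <- rnorm(length(y[(cut + 1):10, ]), sd = 5)
    perturbed <- lstm_forward(model, y)
    expect_equal(perturbed[1:cut], base[1:cut], tolerance = 1e-12)
    # and truncation reproduces the prefix exactly
    expect_equal(lstm_forward(model, x[1:cut, , drop = FALSE]), base[1:cut])
  }
})

test_that("hidden states stay inside (-1, 1)", {
  set.seed(6)
  w <- zero_weights(3, 4)
  for (nm in names(w)) w[[nm]] <- w[[nm]] + rnorm(length(w[[nm]]), sd = 2)
  st <- list(c = rep(0, 4), h = rep(0, 4))
  for (t in 1:20) {
    st <- lstm_cell_step(rnorm(3, sd = 3), st, w)
    expect_true(all(abs(st$h) < 1))
  }
})

test_that("permuting features with matching first-layer rows is invariant", {
  set.seed(8)
  cfg <- lstm_config(n_layers = 2, units = 5, seed = 8)
  nf <- 6
  p <- lstm_init(nf, cfg)
  x <- matrix(rnorm(48), 8, nf)
  perm <- sample(nf)
  p2 <- p
  W1 <- matrix(p[seq_len(nf * 4 * cfg$units)], nrow = nf)
  p2[seq_len(nf * 4 * cfg$units)] <- as.numeric(W1[perm, ])
  m1 <- list(params = p, n_features = nf, config = cfg)
  m2 <- list(params = p2, n_features = nf, config = cfg)
  expect_equal(lstm_forward(m2, x[, perm]), lstm_forward(m1, x),
               tolerance = 1e-12)
})

test_that("analytic gradients match finite differences", {
  set.seed(31)
  cfg <- lstm_config(n_layers = 2, units = 4, seed = 31)
  nf <- 3
  p <- lstm_init(nf, cfg)
  xs <- list(matrix(rnorm(15), 5, 3), matrix(rnorm(9), 3, 3))
  ys <- list(rep(1, 5), rep(0, 3))
  ws <- list(rep(3, 5), rep(1, 3))
  f <- function(par) {
    shockcast:::cpp_lstm_loss_grad(xs, ys, ws, par, nf, cfg$n_layers,
                                   cfg$units, 0)
  }
  g <- as.numeric(f(p)$grad)
  eps <- 1e-6
  ks <- sample(length(p), 40)
  num <- vapply(ks, function(k) {
    up <- p; up[k] <- up[k] + eps
    dn <- p; dn[k] <- dn[k] - eps
    (f(up)$loss - f(dn)$loss) / (2 * eps)
  }, 0)
  expect_equal(g[ks], num, tolerance = 1e-5)
})

test_that("the full-scale configuration builds and takes a training step", {
  cfg <- lstm_config()  # 4 x 100 units, dropout 0.4, positive weight 3
  expect_identical(cfg$n_layers, 4L)
  expect_identical(cfg$units, 100L)
  expect_identical(cfg$epochs, 1000L)
  expect_identical(cfg$batches_per_epoch, 40L)
  expect_identical(cfg$batch_size, 50L)
  expect_equal(cfg$positive_weight, 3)
  set.seed(77)
  p <- lstm_init(31, cfg)
  x <- matrix(rnorm(31 * 6), 6, 31)
  lg <- shockcast:::cpp_lstm_loss_grad(list(x), list(rep(1, 6)),
                                       list(rep(3, 6)), p, 31L, cfg$n_layers,
                                       cfg$units, cfg$dropout_p)
  expect_true(is.finite(lg$loss))
  expect_length(as.numeric(lg$grad), length(p))
})

make_drift_set <- function(n, t_len = 15, nf = 3, seed = 1) {
  set.seed(seed)
  y <- rep(c(TRUE, FALSE), length.out = n)
  x <- lapply(seq_len(n), function(i) {
    base <- matrix(rnorm(t_len * nf, sd = 0.7), t_len, nf)
    if (y[i]) base[, 1] <- base[, 1] + seq(0, 2.5, length.out = t_len)
    base
  })
  list(x = x, y = y)
}

test_that("training is deterministic, learnable, and loss trends down", {
  d <- make_drift_set(40, seed = 3)
  cfg <- lstm_config(n_layers = 1, units = 8, dropout_p = 0.1, epochs = 15,
                     batches_per_epoch = 4, batch_size = 10,
                     learning_rate = 0.02, validation_interval = 5, seed = 4)
  fit1 <- lstm_train(d$x, d$y, config = cfg)
  fit2 <- lstm_train(d$x, d$y, config = cfg)
  expect_identical(fit1$params, fit2$params)
  smooth <- function(v) stats::filter(v, rep(1 / 5, 5), sides = 1)
  sl <- as.numeric(smooth(fit1$log$loss))
  expect_lt(sl[length(sl)], sl[5])
  final_auc <- fit1$log$train_auroc[nrow(fit1$log)]
  expect_gt(final_auc, 0.9)
  # prediction is a pure function; batch equals per-sequence calls
  pr_a <- predict(fit1, d$x)
  pr_b <- lapply(d$x, function(m) predict(fit1, m))
  expect_identical(pr_a, pr_b)
  expect_identical(predict(fit1, d$x[[1]]), predict(fit1, d$x[[1]]))
  expect_error(predict(fit1, d$x[[1]][, 1:2]), "features")
  expect_error(lstm_train(d$x, rep(TRUE, 40), config = cfg), "both")
})

test_that("upweighting positives buys recall at matched specificity", {
  set.seed(12)
  n <- 60
  y <- rep(c(TRUE, FALSE, FALSE, FALSE), length.out = n)  # imbalanced
  x <- lapply(seq_len(n), function(i) {
    base <- matrix(rnorm(12 * 3, sd = 1), 12, 3)
    if (y[i]) base[, 1] <- base[, 1] + seq(0, 1.5, length.out = 12)
    base
  })
  train <- function(w) {
    cfg <- lstm_config(n_layers = 1, units = 8, dropout_p = 0, epochs = 12,
                       batches_per_epoch = 4, batch_size = 15,
                       learning_rate = 0.02, positive_weight = w,
                       validation_interval = 12, seed = 9)
    fit <- lstm_train(x, y, config = cfg)
    vapply(predict(fit, x), max, 0)
  }
  s1 <- train(1)
  s3 <- train(3)
  # operating point: the threshold rejecting 90% of negatives in each model
  spec_thr <- function(s) quantile(s[!y], 0.9)
  recall <- function(s) mean(s[y] >= spec_thr(s))
  expect_gte(recall(s3), recall(s1))
})

test_that("checkpoints round-trip through the JSON container", {
  d <- make_drift_set(20, seed = 15)
  cfg <- lstm_config(n_layers = 1, units = 6, dropout_p = 0, epochs = 3,
                     batches_per_epoch = 2, batch_size = 10,
                     validation_interval = 3, seed = 2)
  fit <- lstm_train(d$x, d$y, config = cfg,
                    features = paste0("f", 1:3))
  path <- tempfile(fileext = ".json")
  save_model(fit, path)
  back <- load_model(path)
  expect_equal(back$params, fit$params)
  expect_identical(back$config$units, fit$config$units)
  expect_equal(predict(back, d$x[[1]]), predict(fit, d$x[[1]]))
  expect_error(load_model(system.file("DESCRIPTION", package = "shockcast")))
})
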