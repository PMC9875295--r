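test_that("exact-design RBF interpolates its calibration data at any spread", {
  set.seed(1)
  X <- matrix(rnorm(12 * 4), 12, 4)
  y <- rnorm(12, mean = 3)
  for (spread in c(0.1, 0.5, 1, 5)) {
    m <- rbf_train(X, y, spread)
    expect_lt(rmse(y, predict(m, X)), 1e-6)
  }
  # single calibration sample fits that point exactly
  m1 <- rbf_train(X[1, , drop = FALSE], y[1], 0.5)
  expect_equal(predict(m1, X[1, , drop = FALSE]), y[1], tolerance = 1e-9)
})

test_that("RBF weights match a hand minimum-norm solve on two samples", {
  X <- matrix(c(0, 1), 2, 1)
  y <- c(1, 3)
  spread <- 0.7
  m <- rbf_train(X, y, spread)
  a <- exp(-(0.8326 / spread)^2 * 1)  # cross-activation at distance 1
  M <- rbind(c(1, a, 1), c(a, 1, 1))  # [A; 1] design, rows = samples
  wb <- MASS::ginv(M) %*% y           # independent minimum-norm least squares
  expect_equal(c(m$weights, m$bias), as.numeric(wb), tolerance = 1e-8)
  expect_equal(predict(m, X), y, tolerance = 1e-8)
})

test_that("RBF predictions are local, continuous in spread, and symmetric", {
  set.seed(2)
  X <- matrix(rnorm(8 * 3), 8, 3)
  y <- rnorm(8, 3)
  # tiny spread: predicting at a centre recovers that centre's target
  m_small <- rbf_train(X, y, 1e-3)
  expect_equal(predict(m_small, X), y, tolerance = 1e-6)
  # continuity in the spread parameter
  p1 <- predict(rbf_train(X, y, 0.600), X[1:2, ])
  p2 <- predict(rbf_train(X, y, 0.601), X[1:2, ])
  expect_lt(max(abs(p1 - p2)), 0.05)
  # permuting the calibration order leaves predictions unchanged
  perm <- c(5, 2, 8, 1, 7, 3, 6, 4)
  mp <- rbf_train(X[perm, ], y[perm], 0.5)
  m0 <- rbf_train(X, y, 0.5)
  Xnew <- matrix(rnorm(9), 3, 3)
  expect_equal(predict(mp, Xnew), predict(m0, Xnew), tolerance = 1e-7)
  expect_error(predict(m0, Xnew[, 1:2]), "features")
  expect_error(rbf_train(X, y, 0), "spread")
})

test_that("spread sweep rows match independent retraining", {
  set.seed(3)
  X <- matrix(rnorm(10 * 3), 10, 3)
  y <- rnorm(10, 3)
  sw <- rbf_spread_sweep(X, y)
  expect_equal(sw$table$spread, seq(0.1, 1, by = 0.1))
  for (k in c(1, 5, 10)) {
    m <- rbf_train(X, y, sw$table$spread[k])
    expect_equal(sw$table$rmsec[k], rmse(y, predict(m, X)), tolerance = 1e-12)
  }
  one <- rbf_spread_sweep(X, y, spreads = 0.4)
  expect_equal(nrow(one$table), 1)
  expect_equal(one$best_spread, 0.4)
})

test_that("BPNN learns an easy linear map and trains deterministically", {
  X <- matrix(seq(-2, 2, length.out = 40))
  y <- as.numeric(1.5 - 2 * X)
  m <- bpnn_train(X, y, max_epochs = 5000, seed = 3)
  expect_gte(r_squared(y, predict(m, X)), 0.99)

  # same seed, same weights; different seed may differ
  m2 <- bpnn_train(X, y, max_epochs = 50, seed = 3)
  m3 <- bpnn_train(X, y, max_epochs = 50, seed = 3)
  expect_identical(m2$W1, m3$W1)
  expect_identical(m2$W2, m3$W2)

  # descent: loss non-increasing under a small learning rate
  m4 <- bpnn_train(X, y, learning_rate = 0.001, max_epochs = 300, seed = 1)
  expect_true(all(diff(m4$loss_trace) <= 1e-12))

  expect_error(bpnn_train(X, rep(1, 40)), "constant")
  expect_error(bpnn_train(X, y, hidden_size = 0), "hidden_size")
})

test_that("BPNN forward pass matches hand arithmetic for one hidden unit", {
  model <- structure(list(
    W1 = matrix(0.5), b1 = 0.1, W2 = 2, b2 = -0.3,
    input_scaler = list(lo = 0, rng = 2),   # maps [0, 2] to [-1, 1]
    output_scaler = list(lo = 1, rng = 4),  # maps [-1, 1] back to [1, 5]
    hidden_size = 1, learning_rate = 0.01, loss_trace = 0, seed = 1),
    class = "bpnn_model")
  x <- 1.5
  xs <- (x - 0) / 2 * 2 - 1              # 0.5
  hand <- (2 * tanh(0.5 * xs + 0.1) - 0.3 + 1) / 2 * 4 + 1
  expect_equal(predict(model, matrix(x)), hand, tolerance = 1e-12)
  expect_error(predict(model, matrix(1, 1, 2)), "features")
})

test_that("evaluate_model reports the four metrics of a split evaluation", {
  cfg <- tiny_config(seed = 9, noise_sd = 0)
  d <- generate_spectra(cfg)
  sp <- ks_split(d, 8)
  sel <- true_informative_indices(cfg, d$frequencies_thz)
  m <- fit_pls(d$power[sp$cal_indices, sel], d$nitrogen_pct[sp$cal_indices], 2)
  rep <- evaluate_model(m, d, sp, sel, model_name = "PLS",
                        selection_name = "truth")
  # noiseless rank-one data: essentially perfect on both subsets
  expect_lt(rep$rmsec_pct, 1e-6)
  expect_gt(rep$r2_pred, 0.999999)
  expect_equal(rep$n_cal + rep$n_pred, n_samples(d))

  # fields equal an independent metric recomputation
  yc <- d$nitrogen_pct[sp$cal_indices]
  yp <- d$nitrogen_pct[sp$pred_indices]
  expect_equal(rep$rmsec_pct, rmse(yc, predict(m, d$power[sp$cal_indices, sel])))
  expect_equal(rep$r2_pred, r_squared(yp, predict(m, d$power[sp$pred_indices, sel])))

  # purity: repeated evaluation is identical
  expect_identical(rep, evaluate_model(m, d, sp, sel, model_name = "PLS",
                                       selection_name = "truth"))
})
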