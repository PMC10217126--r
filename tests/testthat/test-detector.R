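# Detector: encoding, architecture, training mechanics, prediction.

test_that("encoding produces the amplitude/phase tensor with frozen stats", {
  S_list <- lapply(1:6, function(i) random_smatrix(30, seed = i))
  stats <- encoding_stats(S_list)
  e <- encode_scattering(S_list[[1]], stats)
  expect_equal(dim(e), c(30L, 30L, 2L))
  # phase channel scaled by pi into (-1, 1]
  expect_true(all(e[, , 2] > -1 & e[, , 2] <= 1))
  # constant-phase matrix: phase channel identically 0.5 after scaling
  Sc <- matrix(complex(modulus = runif(900, 1, 2), argument = pi / 2), 30, 30)
  ec <- encode_scattering(Sc, stats)
  expect_true(all(abs(ec[, , 2] - 0.5) < 1e-12))
  # zero matrix: defined phase 0, finite amplitude channel
  e0 <- encode_scattering(matrix(0i, 30, 30), stats)
  expect_true(all(e0[, , 2] == 0))
  expect_true(all(is.finite(e0[, , 1])))
  # round trip: amplitude * exp(j * pi * phase) reconstructs S exactly
  amp <- abs(S_list[[1]]); ph <- e[, , 2] * pi
  expect_equal(amp * exp(1i * ph), S_list[[1]], tolerance = 1e-12)
  # stats are mandatory
  expect_error(encode_scattering(S_list[[1]]), class = "mwtomo_missing_stats")
})

test_that("architecture: output in [0, 1], correct parameter count, seeded init", {
  cfg <- detector_config(seed = 123)
  m <- build_detector(cfg)
  np <- n_parameters(m)
  # conv trunk: (3*3*2*32 + 32) + 9 * (3*3*32*32 + 32)
  expect_equal(np$conv_trunk, (3 * 3 * 2 * 32 + 32) + 9 * (3 * 3 * 32 * 32 + 32))
  expect_equal(np$conv_trunk, 83840L)
  expect_equal(np$total, np$conv_trunk + 2L * 32L * 10L + 33L)
  # scores land in [0, 1] (exactly 0.5 for the zero-initialised head)
  X <- array(rnorm(2 * 900 * 3), c(2, 900, 3))
  p <- mwtomo:::cnn_predict(m$params, X)
  expect_true(all(p >= 0 & p <= 1))
  # identical seeds give identical initial weights
  expect_identical(build_detector(cfg)$params, m$params)
  expect_false(identical(build_detector(detector_config(seed = 124))$params$conv_W[[1]],
                         m$params$conv_W[[1]]))
  expect_error(detector_config(threshold = 1.2), class = "mwtomo_bad_config")
})

test_that("first-epoch loss starts at chance level for balanced classes", {
  cfg <- detector_config(seed = 5)
  m <- build_detector(cfg)
  X <- array(rnorm(2 * 900 * 8), c(2, 900, 8))
  y <- rep(0:1, 4)
  expect_equal(mwtomo:::cnn_loss(m$params, X, y), log(2), tolerance = 1e-6)
})

test_that("training learns strongly separated toy data and is reproducible", {
  # structured class difference, no noise: the sanity oracle for the trainer
  set.seed(10)
  n <- 48
  X <- array(rnorm(2 * 900 * n, sd = 0.3), c(2, 900, n))
  y <- rep(0:1, each = n / 2)
  patt <- matrix(sin(seq_len(900) / 20), 1, 900)
  for (i in which(y == 1)) X[1, , i] <- X[1, , i] + 2 * patt
  cfg <- detector_config(epochs = 30L, batch_size = 16L, learning_rate = 2e-3,
                         seed = 4)
  stats <- structure(list(), class = "mwt_encoding_stats")
  fit <- train_detector(build_detector(cfg), X, y, X, y, stats)
  p <- predict(fit, X)
  expect_gt(mean((p$score >= 0.5) == (y == 1)), 0.99)
  expect_equal(nrow(fit$history), 30)
  # reproducibility of the whole run
  fit2 <- train_detector(build_detector(cfg), X, y, X, y, stats)
  expect_identical(fit$history, fit2$history)
  expect_identical(fit$params, fit2$params)
  # degenerate training sets are rejected
  expect_error(train_detector(build_detector(cfg), X, rep(1, n), X, y, stats),
               class = "mwtomo_bad_input")
})

test_that("per-epoch losses are invariant under sample duplication", {
  # duplicating every sample within each minibatch leaves the gradient,
  # batch statistics and Adam trajectory unchanged
  set.seed(2)
  n <- 16
  X <- array(rnorm(2 * 900 * n), c(2, 900, n))
  y <- as.numeric(rep(0:1, n / 2))
  Xd <- X[, , rep(seq_len(n), each = 2)]
  yd <- y[rep(seq_len(n), each = 2)]
  cfg <- detector_config(seed = 9)
  m <- build_detector(cfg)
  adam1 <- mwtomo:::zero_adam(m$params)
  adam2 <- mwtomo:::zero_adam(m$params)
  batches1 <- list(1:8, 9:16)
  batches2 <- list(seq_len(16), 16 + seq_len(16))  # same samples, duplicated
  r1 <- mwtomo:::cnn_train_epoch(rapply(m$params, identity, how = "replace"),
                                 adam1, X, y, batches1, 1e-3, .9, .999, 1e-8, .1)
  r2 <- mwtomo:::cnn_train_epoch(rapply(m$params, identity, how = "replace"),
                                 adam2, Xd, yd, batches2, 1e-3, .9, .999, 1e-8, .1)
  expect_equal(r1$train_loss, r2$train_loss, tolerance = 1e-5)
  expect_equal(r1$params$conv_W[[1]], r2$params$conv_W[[1]], tolerance = 1e-5)
})

test_that("prediction thresholds and labels behave monotonically", {
  set.seed(3)
  cfg <- detector_config(seed = 11, epochs = 2L, batch_size = 8L)
  m <- build_detector(cfg)
  X <- array(rnorm(2 * 900 * 12), c(2, 900, 12))
  y <- rep(0:1, 6)
  stats <- structure(list(), class = "mwt_encoding_stats")
  fit <- train_detector(m, X, y, X, y, stats)
  p1 <- predict(fit, X, threshold = 0.2)
  p2 <- predict(fit, X, threshold = 0.8)
  # scores identical (deterministic inference), labels flip monotonically
  expect_identical(p1$score, p2$score)
  expect_true(all(!(p1$label == "healthy" & p2$label == "suspicious")))
  # batch order invariance
  p_rev <- predict(fit, X[, , 12:1])
  expect_equal(rev(p_rev$score), p1$score, tolerance = 1e-12)
  expect_error(predict(fit, X, threshold = 1.5), class = "mwtomo_bad_config")
  # shape mismatch with the model geometry
  Xbad <- array(rnorm(2 * 625 * 2), c(2, 625, 2))
  expect_error(predict(fit, Xbad), class = "mwtomo_bad_input")
})
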