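# Internal helpers for poking the compute engine directly.
fresh_state <- function(spec, seed = 1) {
  withr::with_seed(seed, dwmacnn:::cpp_init_net(
    dwmacnn:::engine_layers(spec), spec$patch_size, spec$epsilon, 0.99))
}

test_that("a real forward pass reproduces the traced shapes for all four networks", {
  for (n in c(7, 9, 13, 17)) {
    spec <- build_architecture(n)
    tr <- forward_shape_trace(spec)
    st <- fresh_state(spec, seed = n)
    X <- withr::with_seed(n, matrix(rnorm(n * n * 6), n * n, 6))
    acts <- dwmacnn:::cpp_forward_trace(st, X, TRUE)
    expect_length(acts, nrow(tr))
    expect_equal(vapply(acts, ncol, integer(1)), tr$flat)
    expect_true(all(vapply(acts, nrow, integer(1)) == 6))
  }
})

test_that("the convolution layer equals a brute-force cross-correlation oracle", {
  # a lone convolution layer with 2 filters on 5x5 patches
  layers <- list(list(kind = "convolution", n_filters = 2L, has_bias = FALSE))
  st <- withr::with_seed(8, dwmacnn:::cpp_init_net(layers, 5L, 1e-5, 0.99))
  W <- st$layers[[1]]$W             # (9 x 2), row = kw*3 + kh
  X <- withr::with_seed(9, matrix(rnorm(25 * 4), 25, 4))
  out <- dwmacnn:::cpp_forward_trace(st, X, FALSE)[[1]]  # 4 x 18
  for (s in 1:4) {
    patch <- matrix(X[, s], 5, 5)
    for (f in 1:2) {
      k3 <- matrix(W[, f], 3, 3)    # rows kh, cols kw
      o <- oracle_conv3x3_relu(patch, k3)
      got <- matrix(out[s, (f - 1) * 9 + 1:9], 3, 3)
      expect_equal(got, o, tolerance = 1e-6)
    }
  }
})

test_that("batch normalisation standardises per channel and can invert itself", {
  spec <- build_architecture(7)
  st <- fresh_state(spec, 3)
  X <- withr::with_seed(4, matrix(rnorm(49 * 64), 49, 64))
  acts <- dwmacnn:::cpp_forward_trace(st, X, TRUE)
  conv_out <- acts[[1]]   # 64 x (8*25)
  bn_out <- acts[[2]]
  eps <- 1e-5
  for (ch in 1:8) {
    blk <- bn_out[, (ch - 1) * 25 + 1:25]
    expect_equal(mean(blk), 0, tolerance = 1e-8)
    expect_equal(mean(blk^2), 1, tolerance = 1e-3)  # variance up to epsilon
  }
  # gamma = sqrt(var_B + eps), beta = mu_B recovers the input
  st2 <- st
  for (ch in 1:8) {
    blk <- conv_out[, (ch - 1) * 25 + 1:25]
    mu <- mean(blk); v <- mean((blk - mu)^2)
    st2$layers[[2]]$gamma[ch] <- sqrt(v + eps)
    st2$layers[[2]]$beta[ch] <- mu
  }
  acts2 <- dwmacnn:::cpp_forward_trace(st2, X, TRUE)
  expect_equal(acts2[[2]], conv_out, tolerance = 1e-9)
})

test_that("softmax outputs are probabilities summing to one", {
  spec <- build_architecture(9)
  st <- fresh_state(spec, 5)
  X <- withr::with_seed(5, matrix(rnorm(81 * 32), 81, 32))
  P <- dwmacnn:::cpp_predict(st, X, 16L)
  expect_equal(dim(P), c(2L, 32L))
  expect_true(all(P > 0 & P < 1))
  expect_equal(colSums(P), rep(1, 32))
})

test_that("one SGD step at zero momentum descends the exact gradient", {
  spec <- build_architecture(7)
  st <- fresh_state(spec, 42)
  X <- withr::with_seed(43, matrix(rnorm(49 * 8), 49, 8))
  y <- as.integer(c(0, 1, 0, 1, 1, 0, 0, 1))
  lr <- 0.01
  res <- dwmacnn:::cpp_train_epoch(st, X, y, 1:8, 8L, lr, 0)
  h <- 1e-6
  # central finite differences on a handful of parameters in every
  # parameterised layer, including batch-norm scale and shift
  for (li in seq_along(st$layers)) {
    for (fld in c("W", "gamma", "beta", "b")) {
      if (is.null(st$layers[[li]][[fld]])) next
      for (i in unique(c(1L, length(st$layers[[li]][[fld]])))) {
        stp <- st; stp$layers[[li]][[fld]][i] <- stp$layers[[li]][[fld]][i] + h
        stm <- st; stm$layers[[li]][[fld]][i] <- stm$layers[[li]][[fld]][i] - h
        g_fd <- (dwmacnn:::cpp_loss(stp, X, y) -
                 dwmacnn:::cpp_loss(stm, X, y)) / (2 * h)
        g_step <- (st$layers[[li]][[fld]][i] -
                   res$state$layers[[li]][[fld]][i]) / lr
        expect_equal(g_step, g_fd, tolerance = 1e-4,
                     label = sprintf("layer %d %s[%d] step-gradient", li, fld, i))
      }
    }
  }
})

test_that("training separates a toy patch set and respects the config", {
  toy <- toy_patch_set(n_per_class = 150, patch_size = 7, seed = 2)
  cfg <- training_config(batch_size = 64, max_epochs = 5, seed = 7)
  m <- train_cnn(build_architecture(7), toy, cfg)
  expect_s3_class(m, "dwma_cnn")
  expect_lte(length(m$training_log), 5)
  pred <- as.integer(predict_patch_probs(m, toy$X) >= 0.5)
  expect_gt(toy_balanced_accuracy(pred, toy$y), 0.95)

  # defaults carry the published recipe
  cfg0 <- training_config()
  expect_equal(cfg0$batch_size, 256L)
  expect_equal(cfg0$learning_rate, 0.1)
  expect_equal(cfg0$max_epochs, 20L)
  expect_equal(cfg0$early_stop_patience, 3L)

  # single-class data is refused
  one_class <- list(X = toy$X[, toy$y == 0], y = toy$y[toy$y == 0])
  expect_error(train_cnn(build_architecture(7), one_class, cfg), "both classes")
})

test_that("early stopping fires on three equal consecutive losses", {
  expect_true(loss_plateaued(c(0.5, 0.3, 0.3, 0.3), tolerance = 0))
  expect_false(loss_plateaued(c(0.5, 0.3, 0.3), tolerance = 0))
  expect_false(loss_plateaued(c(0.3, 0.3), tolerance = 0))
  expect_true(loss_plateaued(c(1, 0.2001, 0.2002, 0.2000), tolerance = 3e-4))
})

test_that("training is deterministic given the seed", {
  toy <- toy_patch_set(n_per_class = 60, patch_size = 9, seed = 3)
  cfg <- training_config(batch_size = 32, max_epochs = 3, seed = 11)
  m1 <- train_cnn(build_architecture(9), toy, cfg)
  m2 <- train_cnn(build_architecture(9), toy, cfg)
  expect_identical(m1$training_log, m2$training_log)
  expect_identical(m1$state, m2$state)
  cfg2 <- cfg; cfg2$seed <- 12L
  m3 <- train_cnn(build_architecture(9), toy, cfg2)
  expect_false(identical(m1$training_log, m3$training_log))
})

test_that("volume prediction memorises a tiny subject and stays inside white matter", {
  subj <- zscore_subject(toy_subject())
  pd <- extract_patches(subj, 7)
  cfg <- training_config(batch_size = 32, max_epochs = 12,
                         learning_rate = 0.05, seed = 2)
  m <- train_cnn(build_architecture(7), pd, cfg)
  pred <- predict_volume(m, subj)
  expect_true(all(subj$wm_mask[pred$mask]))
  expect_equal(dice(pred$mask, subj$gold_dwma), 1)
  # probabilities live on white matter only
  expect_true(all(pred$probability[!subj$wm_mask] == 0))
  # argmax decision: probability below 0.5 is normal
  expect_true(all(pred$mask == (pred$probability >= 0.5) | !subj$wm_mask))

  # patch-size mismatch between model and data is refused
  pd9 <- extract_patches(subj, 9)
  expect_error(train_cnn(build_architecture(7), pd9, cfg), "mismatch")
  X9 <- patch_matrix(pd9)
  expect_error(predict_patch_probs(m, X9), "mismatch")
})
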