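test_that("trainable parameter count matches the closed-form arithmetic", {
  cfg <- cnn_config()  # 128 filters, width 5, 7 channels, 16 classes
  m <- build_model(cfg)
  # independent arithmetic: conv weights + biases, 2 BN parameters per
  # channel per block, dense weights + biases
  conv1 <- 5 * 7 * 128 + 128
  conv23 <- 2 * (5 * 128 * 128 + 128)
  bn <- 3 * 2 * 128
  dense <- 128 * 16 + 16
  expect_equal(count_parameters(m), conv1 + conv23 + bn + dense)
  # first conv: 128 filters of width 5 over 7 channels
  expect_equal(dim(m$params$W1), c(5L * 7L, 128L))
})

test_that("the forward pass yields normalised probabilities", {
  cfg <- tiny_cnn_config()
  m <- build_model(cfg)
  set.seed(2)
  x <- array(rnorm(6 * cfg$input_len * cfg$n_channels),
             c(6, cfg$input_len, cfg$n_channels))
  p <- predict(m, x)
  expect_equal(dim(p$probabilities), c(6L, cfg$n_classes))
  expect_equal(rowSums(p$probabilities), rep(1, 6), tolerance = 1e-6)
  expect_true(all(p$probabilities >= 0))
  expect_identical(p$labels,
                   max.col(p$probabilities, ties.method = "first") - 1L)
  # eval mode is deterministic
  expect_identical(p$probabilities, predict(m, x)$probabilities)
  # shape mismatch
  expect_error(predict(m, array(0, c(2, 10, 2))), "array")
})

test_that("an input shorter than the receptive field is a build error", {
  expect_error(build_model(cnn_config(input_len = 10L)), "receptive field")
})

test_that("cross-entropy matches its closed forms", {
  t5 <- c(0, 0, 0, 0, 1)
  expect_equal(cross_entropy(t5, t5), 0)
  expect_equal(cross_entropy(c(rep(0, 15), 1), rep(1 / 16, 16)), log(16))
  expect_equal(log(16), 2.772589, tolerance = 1e-6)
})

test_that("split_dataset gives stratified 72/18/10 with a disjoint cover", {
  labels <- rep(0:9, each = 10)  # 100 items
  sp <- split_dataset(labels, seed = 3)
  expect_length(sp$train, 72L)
  expect_length(sp$validation, 18L)
  expect_length(sp$test, 10L)
  all_idx <- c(sp$train, sp$validation, sp$test)
  expect_setequal(all_idx, seq_along(labels))
  expect_length(all_idx, length(labels))  # pairwise disjoint
  # stratification: every class appears in the test set at most ceil share
  expect_true(all(table(labels[sp$test]) <= 2))
  # determinism
  expect_identical(sp, split_dataset(labels, seed = 3))
  expect_false(identical(sp, split_dataset(labels, seed = 4)))
  expect_error(split_dataset(rep(0, 9)), "at least 10")
})

test_that("training learns a noise-free separable set and behaves sanely", {
  # scaled-down stand-in for the generator's noise-free world: 4 classes with
  # distinct spectral signatures, tiny network
  cfg <- tiny_cnn_config(epochs = 30L, learning_rate = 2e-3)
  set.seed(5)
  n <- 40
  y <- rep(0:3, each = 10)
  x <- array(rnorm(n * cfg$input_len * cfg$n_channels, sd = 0.05),
             c(n, cfg$input_len, cfg$n_channels))
  tt <- seq_len(cfg$input_len)
  for (i in seq_len(n)) {
    x[i, , 1] <- x[i, , 1] + sin(2 * pi * (y[i] + 1) * tt / cfg$input_len)
    x[i, , 2] <- x[i, , 2] + cos(2 * pi * (y[i] + 1) * tt / cfg$input_len)
  }
  m <- cnn_train(build_model(cfg), x, y)
  expect_true(m$trained)
  # training accuracy on the separable set (eval mode)
  expect_gte(mean(predict(m, x)$labels == y), 0.95)
  # loss on the training set is non-increasing across epochs up to 5%
  # jitter; measured as the end-of-epoch eval-mode loss on the training set
  # (the running within-epoch average is noisy at batch size 8), with
  # dropout off so it reflects the optimiser rather than mask noise
  m_nodrop <- cnn_train(build_model(tiny_cnn_config(epochs = 30L,
                                                    learning_rate = 2e-3,
                                                    dropout_rate = 0)),
                        x, y, x_val = x, y_val = y)
  l <- m_nodrop$history$val_loss
  expect_true(all(l[-1] <= l[-length(l)] * 1.05))
  # determinism given the seed
  m2 <- cnn_train(build_model(cfg), x, y)
  expect_identical(m$params, m2$params)
  expect_error(cnn_train(build_model(cfg), x[0, , , drop = FALSE], integer(0)),
               "empty")
})

test_that("validation history and early stopping are recorded", {
  cfg <- tiny_cnn_config(epochs = 6L, early_stopping_patience = 2L)
  set.seed(6)
  x <- array(rnorm(24 * cfg$input_len * cfg$n_channels),
             c(24, cfg$input_len, cfg$n_channels))
  y <- rep(0:3, each = 6)
  m <- cnn_train(build_model(cfg), x[1:16, , , drop = FALSE], y[1:16],
                 x[17:24, , , drop = FALSE], y[17:24])
  expect_true(all(c("val_loss", "val_accuracy") %in% names(m$history)))
  expect_true(all(is.finite(m$history$val_loss)))
  expect_lte(nrow(m$history), 6L)
})
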