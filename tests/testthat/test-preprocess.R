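test_that("zero-phase low-pass matches the squared Butterworth magnitude oracle", {
  fs <- 200
  t <- (0:1999) / fs
  # DC passband: a constant is unchanged
  expect_equal(lowpass_zerophase(rep(3.7, 100), 20, fs), rep(3.7, 100),
               tolerance = 1e-9)
  # deep passband: 2 Hz sine keeps its amplitude and is not delayed
  x <- sin(2 * pi * 2 * t)
  y <- lowpass_zerophase(x, 20, fs)
  core <- 200:1800
  expect_gte(max(abs(y[core])), 0.99)
  lags <- -10:10
  xc <- vapply(lags, function(l) {
    idx <- core
    sum(y[idx] * x[idx + l])
  }, numeric(1))
  expect_equal(lags[which.max(xc)], 0L)
  # stopband: attenuation at least the analytic |H|^2 (+1%)
  for (f in c(35, 45, 60)) {
    xf <- sin(2 * pi * f * t)
    yf <- lowpass_zerophase(xf, 20, fs)
    expect_lte(max(abs(yf[core])), butter_mag_sq(f, 20, 2) * 1.01)
  }
})

test_that("zero-phase property holds across band-limited test sines", {
  fs <- 100
  t <- (0:999) / fs
  core <- 100:900
  for (f in c(1, 3, 7, 12)) {
    x <- sin(2 * pi * f * t)
    y <- lowpass_zerophase(x, 15, fs)
    lags <- -5:5
    xc <- vapply(lags, function(l) sum(y[core] * x[core + l]), numeric(1))
    expect_equal(lags[which.max(xc)], 0L)
  }
})

test_that("low-pass rejects degenerate input", {
  expect_error(lowpass_zerophase(1:5, 20, 200), "too short")
  expect_error(lowpass_zerophase(rnorm(100), 120, 200), "Nyquist")
  expect_error(lowpass_zerophase(rnorm(100), 0, 200), "Nyquist")
})

test_that("detrend_diff differences with the repeat-first convention", {
  expect_equal(detrend_diff(rep(5, 10)), rep(0, 10))
  expect_equal(detrend_diff(0.5 * (0:9)), rep(0.5, 10))  # ramp -> constant
  expect_equal(detrend_diff(c(1, 3, 2)), c(2, 2, -1))
  expect_error(detrend_diff(1), "at least 2")
})

test_that("median stage removes short irregular peaks", {
  expect_equal(driveact:::median_filter(c(1, 1, 9, 1, 1), 3), rep(1, 5))
  impulse <- numeric(50); impulse[25] <- 10
  expect_equal(driveact:::median_filter(impulse, 5), numeric(50))
  # oracle: brute-force median of each (edge-replicated) neighbourhood
  set.seed(42)
  x <- rnorm(80)
  k <- 5; h <- 2
  xp <- c(rep(x[1], h), x, rep(x[80], h))
  oracle <- vapply(seq_along(x), function(i) median(xp[i:(i + 2 * h)]),
                   numeric(1))
  expect_equal(driveact:::median_filter(x, k), oracle)
})

test_that("acc_clean preserves constants and removes impulses", {
  cfg <- preproc_config()
  expect_equal(acc_clean(rep(0.25, 100), cfg), rep(0.25, 100),
               tolerance = 1e-6)
  x <- rep(1, 100); x[50] <- 5   # width-1 spike, kernel 5
  expect_equal(acc_clean(x, cfg), rep(1, 100), tolerance = 1e-6)
  expect_error(acc_clean(rnorm(20), cfg), "too short")
})

test_that("synchronize decimates to matching lengths", {
  cfg <- quiet_config()
  expect_equal(nrow(synchronize(synthesize_recording(15, 2.06, cfg, 1))), 103L)
  expect_equal(nrow(synchronize(synthesize_recording(9, 60.26, cfg, 1))), 3013L)
  # already at the sync rate: unchanged
  rec <- synced_recording(103)
  out <- synchronize(rec)
  expect_identical(out[, "EOGL"], rec$eog_l)
  expect_identical(out[, "ACCX"], rec$acc_x)
  # non-integer decimation factor
  rec$eog_rate <- 130
  expect_error(synchronize(rec), "integer multiple")
})

test_that("zscore standardises with the population convention", {
  expect_equal(zscore(c(2, 4, 6)), c(-1.224745, 0, 1.224745),
               tolerance = 1e-6)
  set.seed(7)
  for (i in 1:5) {
    x <- rnorm(50 + i, mean = runif(1, -5, 5), sd = runif(1, 0.1, 10))
    z <- zscore(x)
    expect_equal(mean(z), 0, tolerance = 1e-9)
    expect_equal(sqrt(mean((z - mean(z))^2)), 1, tolerance = 1e-9)
    # idempotence
    expect_equal(zscore(z), z, tolerance = 1e-9)
  }
  expect_warning(z <- zscore(c(5, 5, 5)), "constant")
  expect_equal(z, c(0, 0, 0))
  expect_error(zscore(numeric(0)), "empty")
})

test_that("sliding windows follow the truncate-then-stride rule", {
  expect_length(sliding_windows(matrix(rnorm(280 * 2), 280), 280, 140), 1L)
  w <- sliding_windows(matrix(seq_len(420), 420), 280, 140)
  expect_length(w, 2L)
  expect_equal(w[[1]][1, 1], 1)    # start 0
  expect_equal(w[[2]][1, 1], 141)  # start 140
  expect_length(sliding_windows(matrix(rnorm(279), 279), 280, 140), 0L)
})

test_that("window counts equal the brute-force enumerator for lengths 0-1000", {
  for (n in 0:1000) {
    x <- matrix(0, n, 1)
    expect_length(sliding_windows(x, 280, 140),
                  length(brute_force_window_starts(n, 280, 140)))
  }
  # a second geometry, windows not aligned with the stride grid
  for (n in seq(0, 400, by = 7)) {
    got <- sliding_windows(matrix(seq_len(n), ncol = 1), 50, 30)
    starts <- brute_force_window_starts(n, 50, 30)
    expect_length(got, length(starts))
    if (length(starts)) {
      expect_equal(vapply(got, function(w) w[1, 1], numeric(1)), starts + 1)
    }
  }
})

test_that("resample_to_length interpolates linearly and keeps endpoints", {
  x <- matrix(rnorm(300 * 2), 300)
  expect_equal(resample_to_length(x, 300), x, tolerance = 1e-9,
               ignore_attr = TRUE)
  ramp <- seq(0, 1, length.out = 101)
  out <- resample_to_length(ramp, 3000)
  expect_equal(as.numeric(out), seq(0, 1, length.out = 3000),
               tolerance = 1e-6)
  expect_true(all(diff(as.numeric(out)) >= 0))  # monotone stays monotone
  const <- resample_to_length(rep(2.5, 10), 3000)
  expect_equal(as.numeric(const), rep(2.5, 3000))
  expect_error(resample_to_length(matrix(1, 1, 1), 10), "at least 2")
})

test_that("the full chain produces standardized fixed-size model inputs", {
  cfg <- quiet_config()
  rec <- synthesize_recording(9, 60.26, cfg, seed = 3)
  mi <- preprocess_recording(rec, preproc_config())
  expect_s3_class(mi, "model_input")
  expect_equal(dim(mi$values), c(3000L, 7L))
  expect_true(all(is.finite(mi$values)))
  for (j in 1:7) {
    v <- mi$values[, j]
    expect_equal(mean(v), 0, tolerance = 1e-6)
    expect_equal(sqrt(mean((v - mean(v))^2)), 1, tolerance = 1e-6)
  }

  # 5.6 s recording in windows mode -> exactly one 280 x 7 window
  rec2 <- synthesize_recording(15, 5.6, cfg, seed = 4)
  wins <- preprocess_recording(rec2, preproc_config(segmentation_mode = "windows"))
  expect_length(wins, 1L)
  expect_equal(dim(wins[[1]]$values), c(280L, 7L))

  # determinism: identical inputs and config give bitwise-identical outputs
  mi2 <- preprocess_recording(rec, preproc_config())
  expect_identical(mi$values, mi2$values)

  # stage errors carry the stage name
  short <- synthesize_recording(15, 2.06, cfg, seed = 5)
  short$acc_x <- short$acc_x[1:10]
  short$acc_y <- short$acc_y[1:10]
  short$acc_z <- short$acc_z[1:10]
  expect_error(preprocess_recording(short, preproc_config()),
               "stage 'acc_clean")
})
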