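test_that("event templates honour amplitude, duration and baseline", {
  for (kind in c("saccade", "blink", "head_turn", "reach")) {
    # zero amplitude -> all-zero waveform
    expect_equal(make_event_template(kind, 0, 0.5, 100), rep(0, 50))
    # sign symmetry
    w_pos <- make_event_template(kind, 3.5, 0.4, 200)
    w_neg <- make_event_template(kind, -3.5, 0.4, 200)
    expect_equal(w_neg, -w_pos)
    # baseline at both ends, peak magnitude = |amplitude|
    expect_equal(w_pos[1], 0)
    expect_equal(w_pos[length(w_pos)], 0)
    expect_equal(max(abs(w_pos)), 3.5, tolerance = 1e-12)
  }
  w <- make_event_template("saccade", 100, 0.2, 200)
  expect_length(w, 40L)
  expect_equal(max(w), 100, tolerance = 1e-9)

  expect_error(make_event_template("saccade", 1, 0, 100), "duration")
  expect_error(make_event_template("saccade", 1, 1, -5), "rate")
})

test_that("synthesize_recording is deterministic and satisfies channel identities", {
  cfg <- quiet_config()
  a <- synthesize_recording(3, 12, cfg, seed = 99)
  b <- synthesize_recording(3, 12, cfg, seed = 99)
  expect_identical(a, b)
  c <- synthesize_recording(3, 12, cfg, seed = 100)
  expect_false(identical(a$eog_l, c$eog_l))

  for (code in c(0, 5, 9, 12, 15)) {
    dur <- mean(driveact:::class_duration_range(code))
    rec <- synthesize_recording(code, dur, cfg, seed = code + 1)
    expect_identical(rec$eog_h, rec$eog_l - rec$eog_r)
    expect_identical(rec$eog_v, -(rec$eog_l + rec$eog_r) / 2)
    expect_equal(length(rec$acc_x), length(rec$eog_l) / 2)
    expect_true(max(abs(c(rec$acc_x, rec$acc_y, rec$acc_z))) <= 2)
  }
})

test_that("a 2.06 s recording has 412 EOG / 206 ACC samples and 103 after sync", {
  rec <- synthesize_recording(15, 2.06, quiet_config(), seed = 5)
  expect_length(rec$eog_l, 412L)
  expect_length(rec$acc_x, 206L)
  expect_equal(nrow(synchronize(rec)), 103L)
})

test_that("invalid labels and out-of-range durations are rejected", {
  expect_error(synthesize_recording(16, 10, quiet_config()), "unknown")
  expect_error(synthesize_recording(0, 1, quiet_config()), "outside")
  expect_error(synthesize_recording(0, 99, quiet_config()), "outside")
})

test_that("acceleration is clipped to +/- 2 g and clipping is counted", {
  cfg <- quiet_config(head_motion_amplitude = 6)
  rec <- synthesize_recording(12, 8, cfg, seed = 2)  # large trunk dive
  expect_true(max(abs(c(rec$acc_x, rec$acc_y, rec$acc_z))) <= 2)
  expect_gt(rec$n_clipped, 0)
})

test_that("generate_dataset spreads counts evenly with round-robin remainders", {
  # even case at reduced scale mirroring the 1200/700 design
  ds <- generate_dataset(quiet_config(n_primary = 24, n_secondary = 8, seed = 4))
  counts <- table(factor(ds$manifest$label, levels = 0:15))
  expect_true(all(counts[1:12] == 2))
  expect_true(all(counts[13:16] == 2))
  expect_equal(nrow(ds$manifest), 32L)

  # the default 1200/700 allocation: 100 per primary, 175 per secondary class
  expect_equal(driveact:::spread_evenly(1200, 12), rep(100L, 12))
  expect_equal(driveact:::spread_evenly(700, 4), rep(175L, 4))

  # remainder goes to the lowest codes first
  expect_equal(driveact:::spread_evenly(14, 12),
               c(2L, 2L, rep(1L, 10)))

  # empty dataset is valid
  empty <- generate_dataset(quiet_config(n_primary = 0, n_secondary = 0))
  expect_length(empty$recordings, 0L)
  expect_equal(nrow(empty$manifest), 0L)
})

test_that("datasets are reproducible from the master seed", {
  cfg <- quiet_config(seed = 21)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1, d2)
  d3 <- generate_dataset(quiet_config(seed = 22))
  expect_false(identical(d1$recordings[[1]]$eog_l, d3$recordings[[1]]$eog_l))
})

test_that("noise-free class templates are pairwise distinct", {
  cfg <- noise_free(quiet_config())
  inputs <- lapply(0:15, function(code) {
    dur <- mean(driveact:::class_duration_range(code))
    rec <- synthesize_recording(code, dur, cfg, seed = 1)
    # constant channels (e.g. a flat vertical EOG with no noise) z-score to
    # zero with a warning; that is expected here
    suppressWarnings(
      preprocess_recording(rec, preproc_config(model_input_len = 300))$values
    )
  })
  for (i in 1:15) for (j in (i + 1):16) {
    d <- sqrt(mean((inputs[[i]] - inputs[[j]])^2))
    expect_gt(d, 0.05)  # strictly positive separation for every class pair
  }
})
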