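# Shared fixtures and independent oracles, all built in code at test time.

# A small, quiet generator configuration for unit tests.
quiet_config <- function(n_primary = 12, n_secondary = 4, ...) {
  synthetic_config(n_primary = n_primary, n_secondary = n_secondary, ...)
}

# Brute-force sliding-window start enumerator (independent of the package
# implementation): truncate to a multiple of `stride`, then take every start
# whose full window fits.
brute_force_window_starts <- function(n, window_len, stride) {
  n_trunc <- (n %/% stride) * stride
  starts <- seq(0L, max(0L, n_trunc), by = stride)
  starts[starts + window_len <= n_trunc]
}

# Brute-force one-vs-rest counts for class `cls` from raw label pairs.
brute_force_counts <- function(y_true, y_pred, cls) {
  list(
    tp = sum(y_true == cls & y_pred == cls),
    fp = sum(y_true != cls & y_pred == cls),
    fn = sum(y_true == cls & y_pred != cls),
    tn = sum(y_true != cls & y_pred != cls)
  )
}

# Squared analog Butterworth magnitude: the zero-phase (forward+backward)
# response of an order-n Butterworth low-pass.
butter_mag_sq <- function(f, fc, order = 2) 1 / (1 + (f / fc)^(2 * order))

# A deterministic synchronized-rate recording (50 Hz both streams) for I/O
# tests where EOG and ACC grids coincide.
synced_recording <- function(n = 103, code = 15) {
  t <- seq_len(n)
  l <- sin(t / 7) * 40
  r <- cos(t / 9) * 35
  raw_recording(label_map(code),
                eog_l = l, eog_r = r, eog_h = l - r, eog_v = -(l + r) / 2,
                acc_x = sin(t / 11) * 0.5, acc_y = cos(t / 13) * 0.4,
                acc_z = rep(1, n) + sin(t / 17) * 0.1,
                eog_rate = 50, acc_rate = 50)
}

# Tiny CNN configuration that trains in well under a second.
tiny_cnn_config <- function(epochs = 3L, learning_rate = 1e-3, ...) {
  cnn_config(n_filters = 8L, kernel_size = 3L, pool_size = 2L,
             n_classes = 4L, input_len = 40L, n_channels = 2L,
             batch_size = 8L, epochs = epochs,
             learning_rate = learning_rate, seed = 11L, ...)
}
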