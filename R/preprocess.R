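#' Preprocessing configuration
#'
#' Parameters of the signal-conditioning chain: EOG channels are low-pass
#' filtered (zero-phase Butterworth) and detrended by differencing;
#' acceleration channels pass a median filter then a Hamming-window FIR
#' low-pass; all channels are synchronised to a common rate, z-scored, and
#' either resampled to a fixed model length (`whole_resampled`) or cut into
#' overlapping windows (`windows`).
#'
#' @param eog_lowpass_cutoff_Hz EOG low-pass cut-off (default 20 Hz: keeps
#'   saccadic content, removes 50/60 Hz mains before decimation).
#' @param butterworth_order One-pass Butterworth order (default 2; the
#'   forward-backward application doubles it).
#' @param acc_median_kernel Odd median window in samples (default 5).
#' @param acc_lowpass_cutoff_Hz Acceleration FIR cut-off (default 20 Hz).
#' @param fir_length Hamming FIR length in taps (default 31, odd).
#' @param sync_rate_Hz Common rate after decimation (default 50 Hz).
#' @param window_len Window length T in samples (default 280 = 5.6 s at 50 Hz).
#' @param stride Window stride in samples (default 140, a 50% overlap).
#' @param model_input_len Fixed model input length (default 3000).
#' @param segmentation_mode `"whole_resampled"` or `"windows"`.
#' @param eog_detrend `"diff"` (first difference) or `"highpass"`
#'   (subtract a zero-phase low-pass at `highpass_corner_Hz`).
#' @param highpass_corner_Hz Corner for the optional high-pass detrend.
#' @return A list of class `preproc_config`.
#' @export
preproc_config <- function(eog_lowpass_cutoff_Hz = 20, butterworth_order = 2L,
                           acc_median_kernel = 5L, acc_lowpass_cutoff_Hz = 20,
                           fir_length = 31L, sync_rate_Hz = 50,
                           window_len = 280L, stride = 140L,
                           model_input_len = 3000L,
                           segmentation_mode = c("whole_resampled", "windows"),
                           eog_detrend = c("diff", "highpass"),
                           highpass_corner_Hz = 0.05) {
  segmentation_mode <- match.arg(segmentation_mode)
  eog_detrend <- match.arg(eog_detrend)
  stopifnot(window_len > 0, stride > 0, model_input_len >= 2,
            acc_median_kernel %% 2L == 1L, fir_length %% 2L == 1L)
  structure(list(
    eog_lowpass_cutoff_Hz = eog_lowpass_cutoff_Hz,
    butterworth_order = as.integer(butterworth_order),
    acc_median_kernel = as.integer(acc_median_kernel),
    acc_lowpass_cutoff_Hz = acc_lowpass_cutoff_Hz,
    fir_length = as.integer(fir_length),
    sync_rate_Hz = sync_rate_Hz,
    window_len = as.integer(window_len), stride = as.integer(stride),
    model_input_len = as.integer(model_input_len),
    segmentation_mode = segmentation_mode,
    eog_detrend = eog_detrend, highpass_corner_Hz = highpass_corner_Hz
  ), class = "preproc_config")
}

MODEL_CHANNELS <- c("ACCX", "ACCY", "ACCZ", "EOGL", "EOGR", "EOGH", "EOGV")

#' Detrend a series by differencing
#'
#' First difference with the first value repeated so the output keeps the
#' input length: removes constant offsets and turns linear drift into a
#' constant.
#'
#' @param x Numeric series of length >= 2.
#' @return Series of the same length: `c(d[1], d)` with `d = diff(x)`.
#' @export
#' @examples
#' detrend_diff(c(1, 3, 2))  # 2 2 -1
detrend_diff <- function(x) {
  if (length(x) < 2L) stop("detrend_diff needs at least 2 samples", call. = FALSE)
  d <- diff(x)
  c(d[1], d)
}

#' Clean an acceleration channel
#'
#' Edge-replicated median filter (suppresses short irregular peaks narrower
#' than half the kernel) followed by a linear-phase Hamming-window FIR
#' low-pass whose group delay is compensated exactly.
#'
#' @param x Numeric series longer than the FIR length.
#' @param config A [preproc_config()].
#' @param rate_Hz Sampling rate of `x`.
#' @return Filtered series, same length as `x`.
#' @export
acc_clean <- function(x, config = preproc_config(), rate_Hz = ACC_RATE) {
  if (length(x) <= config$fir_length) {
    stop("series too short for acc_clean (need more than ",
         config$fir_length, " samples)", call. = FALSE)
  }
  y <- median_filter(x, config$acc_median_kernel)
  h <- fir_hamming_lowpass(config$fir_length, config$acc_lowpass_cutoff_Hz,
                           rate_Hz)
  half <- (config$fir_length - 1L) %/% 2L
  n <- length(y)
  yp <- c(rep(y[1], half), y, rep(y[n], half))
  out <- stats::filter(yp, h, method = "convolution", sides = 2)
  as.numeric(out[(half + 1L):(half + n)])
}

#' Synchronize all channels to a common rate
#'
#' Decimates EOG and acceleration channels to `sync_rate_Hz`; decimation
#' factors must be integers.  For factors greater than 1 an anti-alias
#' zero-phase Butterworth (order 4, cut-off `0.4 * sync_rate_Hz`) is applied
#' before sample picking.
#'
#' @param recording A [raw_recording()] (or any list with the same channel
#'   fields and rates).
#' @param sync_rate_Hz Target rate (default 50 Hz).
#' @return Numeric matrix with one row per synchronized sample and columns
#'   `ACCX, ACCY, ACCZ, EOGL, EOGR, EOGH, EOGV`.
#' @export
synchronize <- function(recording, sync_rate_Hz = 50) {
  f_eog <- recording$eog_rate / sync_rate_Hz
  f_acc <- recording$acc_rate / sync_rate_Hz
  if (f_eog != round(f_eog) || f_acc != round(f_acc) || f_eog < 1 || f_acc < 1) {
    stop(sprintf("native rates (%g, %g Hz) are not integer multiples of %g Hz",
                 recording$eog_rate, recording$acc_rate, sync_rate_Hz),
         call. = FALSE)
  }
  dec <- function(x, factor, rate) {
    if (factor == 1) return(x)
    x <- lowpass_zerophase(x, 0.4 * sync_rate_Hz, rate, order = 4L)
    x[seq(1L, length(x), by = factor)]
  }
  cols <- list(
    ACCX = dec(recording$acc_x, f_acc, recording$acc_rate),
    ACCY = dec(recording$acc_y, f_acc, recording$acc_rate),
    ACCZ = dec(recording$acc_z, f_acc, recording$acc_rate),
    EOGL = dec(recording$eog_l, f_eog, recording$eog_rate),
    EOGR = dec(recording$eog_r, f_eog, recording$eog_rate),
    EOGH = dec(recording$eog_h, f_eog, recording$eog_rate),
    EOGV = dec(recording$eog_v, f_eog, recording$eog_rate)
  )
  n <- min(lengths(cols))
  out <- vapply(cols, function(x) x[seq_len(n)], numeric(n))
  colnames(out) <- MODEL_CHANNELS
  out
}

#' Z-score normalisation
#'
#' Subtracts the mean and divides by the population standard deviation, so
#' the result has mean 0 and standard deviation 1.  A constant series has no
#' scale and is mapped to all zeros with a warning.
#'
#' @param x Non-empty numeric series.
#' @return Standardised series.
#' @export
#' @examples
#' zscore(c(2, 4, 6))
zscore <- function(x) {
  if (length(x) == 0L) stop("cannot z-score an empty series", call. = FALSE)
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0) {
    warning("constant series: z-score undefined, returning zeros",
            call. = FALSE)
    return(numeric(length(x)))
  }
  (x - m) / s
}

#' Sliding-window segmentation
#'
#' The series is first truncated from the end to the largest multiple of
#' `stride`; windows then start at 0, `stride`, `2 * stride`, ... while the
#' full window fits in the truncated length.  Short inputs yield zero
#' windows.
#'
#' @param x Numeric matrix (samples in rows) or vector.
#' @param window_len Window length T in samples.
#' @param stride Stride in samples.
#' @return List of windows, each a `window_len`-row matrix.
#' @export
sliding_windows <- function(x, window_len = 280L, stride = 140L) {
  stopifnot(window_len > 0L, stride > 0L)
  if (is.vector(x)) x <- matrix(x, ncol = 1L)
  n <- (nrow(x) %/% stride) * stride
  starts <- integer(0)
  s <- 0L
  while (s + window_len <= n) {
    starts <- c(starts, s)
    s <- s + stride
  }
  lapply(starts, function(s0) x[(s0 + 1L):(s0 + window_len), , drop = FALSE])
}

#' Resample a series to a fixed length
#'
#' Linear interpolation onto `length_out` equally spaced points spanning the
#' full series, preserving the first and last samples and monotonicity.
#'
#' @param x Numeric matrix (samples in rows) or vector with at least 2 rows.
#' @param length_out Target length (default 3000).
#' @return Matrix with `length_out` rows.
#' @export
resample_to_length <- function(x, length_out = 3000L) {
  if (is.vector(x)) x <- matrix(x, ncol = 1L)
  n <- nrow(x)
  if (n < 2L) stop("resampling needs at least 2 samples", call. = FALSE)
  grid <- seq(1, n, length.out = length_out)
  out <- apply(x, 2L, function(col) stats::approx(seq_len(n), col, grid)$y)
  colnames(out) <- colnames(x)
  out
}

#' Run the full preprocessing chain on one recording
#'
#' EOG channels: zero-phase low-pass then detrend; acceleration channels:
#' median + FIR low-pass; then synchronisation to the common rate,
#' per-channel z-scoring, and either resampling to the fixed model length
#' (with the z-score reapplied so inputs are exactly standardised) or
#' sliding-window segmentation.
#'
#' @param recording A [raw_recording()].
#' @param config A [preproc_config()].
#' @param source_id Optional provenance tag stored on the result.
#' @return In `whole_resampled` mode, one `model_input` (list with a
#'   `model_input_len x 7` `values` matrix, `label` and `source_id`); in
#'   `windows` mode, a list of `model_input`s, one per window.
#' @export
preprocess_recording <- function(recording, config = preproc_config(),
                                 source_id = NA_character_) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("preprocessing stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  rec <- recording
  detrend <- function(x) {
    if (config$eog_detrend == "diff") detrend_diff(x)
    else x - lowpass_zerophase(x, config$highpass_corner_Hz, rec$eog_rate,
                               config$butterworth_order)
  }
  for (ch in c("eog_l", "eog_r", "eog_h", "eog_v")) {
    rec[[ch]] <- stage(paste0("eog_filter:", ch), {
      detrend(lowpass_zerophase(rec[[ch]], config$eog_lowpass_cutoff_Hz,
                                rec$eog_rate, config$butterworth_order))
    })
  }
  for (ch in c("acc_x", "acc_y", "acc_z")) {
    rec[[ch]] <- stage(paste0("acc_clean:", ch),
                       acc_clean(rec[[ch]], config, rec$acc_rate))
  }
  synced <- stage("synchronize", synchronize(rec, config$sync_rate_Hz))
  normed <- stage("zscore", apply(synced, 2L, zscore))
  colnames(normed) <- colnames(synced)

  if (config$segmentation_mode == "whole_resampled") {
    vals <- stage("resample", resample_to_length(normed, config$model_input_len))
    vals <- apply(vals, 2L, zscore)
    colnames(vals) <- MODEL_CHANNELS
    model_input(vals, recording$label, source_id)
  } else {
    wins <- stage("windows",
                  sliding_windows(normed, config$window_len, config$stride))
    lapply(wins, model_input, label = recording$label, source_id = source_id)
  }
}

model_input <- function(values, label, source_id = NA_character_) {
  structure(list(values = values, label = label, source_id = source_id),
            class = "model_input")
}

#' @export
print.model_input <- function(x, ...) {
  cat(sprintf("<model_input %s: %d x %d>\n", x$label$name, nrow(x$values),
              ncol(x$values)))
  invisible(x)
}

#' Sampling-rate arithmetic helpers
#'
#' @param seconds,n_samples Quantity to convert.
#' @param rate_Hz Sampling rate in Hz.
#' @return `seconds_to_samples()` gives `round(seconds * rate_Hz)`;
#'   `samples_to_seconds()` gives `n_samples / rate_Hz`.
#' @export
seconds_to_samples <- function(seconds, rate_Hz) as.integer(round(seconds * rate_Hz))

#' @rdname seconds_to_samples
#' @export
samples_to_seconds <- function(n_samples, rate_Hz) n_samples / rate_Hz
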