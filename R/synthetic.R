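#' Configuration for the synthetic recording generator
#'
#' The generator emulates smart-glasses recordings of the sixteen driving
#' activities: four EOG channels at a native 200 Hz and three accelerometer
#' axes (range +/- 2 g) at a native 100 Hz.  Defaults reflect the study
#' design the generator stands in for: 1200 primary recordings split evenly
#' over 12 classes and 700 secondary recordings split evenly over 4 classes,
#' with durations between 2.06 s and 60.26 s.
#'
#' EOG amplitudes are in arbitrary units (the device's raw units are not
#' physiologically calibrated); downstream z-scoring makes the scale
#' immaterial.  Noise terms model the contamination the preprocessing chain
#' is designed to remove: powerline pickup (50 or 60 Hz), slow baseline
#' drift, sparse spikes and white sensor noise.
#'
#' @param n_primary,n_secondary Number of primary / secondary recordings.
#' @param duration_range_s Admissible duration range in seconds.
#' @param saccade_amplitude Peak horizontal saccade potential (arbitrary units).
#' @param blink_rate Spontaneous blink rate in events per second.
#' @param head_motion_amplitude Peak head/trunk acceleration in g.
#' @param powerline_freq_Hz Mains frequency, 50 or 60 Hz.
#' @param powerline_amp,drift_amp Amplitudes of the mains and drift terms.
#' @param spike_rate Sparse artefact spikes per second.
#' @param eog_noise_sd,acc_noise_sd White-noise standard deviations.
#' @param seed Master seed for dataset generation.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_primary = 1200, n_secondary = 700,
                             duration_range_s = c(2.06, 60.26),
                             saccade_amplitude = 100, blink_rate = 0.2,
                             head_motion_amplitude = 0.5,
                             powerline_freq_Hz = 50, powerline_amp = 8,
                             drift_amp = 30, spike_rate = 0.05,
                             eog_noise_sd = 5, acc_noise_sd = 0.02,
                             seed = 1L) {
  stopifnot(n_primary >= 0, n_secondary >= 0,
            length(duration_range_s) == 2L,
            duration_range_s[1] <= duration_range_s[2])
  if (!powerline_freq_Hz %in% c(50, 60)) {
    stop("powerline_freq_Hz must be 50 or 60", call. = FALSE)
  }
  structure(list(
    n_primary = as.integer(n_primary), n_secondary = as.integer(n_secondary),
    duration_range_s = as.numeric(duration_range_s),
    saccade_amplitude = saccade_amplitude, blink_rate = blink_rate,
    head_motion_amplitude = head_motion_amplitude,
    powerline_freq_Hz = powerline_freq_Hz, powerline_amp = powerline_amp,
    drift_amp = drift_amp, spike_rate = spike_rate,
    eog_noise_sd = eog_noise_sd, acc_noise_sd = acc_noise_sd,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' @rdname synthetic_config
#' @param config A `synthetic_config`.
#' @export
noise_free <- function(config) {
  config$powerline_amp <- 0
  config$drift_amp <- 0
  config$spike_rate <- 0
  config$eog_noise_sd <- 0
  config$acc_noise_sd <- 0
  config$blink_rate <- 0
  config
}

EOG_RATE <- 200
ACC_RATE <- 100

#' Construct a raw multichannel recording
#'
#' Container for one labelled recording with the channel identities of the
#' glasses: `eog_h = eog_l - eog_r` and `eog_v = -(eog_l + eog_r)/2`
#' (exact for synthetic data), accelerometer values within +/- 2 g, and the
#' accelerometer stream at half the EOG length (100 vs 200 Hz).
#'
#' @param label An `activity_label` (see [label_map()]).
#' @param eog_l,eog_r,eog_h,eog_v EOG channels at `eog_rate` Hz.
#' @param acc_x,acc_y,acc_z Acceleration channels in g at `acc_rate` Hz.
#' @param eog_rate,acc_rate Native sampling rates in Hz.
#' @param timestamps Optional date strings (`dd.mm.yyyy:hh:mm:ss`), one per
#'   EOG sample; generated from a fixed epoch when omitted.
#' @param n_clipped Number of accelerometer samples clipped to +/- 2 g.
#' @return A list of class `raw_recording`.
#' @export
raw_recording <- function(label, eog_l, eog_r, eog_h, eog_v,
                          acc_x, acc_y, acc_z,
                          eog_rate = EOG_RATE, acc_rate = ACC_RATE,
                          timestamps = NULL, n_clipped = 0L) {
  n_eog <- length(eog_l)
  stopifnot(length(eog_r) == n_eog, length(eog_h) == n_eog,
            length(eog_v) == n_eog)
  n_acc <- length(acc_x)
  stopifnot(length(acc_y) == n_acc, length(acc_z) == n_acc)
  expected_acc <- round(n_eog * acc_rate / eog_rate)
  if (n_acc != expected_acc) {
    stop(sprintf("acc length %d inconsistent with eog length %d (rates %g/%g)",
                 n_acc, n_eog, acc_rate, eog_rate), call. = FALSE)
  }
  if (n_acc && max(abs(c(acc_x, acc_y, acc_z))) > 2 + 1e-12) {
    stop("acceleration values exceed the +/- 2 g sensor range", call. = FALSE)
  }
  if (is.null(timestamps)) timestamps <- make_timestamps(n_eog, eog_rate)
  structure(list(
    label = label,
    eog_l = eog_l, eog_r = eog_r, eog_h = eog_h, eog_v = eog_v,
    acc_x = acc_x, acc_y = acc_y, acc_z = acc_z,
    eog_rate = eog_rate, acc_rate = acc_rate,
    timestamps = timestamps,
    sample_index = if (n_eog) 0:(n_eog - 1L) else integer(0),
    n_clipped = as.integer(n_clipped)
  ), class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording %s: %d EOG samples @%g Hz, %d ACC samples @%g Hz (%.2f s)>\n",
              x$label$name, length(x$eog_l), x$eog_rate,
              length(x$acc_x), x$acc_rate, length(x$eog_l) / x$eog_rate))
  invisible(x)
}

#' @export
#' @rdname raw_recording
#' @param x A `raw_recording`.
duration_seconds <- function(x) length(x$eog_l) / x$eog_rate

make_timestamps <- function(n, rate, origin = "01.01.2023:12:00:00") {
  if (n == 0L) return(character(0))
  t0 <- as.POSIXct(origin, format = "%d.%m.%Y:%H:%M:%S", tz = "UTC")
  format(t0 + floor((0:(n - 1L)) / rate), "%d.%m.%Y:%H:%M:%S")
}

# Per-class duration ranges in seconds (within the global 2.06-60.26 s span):
# short secondary actions, long roundabout manoeuvres.
class_duration_range <- function(code) {
  lo <- c(8, 8, 8, 12, 12, 12, 12, 12, 12, 30, 15, 20, 4, 5, 6, 2.06)
  hi <- c(20, 20, 20, 30, 30, 30, 30, 30, 30, 60.26, 30, 40, 10, 12, 15, 8)
  c(lo[code + 1L], hi[code + 1L])
}

#' Synthesize one labelled recording
#'
#' Builds the clean left/right eye potentials and head accelerations from a
#' fixed label-to-event grammar (saccade bursts, scanning sequences, gaze
#' oscillations, vertical excursions and trunk motions -- see the methods
#' vignette), derives the horizontal and vertical EOG channels exactly from
#' the electrode pair, then adds powerline, drift, spike and white noise per
#' the configuration.  Deterministic given `(label, duration_s, config, seed)`.
#'
#' @param label An `activity_label` or a code/name accepted by [label_map()].
#' @param duration_s Duration in seconds, within `config$duration_range_s`.
#' @param config A [synthetic_config()].
#' @param seed Integer seed for this recording.
#' @return A [raw_recording()].
#' @export
synthesize_recording <- function(label, duration_s, config = synthetic_config(),
                                 seed = 1L) {
  if (!inherits(label, "activity_label")) label <- label_map(label)
  rng <- config$duration_range_s
  if (duration_s < rng[1] - 1e-9 || duration_s > rng[2] + 1e-9) {
    stop(sprintf("duration %.3f s outside configured range [%.2f, %.2f]",
                 duration_s, rng[1], rng[2]), call. = FALSE)
  }
  n_acc <- as.integer(round(duration_s * ACC_RATE))
  n_eog <- 2L * n_acc
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  sig <- class_signals(label$code, n_eog, n_acc, config)

  # Electrode potentials; the derived channels are exact by construction.
  l <- sig$gaze_h / 2 - sig$gaze_v
  r <- -sig$gaze_h / 2 - sig$gaze_v
  l <- l + eog_noise(n_eog, config)
  r <- r + eog_noise(n_eog, config)
  h <- l - r
  v <- -(l + r) / 2

  acc <- lapply(list(sig$ax, sig$ay, sig$az), function(a) {
    a + acc_noise(n_acc, config)
  })
  n_clipped <- sum(vapply(acc, function(a) sum(abs(a) > 2), integer(1)))
  acc <- lapply(acc, function(a) pmin(pmax(a, -2), 2))

  raw_recording(label, l, r, h, v, acc[[1]], acc[[2]], acc[[3]],
                n_clipped = n_clipped)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

eog_noise <- function(n, cfg) {
  if (n == 0L) return(numeric(0))
  t <- (0:(n - 1L)) / EOG_RATE
  out <- numeric(n)
  if (cfg$powerline_amp > 0) {
    out <- out + cfg$powerline_amp *
      sin(2 * pi * cfg$powerline_freq_Hz * t + runif(1, 0, 2 * pi))
  }
  if (cfg$drift_amp > 0) {
    f1 <- runif(1, 0.01, 0.05); f2 <- runif(1, 0.05, 0.12)
    out <- out + cfg$drift_amp * (sin(2 * pi * f1 * t + runif(1, 0, 2 * pi)) +
                                    0.5 * sin(2 * pi * f2 * t + runif(1, 0, 2 * pi)))
  }
  if (cfg$spike_rate > 0) {
    k <- rpois(1, cfg$spike_rate * n / EOG_RATE)
    if (k > 0) {
      pos <- sample.int(n, k, replace = TRUE)
      amp <- runif(k, 1, 1.5) * cfg$saccade_amplitude * sample(c(-1, 1), k, TRUE)
      for (i in seq_len(k)) {
        w <- min(sample(1:2, 1), n - pos[i] + 1L)
        out[pos[i]:(pos[i] + w - 1L)] <- out[pos[i]:(pos[i] + w - 1L)] + amp[i]
      }
    }
  }
  if (cfg$eog_noise_sd > 0) out <- out + rnorm(n, 0, cfg$eog_noise_sd)
  out
}

acc_noise <- function(n, cfg) {
  if (n == 0L) return(numeric(0))
  out <- numeric(n)
  if (cfg$acc_noise_sd > 0) out <- out + rnorm(n, 0, cfg$acc_noise_sd)
  if (cfg$spike_rate > 0) {
    k <- rpois(1, 0.5 * cfg$spike_rate * n / ACC_RATE)
    if (k > 0) {
      pos <- sample.int(n, k, replace = TRUE)
      out[pos] <- out[pos] + runif(k, 0.2, 0.5) * sample(c(-1, 1), k, TRUE)
    }
  }
  out
}

# ---------------------------------------------------------------------------
# Label -> event grammar.  Returns clean (noise-free) component signals:
# gaze_h / gaze_v at 200 Hz (horizontal / vertical gaze potential) and
# ax / ay / az at 100 Hz (lateral, longitudinal, vertical acceleration in g,
# with gravity on az).  Event positions/amplitudes carry small seeded jitter
# so recordings within a class differ.
class_signals <- function(code, n_eog, n_acc, cfg) {
  A <- cfg$saccade_amplitude
  M <- cfg$head_motion_amplitude
  gh <- numeric(n_eog); gv <- numeric(n_eog)
  ax <- numeric(n_acc); ay <- numeric(n_acc)
  az <- rep(1, n_acc)  # gravity along the vertical axis at rest
  dur <- n_eog / EOG_RATE

  jit <- function(x, p = 0.12) x * runif(1, 1 - p, 1 + p)
  jfrac <- function(f) min(0.95, max(0.02, f + runif(1, -0.03, 0.03)))
  put <- function(x, kind, amp, dsec, frac, rate) {
    w <- make_event_template(kind, amp, dsec, rate)
    start <- max(1L, round(jfrac(frac) * (length(x) - length(w))) + 1L)
    add_event(x, w, start)
  }

  side <- 0  # -1 left, +1 right for lateralised classes
  if (code %in% c(0L, 3L, 5L, 7L, 9L)) side <- -1
  if (code %in% c(1L, 4L, 6L, 8L, 10L)) side <- 1

  if (code %in% 0:2) {            # crossroad: check saccades + one turn
    if (code == 2L) {
      gh <- put(gh, "saccade", jit(-A), jit(0.5), 0.30, EOG_RATE)
      gh <- put(gh, "saccade", jit(+A), jit(0.5), 0.48, EOG_RATE)
      ay <- put(ay, "reach", jit(0.4 * M), jit(0.15 * dur), 0.5, ACC_RATE)
    } else {
      gh <- put(gh, "saccade", side * jit(A), jit(0.4), 0.20, EOG_RATE)
      gh <- put(gh, "saccade", side * jit(A), jit(0.4), 0.35, EOG_RATE)
      gh <- put(gh, "saccade", side * jit(1.2 * A), jit(1.5), 0.55, EOG_RATE)
      ax <- put(ax, "head_turn", side * jit(M), jit(0.30 * dur), 0.5, ACC_RATE)
      ay <- put(ay, "reach", jit(0.3 * M), jit(0.12 * dur), 0.45, ACC_RATE)
    }
  } else if (code %in% 3:8) {     # parking: side-biased scanning saccades,
    # subtype-specific scan counts and shunting (accy) patterns
    reps <- c(3L, 3L, 6L, 6L, 4L, 4L)[code - 2L]
    fr <- seq(0.15, 0.82, length.out = reps)
    for (i in seq_len(reps)) {
      gh <- put(gh, "saccade", side * jit(A), jit(0.6), fr[i], EOG_RATE)
      gh <- put(gh, "saccade", -side * jit(0.45 * A), jit(0.4), fr[i] + 0.04,
                EOG_RATE)
      ax <- put(ax, "head_turn", side * (-1)^(i - 1L) * jit(0.8 * M),
                jit(1.2), fr[i], ACC_RATE)
    }
    # sustained lateral component: the vehicle arcs toward the parking side
    ax <- put(ax, "reach", side * jit(0.5 * M), jit(0.45 * dur), 0.5, ACC_RATE)
    subtype <- (code - 3L) %/% 2L  # 0 diagonal, 1 parallel, 2 perpendicular
    if (subtype == 0L) {
      ay <- put(ay, "reach", jit(-0.45 * M), jit(0.10 * dur), 0.30, ACC_RATE)
      ay <- put(ay, "reach", jit(+0.45 * M), jit(0.10 * dur), 0.70, ACC_RATE)
    } else if (subtype == 1L) {   # parallel: back-and-forth shunting
      ay <- put(ay, "reach", jit(-0.5 * M), jit(0.08 * dur), 0.30, ACC_RATE)
      ay <- put(ay, "reach", jit(+0.5 * M), jit(0.08 * dur), 0.50, ACC_RATE)
      ay <- put(ay, "reach", jit(-0.5 * M), jit(0.08 * dur), 0.70, ACC_RATE)
    } else {                      # perpendicular: one long reverse
      ay <- put(ay, "reach", jit(-0.6 * M), jit(0.30 * dur), 0.55, ACC_RATE)
    }
  } else if (code %in% 9:11) {    # roundabout: sustained lateral oscillation
    cycles <- c(3L, 1L, 2L)[code - 8L]
    lead <- if (code == 10L) 1 else -1
    gh <- gh + oscillation(n_eog, cycles, lead * jit(0.8 * A), 0.15, 0.85)
    ax <- ax + oscillation(n_acc, cycles, lead * jit(0.9 * M), 0.15, 0.85)
    fr <- seq(0.18, 0.82, length.out = cycles + 1L)
    for (i in seq_len(cycles + 1L)) {  # one glance per exit passed
      gh <- put(gh, "saccade", lead * jit(0.9 * A), jit(0.5), fr[i], EOG_RATE)
    }
    if (code == 11L) {            # straight: brake at entry and exit islands
      ay <- put(ay, "reach", jit(-0.4 * M), jit(0.06 * dur), 0.12, ACC_RATE)
      ay <- put(ay, "reach", jit(-0.4 * M), jit(0.06 * dur), 0.88, ACC_RATE)
    } else {
      ay <- put(ay, "reach", jit(-0.3 * M), jit(0.08 * dur), 0.12, ACC_RATE)
      ay <- put(ay, "reach", jit(+0.3 * M), jit(0.08 * dur), 0.88, ACC_RATE)
    }
  } else if (code == 12L) {       # bending: single large slow downward dive
    gv <- put(gv, "reach", jit(-1.8 * A), jit(0.55 * dur), 0.5, EOG_RATE)
    az <- put(az, "reach", jit(-0.9 * M), jit(0.50 * dur), 0.5, ACC_RATE)
    ay <- put(ay, "reach", jit(0.5 * M), jit(0.35 * dur), 0.5, ACC_RATE)
  } else if (code == 13L) {       # drinking: two upward tilt-back excursions
    gv <- put(gv, "reach", jit(1.3 * A), jit(0.22 * dur), 0.30, EOG_RATE)
    gv <- put(gv, "reach", jit(1.3 * A), jit(0.22 * dur), 0.62, EOG_RATE)
    az <- put(az, "reach", jit(0.7 * M), jit(0.20 * dur), 0.30, ACC_RATE)
    az <- put(az, "reach", jit(0.7 * M), jit(0.20 * dur), 0.62, ACC_RATE)
  } else if (code == 14L) {       # eating: rhythmic chewing/bite pulses
    fr <- seq(0.15, 0.85, length.out = 5L)
    for (f in fr) {
      gv <- put(gv, "blink", jit(1.1 * A), jit(0.5), f, EOG_RATE)
    }
    for (f in fr[c(1, 3, 5)]) {
      az <- put(az, "head_turn", jit(0.35 * M), jit(1.0), f, ACC_RATE)
    }
  } else if (code == 15L) {       # turning back: huge horizontal sweep with
    # the over-the-shoulder vertical component and a trunk twist
    gh <- put(gh, "saccade", jit(1.7 * A), jit(0.55 * dur), 0.5, EOG_RATE)
    gv <- put(gv, "reach", jit(1.4 * A), jit(0.50 * dur), 0.5, EOG_RATE)
    ay <- put(ay, "head_turn", jit(1.0 * M), jit(0.45 * dur), 0.5, ACC_RATE)
    az <- put(az, "reach", jit(-0.8 * M), jit(0.45 * dur), 0.5, ACC_RATE)
    ax <- put(ax, "head_turn", jit(-0.8 * M), jit(0.45 * dur), 0.5, ACC_RATE)
  }

  # spontaneous blinks on the vertical gaze channel, all classes
  if (cfg$blink_rate > 0) {
    k <- rpois(1, cfg$blink_rate * dur)
    if (k > 0) {
      for (f in runif(k, 0.05, 0.95)) {
        gv <- put(gv, "blink", jit(0.9 * A), 0.25, f, EOG_RATE)
      }
    }
  }
  list(gaze_h = gh, gaze_v = gv, ax = ax, ay = ay, az = az)
}

# Hann-enveloped sinusoid with an integer number of cycles spanning
# [from, to] of the n-sample series; zero outside.
oscillation <- function(n, cycles, amp, from, to) {
  out <- numeric(n)
  i1 <- max(1L, round(from * n)); i2 <- min(n, round(to * n))
  if (i2 - i1 < 3L) return(out)
  u <- seq(0, 1, length.out = i2 - i1 + 1L)
  out[i1:i2] <- amp * 0.5 * (1 - cos(2 * pi * u)) * sin(2 * pi * cycles * u)
  out
}

#' Generate a labelled synthetic dataset
#'
#' Spreads `n_primary` recordings evenly over the 12 primary classes and
#' `n_secondary` over the 4 secondary classes (remainders distributed
#' round-robin by ascending label code), draws per-class durations, and
#' synthesizes each recording with a seed derived from `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @param dir Optional directory; when given, recordings are written as JINS
#'   CSV files and the manifest as `manifest.tsv` there.
#' @return A list with `recordings` (list of [raw_recording()]) and
#'   `manifest` (data frame: path, label, name, duration_s, seed, n_clipped).
#' @export
generate_dataset <- function(config = synthetic_config(), dir = NULL) {
  tab <- activity_labels()
  counts <- c(spread_evenly(config$n_primary, 12L),
              spread_evenly(config$n_secondary, 4L))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)

  rows <- list(); recs <- list(); idx <- 0L
  for (code in 0:15) {
    k <- counts[code + 1L]
    if (k == 0L) next
    rng <- class_duration_range(code)
    rng <- c(max(rng[1], config$duration_range_s[1]),
             min(rng[2], config$duration_range_s[2]))
    durations <- runif(k, rng[1], rng[2])
    for (j in seq_len(k)) {
      idx <- idx + 1L
      seed_j <- as.integer((as.numeric(config$seed) * 1000003 + idx * 7919) %%
                             2147483647)
      rec <- synthesize_recording(label_map(code), durations[j], config, seed_j)
      recs[[idx]] <- rec
      path <- NA_character_
      if (!is.null(dir)) {
        path <- file.path(dir, sprintf("rec_%04d_label%02d.csv", idx, code))
        write_jins_csv(rec, path)
      }
      rows[[idx]] <- data.frame(
        path = path, label = code, name = tab$name[code + 1L],
        duration_s = durations[j], seed = seed_j,
        n_clipped = rec$n_clipped, stringsAsFactors = FALSE
      )
    }
  }
  manifest <- if (idx) do.call(rbind, rows) else
    data.frame(path = character(0), label = integer(0), name = character(0),
               duration_s = numeric(0), seed = integer(0),
               n_clipped = integer(0))
  if (!is.null(dir)) {
    utils::write.table(manifest, file.path(dir, "manifest.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  list(recordings = recs, manifest = manifest)
}

# n items over k classes, remainder round-robin by ascending class index
spread_evenly <- function(n, k) {
  base <- n %/% k
  extra <- n %% k
  base + as.integer(seq_len(k) <= extra)
}
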