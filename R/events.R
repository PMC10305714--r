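#' Event waveform primitives
#'
#' Closed-form templates for the elementary eye and head movements that make
#' up a driving activity: `saccade` (smooth sigmoidal step with an
#' exponential return to baseline), `blink` (biphasic pulse with a small
#' rebound lobe), `head_turn` (Gaussian-windowed single-cycle sinusoid, used
#' for yaw/roll accelerations) and `reach` (slow unimodal raised-cosine
#' excursion, used for trunk and arm movements).
#'
#' Every template starts and ends exactly at baseline 0 and its peak
#' magnitude equals `abs(amplitude)` exactly (the waveform is normalised to
#' unit peak before scaling).
#'
#' @param kind One of `"saccade"`, `"blink"`, `"head_turn"`, `"reach"`.
#' @param amplitude Peak value; the sign flips the waveform.
#' @param duration_s Event duration in seconds (> 0).
#' @param rate_Hz Sampling rate in Hz (> 0).
#' @return Numeric vector of `round(duration_s * rate_Hz)` samples.
#' @export
#' @examples
#' w <- make_event_template("saccade", 100, 0.2, 200)
#' length(w)  # 40
#' max(w)     # 100
make_event_template <- function(kind = c("saccade", "blink", "head_turn", "reach"),
                                amplitude, duration_s, rate_Hz) {
  kind <- match.arg(kind)
  if (!is.numeric(duration_s) || length(duration_s) != 1L || duration_s <= 0) {
    stop("duration_s must be a positive scalar", call. = FALSE)
  }
  if (!is.numeric(rate_Hz) || length(rate_Hz) != 1L || rate_Hz <= 0) {
    stop("rate_Hz must be a positive scalar", call. = FALSE)
  }
  n <- max(1L, as.integer(round(duration_s * rate_Hz)))
  t <- if (n == 1L) 0 else seq(0, 1, length.out = n)
  w <- switch(kind,
    saccade = saccade_shape(t),
    blink = blink_shape(t),
    head_turn = head_turn_shape(t),
    reach = 0.5 * (1 - cos(2 * pi * t))
  )
  peak <- max(abs(w))
  if (peak > 0) w <- w / peak
  amplitude * w
}

# Raised-cosine rise (0-30% of the event), plateau (30-60%), exponential
# return pinned to end exactly at 0.
saccade_shape <- function(t) {
  w <- numeric(length(t))
  rise <- t < 0.3
  hold <- t >= 0.3 & t < 0.6
  fall <- t >= 0.6
  w[rise] <- 0.5 * (1 - cos(pi * t[rise] / 0.3))
  w[hold] <- 1
  u <- (t[fall] - 0.6) / 0.4
  w[fall] <- (exp(-5 * u) - exp(-5)) / (1 - exp(-5))
  w
}

# Main lobe then a 30% rebound of opposite sign.
blink_shape <- function(t) {
  w <- numeric(length(t))
  main <- t <= 0.6
  w[main] <- sin(pi * t[main] / 0.6)
  w[!main] <- -0.3 * sin(pi * (t[!main] - 0.6) / 0.4)
  w
}

# Gaussian window times one full sine cycle; sin(2*pi*t) is exactly 0 at both
# ends, so no edge correction is needed.
head_turn_shape <- function(t, cycles = 1) {
  exp(-0.5 * ((t - 0.5) / 0.22)^2) * sin(2 * pi * cycles * t)
}

# Add `w` into `x` starting at sample `start` (1-based), clipping at borders.
add_event <- function(x, w, start) {
  n <- length(x)
  idx <- seq.int(start, length.out = length(w))
  keep <- idx >= 1L & idx <= n
  x[idx[keep]] <- x[idx[keep]] + w[keep]
  x
}
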