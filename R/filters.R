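#' Butterworth low-pass coefficients
#'
#' Digital Butterworth design by pole placement and bilinear transform with
#' frequency prewarping.  The analytic magnitude of the analog prototype,
#' `|H(f)| = 1/sqrt(1 + (f/fc)^(2n))`, is the oracle the tests compare
#' against.
#'
#' @param cutoff_Hz Cut-off frequency (0 < cutoff < rate/2).
#' @param rate_Hz Sampling rate.
#' @param order Filter order (>= 1).
#' @return List with numerator `b` and monic denominator `a`.
#' @keywords internal
butter_lowpass <- function(cutoff_Hz, rate_Hz, order = 2L) {
  if (cutoff_Hz <= 0 || cutoff_Hz >= rate_Hz / 2) {
    stop("cutoff must lie strictly between 0 and the Nyquist rate",
         call. = FALSE)
  }
  n <- as.integer(order)
  W <- tan(pi * cutoff_Hz / rate_Hz)              # prewarped analog cutoff
  k <- seq_len(n)
  p_analog <- W * exp(1i * pi * (2 * k + n - 1) / (2 * n))
  z <- (1 + p_analog) / (1 - p_analog)            # bilinear transform
  a <- Re(poly_from_roots(z))
  b <- Re(poly_from_roots(rep(-1 + 0i, n)))       # n zeros at z = -1
  b <- b * sum(a) / sum(b)                        # unit gain at DC
  list(b = b, a = a)
}

poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (ri in r) p <- c(p, 0) - c(0, p) * ri
  p
}

# Steady-state initial filter state (direct form II transposed), so that a
# constant input produces a constant output from the first sample.
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  if (n == 1L) return(numeric(0))
  comp <- matrix(0, n - 1L, n - 1L)               # companion matrix of a
  comp[1, ] <- -a[-1] / a[1]
  if (n > 2L) comp[cbind(2:(n - 1L), 1:(n - 2L))] <- 1
  B <- b[-1] - a[-1] * b[1]
  solve(diag(n - 1L) - t(comp), B)
}

#' Zero-phase low-pass filtering
#'
#' Applies a Butterworth low-pass forward and then backward over the series,
#' which doubles the effective order and cancels the phase response: the
#' magnitude response is the squared Butterworth magnitude and band-limited
#' components are not delayed.  Edges are handled by odd-reflection padding
#' with steady-state initial conditions.
#'
#' @param x Numeric series of length greater than `3 * order`.
#' @param cutoff_Hz Cut-off frequency in Hz.
#' @param rate_Hz Sampling rate in Hz.
#' @param order Order of the underlying one-pass Butterworth (default 2).
#' @return Filtered series, same length as `x`.
#' @export
#' @examples
#' t <- seq(0, 1, by = 1 / 200)
#' y <- lowpass_zerophase(sin(2 * pi * 2 * t), 20, 200)
lowpass_zerophase <- function(x, cutoff_Hz, rate_Hz, order = 2L) {
  if (length(x) <= 3L * order) {
    stop(sprintf("series too short for zero-phase filtering (need > %d samples)",
                 3L * order), call. = FALSE)
  }
  coefs <- butter_lowpass(cutoff_Hz, rate_Hz, order)
  filtfilt_1d(coefs$b, coefs$a, x)
}

filtfilt_1d <- function(b, a, x) {
  n <- length(x)
  nfilt <- max(length(a), length(b))
  padlen <- min(n - 1L, 3L * nfilt)
  ext <- c(2 * x[1] - x[(padlen + 1L):2],
           x,
           2 * x[n] - x[(n - 1L):(n - padlen)])
  zi <- lfilter_zi(b, a)
  y <- iir_filter_cpp(b, a, ext, zi * ext[1])
  y <- rev(y)
  y <- iir_filter_cpp(b, a, y, zi * y[1])
  y <- rev(y)
  y[(padlen + 1L):(padlen + n)]
}

#' Hamming-window FIR low-pass coefficients
#'
#' Windowed-sinc design, normalised to unit DC gain; odd length gives an
#' integer group delay that [acc_clean()] compensates exactly.
#'
#' @param n_taps Filter length (odd).
#' @param cutoff_Hz,rate_Hz Cut-off and sampling rate in Hz.
#' @return Numeric vector of `n_taps` coefficients.
#' @keywords internal
fir_hamming_lowpass <- function(n_taps = 31L, cutoff_Hz, rate_Hz) {
  if (n_taps %% 2L == 0L) stop("n_taps must be odd", call. = FALSE)
  if (cutoff_Hz <= 0 || cutoff_Hz >= rate_Hz / 2) {
    stop("cutoff must lie strictly between 0 and the Nyquist rate",
         call. = FALSE)
  }
  m <- seq_len(n_taps) - 1L - (n_taps - 1L) / 2
  fcn <- cutoff_Hz / rate_Hz
  h <- 2 * fcn * sinc(2 * fcn * m)
  w <- 0.54 - 0.46 * cos(2 * pi * (seq_len(n_taps) - 1L) / (n_taps - 1L))
  h <- h * w
  h / sum(h)
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

#' Edge-replicated running median
#'
#' @param x Numeric series.
#' @param k Odd window length.
#' @return Filtered series, same length as `x`.
#' @keywords internal
median_filter <- function(x, k = 5L) {
  if (k %% 2L == 0L) stop("median kernel must be odd", call. = FALSE)
  n <- length(x)
  if (k == 1L || n == 0L) return(x)
  h <- (k - 1L) %/% 2L
  xp <- c(rep(x[1], h), x, rep(x[n], h))
  y <- stats::runmed(xp, k, endrule = "keep")
  y[(h + 1L):(h + n)]
}
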