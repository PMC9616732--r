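#' @keywords internal
"_PACKAGE"

# Zero-phase Butterworth band-pass filtering in second-order sections.
#
# The slow-oscillation band (0.3-1.25 Hz at fs = 200) sits at a normalized
# frequency of ~0.003, where an 8-pole transfer function in expanded (b, a)
# form is numerically ill-conditioned. Filtering is therefore done as a
# cascade of biquads designed directly from the analog Butterworth poles
# (low-pass prototype -> band-pass transform -> bilinear transform), the
# standard construction used by scientific DSP libraries.

# Analog prototype poles for an order-n Butterworth low-pass (cutoff 1 rad/s)
butter_prototype_poles <- function(n) {
  k <- seq_len(n)
  complex(modulus = 1, argument = pi * (2 * k + n - 1) / (2 * n))
}

#' Design a digital Butterworth band-pass filter as second-order sections
#'
#' @param order Prototype filter order; the band-pass filter has `2 * order`
#'   poles. The detectors use `order = 4`.
#' @param band Numeric length-2, pass-band edges in Hz.
#' @param fs Sampling rate in Hz.
#' @return A list with `sos` (matrix, one row per section: b0 b1 b2 a0 a1 a2)
#'   and `gain` (scalar applied to the first section), unity gain at the
#'   geometric band centre.
#' @keywords internal
butter_bandpass_sos <- function(order, band, fs) {
  stopifnot(length(band) == 2, band[1] > 0, band[1] < band[2])
  if (band[2] >= fs / 2) {
    stop("band edge ", band[2], " Hz is at or above the Nyquist frequency (",
         fs / 2, " Hz)")
  }
  p <- butter_prototype_poles(order)
  # pre-warped analog edge frequencies
  w1 <- 2 * fs * tan(pi * band[1] / fs)
  w2 <- 2 * fs * tan(pi * band[2] / fs)
  w0 <- sqrt(w1 * w2)
  bw <- w2 - w1
  # low-pass -> band-pass: each prototype pole yields a pair
  pb <- complex(0)
  for (pp in p) {
    a <- pp * bw / 2
    d <- sqrt(a^2 - w0^2 + 0i)
    pb <- c(pb, a + d, a - d)
  }
  # bilinear transform of poles; zeros map to z = 1 (order of them) and
  # z = -1 (order of them)
  fs2 <- 2 * fs
  zd <- (fs2 + pb) / (fs2 - pb)
  # pair poles into conjugate pairs
  pos <- zd[Im(zd) >= 0]
  neg <- zd[Im(zd) < 0]
  stopifnot(length(pos) == length(neg))
  used <- rep(FALSE, length(neg))
  sos <- matrix(0, nrow = length(pos), ncol = 6)
  for (i in seq_along(pos)) {
    dif <- abs(neg - Conj(pos[i])) + ifelse(used, Inf, 0)
    j <- which.min(dif)
    used[j] <- TRUE
    q1 <- pos[i]; q2 <- neg[j]
    # denominator (1 - q1 z^-1)(1 - q2 z^-1); numerator (1 - z^-1)(1 + z^-1)
    sos[i, ] <- c(1, 0, -1, 1, -Re(q1 + q2), Re(q1 * q2))
  }
  # normalize gain at the geometric centre of the digital band
  wc <- 2 * pi * sqrt(band[1] * band[2]) / fs
  z1 <- exp(-1i * wc)
  h <- 1 + 0i
  for (i in seq_len(nrow(sos))) {
    h <- h * (sos[i, 1] + sos[i, 2] * z1 + sos[i, 3] * z1^2) /
      (sos[i, 4] + sos[i, 5] * z1 + sos[i, 6] * z1^2)
  }
  list(sos = sos, gain = 1 / Mod(h))
}

# One biquad applied causally (direct form via MA then AR recursion)
biquad_filter <- function(x, s) {
  n <- length(x)
  v <- s[1] * x
  if (n > 1) v[2:n] <- v[2:n] + s[2] * x[1:(n - 1)]
  if (n > 2) v[3:n] <- v[3:n] + s[3] * x[1:(n - 2)]
  as.numeric(stats::filter(v, c(-s[5], -s[6]), method = "recursive"))
}

sos_filter <- function(x, filt) {
  y <- x * filt$gain
  for (i in seq_len(nrow(filt$sos))) y <- biquad_filter(y, filt$sos[i, ])
  y
}

# Forward-backward (zero-phase) application with odd-reflection edge padding.
sos_filtfilt <- function(x, filt, padlen = NULL) {
  n <- length(x)
  if (is.null(padlen)) padlen <- min(n - 1L, max(200L, 9L * nrow(filt$sos)))
  if (padlen > 0) {
    head_pad <- 2 * x[1] - x[(padlen + 1):2]
    tail_pad <- 2 * x[n] - x[(n - 1):(n - padlen)]
    xe <- c(head_pad, x, tail_pad)
  } else {
    xe <- x
  }
  y <- sos_filter(xe, filt)
  y <- rev(sos_filter(rev(y), filt))
  if (padlen > 0) y <- y[(padlen + 1):(padlen + n)]
  y
}

#' Theoretical squared-magnitude response of the two-pass Butterworth band-pass
#'
#' Closed form used as an independent oracle in tests: a single pass has
#' `|H(f)|^2 = 1 / (1 + Q(f)^(2 n))` with
#' `Q(f) = (f^2 - f1 f2) / (f (f2 - f1))`; the forward-backward filter applies
#' it twice.
#'
#' @param f Frequency in Hz.
#' @param band Pass-band edges in Hz.
#' @param order Prototype order.
#' @return Two-pass gain `|H(f)|^2` (amplitude ratio for the zero-phase
#'   filter).
#' @export
butter_bandpass_gain <- function(f, band, order = 4) {
  q <- (f^2 - band[1] * band[2]) / (f * (band[2] - band[1]))
  (1 / (1 + q^(2 * order)))
}

#' Band-pass filter a recording with a zero-phase Butterworth filter
#'
#' Applies an order-`order` Butterworth band-pass forward and backward
#' (zero-phase, effective attenuation is the squared magnitude response) to
#' every channel.
#'
#' @param rec A [recording()].
#' @param band Numeric length-2 pass band in Hz; must lie inside
#'   `(0, fs / 2)`.
#' @param order Filter order of the underlying single-pass filter (default 4).
#' @return A filtered [recording()] with the same channels and sampling rate.
#' @export
bandpass <- function(rec, band, order = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (band[1] <= 0 || band[2] >= rec$fs / 2) {
    stop("band (", band[1], ", ", band[2], ") Hz must lie strictly inside (0, ",
         rec$fs / 2, ") Hz")
  }
  filt <- butter_bandpass_sos(order, band, rec$fs)
  out <- rec
  pl <- filtfilt_padlen(ncol(rec$signal), band, rec$fs)
  for (i in seq_len(nrow(rec$signal))) {
    out$signal[i, ] <- sos_filtfilt(rec$signal[i, ], filt, padlen = pl)
  }
  out
}

# Edge padding long enough for the filter transient at the low band edge
filtfilt_padlen <- function(n, band, fs) {
  min(n - 1L, as.integer(round(3 * fs / band[1])))
}

# Analytic signal via FFT (Hilbert transform)
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Centered moving average with edge replication, window of w samples (odd)
moving_average <- function(x, w) {
  if (w <= 1) return(x)
  if (w %% 2 == 0) w <- w + 1L
  half <- (w - 1L) / 2L
  xe <- c(rep(x[1], half), x, rep(x[length(x)], half))
  as.numeric(stats::filter(xe, rep(1 / w, w), sides = 2))[(half + 1):(half + length(x))]
}
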