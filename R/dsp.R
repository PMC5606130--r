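# Shared filtering and spectral primitives. All frequency-domain features in
# the package are based on Welch estimates with 2 s segments, 1 s overlap and
# a Hann taper; all filters are zero-phase (forward-backward Butterworth).

#' @rdname welchPSD
#' @export
setClass("WelchPSD",
  representation(
    freqs = "numeric",     # Hz, ascending from 0 to fs/2
    density = "numeric",   # one-sided PSD, V^2/Hz
    settings = "list"      # segmentS, overlapS, window, fs
  )
)

setValidity("WelchPSD", function(object) {
  if (length(object@freqs) != length(object@density))
    return("'freqs' and 'density' must have equal length")
  if (any(object@density < -1e-30)) return("density must be nonnegative")
  if (is.unsorted(object@freqs)) return("'freqs' must be ascending")
  TRUE
})

#' @describeIn welchPSD frequency grid in Hz.
#' @param x A `WelchPSD`.
#' @export
psdFreqs <- function(x) x@freqs

#' @describeIn welchPSD one-sided spectral density in V^2/Hz.
#' @export
psdDensity <- function(x) x@density

setMethod("show", "WelchPSD", function(object) {
  s <- object@settings
  cat(sprintf(
    "WelchPSD: %d bins, 0-%g Hz (bin %g Hz); %g s segments, %g s overlap, %s\n",
    length(object@freqs), max(object@freqs),
    object@freqs[2] - object@freqs[1], s$segmentS, s$overlapS, s$window))
})

# One-sided periodogram of a single Hann-tapered segment; density in V^2/Hz.
.segmentPeriodogram <- function(seg, fs, w, wnorm) {
  n <- length(seg)
  X <- fft(seg * w)
  nhalf <- n %/% 2L
  p <- (Mod(X[seq_len(nhalf + 1L)])^2) / (fs * wnorm)
  # fold negative frequencies onto positive ones (DC and Nyquist excluded)
  if (nhalf > 1L) p[2:nhalf] <- 2 * p[2:nhalf]
  p
}

#' Welch power spectral density estimate
#'
#' One-sided Welch PSD with the settings used throughout the package:
#' 2-second segments, 1-second overlap, Hann window. Scaled so that the sum
#' of `density * bin_width` approximates the time-domain variance
#' (for zero-mean signals).
#'
#' @param x Numeric signal in volts.
#' @param fs Sampling rate in Hz.
#' @param segmentS Segment length in seconds (default 2).
#' @param overlapS Overlap between consecutive segments in seconds (default 1).
#' @return A [WelchPSD-class] object.
#' @examples
#' psd <- welchPSD(sin(2 * pi * 10 * seq(0, 30, by = 1/200))[-1], fs = 200)
#' psdFreqs(psd)[which.max(psdDensity(psd))]  # 10 Hz
#' @aliases WelchPSD-class
#' @export
welchPSD <- function(x, fs, segmentS = 2, overlapS = 1) {
  n <- as.integer(round(segmentS * fs))
  hop <- as.integer(round((segmentS - overlapS) * fs))
  if (length(x) < n)
    stop("signal shorter than one Welch segment (", segmentS, " s)")
  w <- signal::hanning(n)
  wnorm <- sum(w^2)
  nseg <- (length(x) - n) %/% hop + 1L
  acc <- numeric(n %/% 2L + 1L)
  for (k in seq_len(nseg)) {
    i0 <- (k - 1L) * hop
    acc <- acc + .segmentPeriodogram(x[(i0 + 1L):(i0 + n)], fs, w, wnorm)
  }
  new("WelchPSD",
      freqs = (0:(n %/% 2L)) * fs / n,
      density = acc / nseg,
      settings = list(segmentS = segmentS, overlapS = overlapS,
                      window = "hann", fs = fs, nSegments = nseg))
}

#' Mean spectral density over a frequency band
#'
#' Mean Welch PSD density over the frequency bins falling in `band`
#' (inclusive endpoints), in V^2/Hz. This is the quantity that the
#' channel-rejection rule thresholds.
#'
#' @param x Numeric signal in volts.
#' @param fs Sampling rate in Hz.
#' @param band Length-2 numeric, band edges in Hz.
#' @param psd Optionally, a precomputed [WelchPSD-class] for `x` (then `x`
#'   and `fs` are ignored).
#' @return Mean density over the band, V^2/Hz.
#' @examples
#' bandPowerDensity(rnorm(6000) * 1e-6, fs = 200, band = c(10, 35))
#' @export
bandPowerDensity <- function(x, fs, band, psd = NULL) {
  if (is.null(psd)) {
    if (band[2] >= fs / 2) stop("band extends to or beyond Nyquist")
    psd <- welchPSD(x, fs)
  }
  sel <- psd@freqs >= band[1] & psd@freqs <= band[2]
  if (!any(sel)) stop("no frequency bins in band [", band[1], ", ", band[2], "] Hz")
  mean(psd@density[sel])
}

#' Zero-phase Butterworth band-pass filter
#'
#' 4th-order Butterworth applied forward and backward (zero phase), so the
#' effective magnitude response is the squared 4th-order response. Output
#' length equals input length.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param lo,hi Passband edges in Hz, `0 <= lo < hi < fs/2`. `lo = 0`
#'   degenerates to a low-pass.
#' @param order Filter order (default 4).
#' @return Filtered signal, same length as `x`.
#' @examples
#' y <- bandpassFilter(rnorm(2000), fs = 200, lo = 2, hi = 32)
#' @export
bandpassFilter <- function(x, fs, lo, hi, order = 4) {
  if (lo < 0 || hi <= lo || hi >= fs / 2)
    stop("invalid band [", lo, ", ", hi, "] Hz at fs = ", fs, " Hz")
  if (lo == 0) {
    bt <- signal::butter(order, hi / (fs / 2), type = "low")
  } else {
    bt <- signal::butter(order, c(lo, hi) / (fs / 2), type = "pass")
  }
  as.numeric(signal::filtfilt(bt, x))
}

#' Zero-phase 50 Hz notch filter
#'
#' Second-order IIR notch (biquad) at 50 Hz with quality factor 30, applied
#' forward-backward. Attenuation at the notch exceeds 30 dB while 45 and
#' 55 Hz are altered by less than 1 dB.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz; must exceed 100 Hz.
#' @param f0 Notch frequency in Hz (default 50, European mains).
#' @param Q Quality factor (default 30).
#' @return Filtered signal, same length as `x`.
#' @examples
#' y <- notchFilter50(sin(2 * pi * 50 * (1:1000) / 200), fs = 200)
#' sqrt(mean(y^2))  # near zero
#' @export
notchFilter50 <- function(x, fs, f0 = 50, Q = 30) {
  if (fs <= 2 * f0) stop("sampling rate too low for a ", f0, " Hz notch")
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  flt <- signal::Arma(b = b / a[1], a = a / a[1])
  as.numeric(signal::filtfilt(flt, x))
}

# Sliding-window RMS with a centred rectangular window of `n` samples
# (shorter at the edges). Used for spindle envelopes.
.slidingRMS <- function(x, n) {
  csum <- cumsum(c(0, x^2))
  half <- n %/% 2L
  N <- length(x)
  i <- seq_len(N)
  lo <- pmax(i - half, 1L)
  hi <- pmin(i + half, N)
  sqrt((csum[hi + 1L] - csum[lo]) / (hi - lo + 1L))
}

# Complex Morlet continuous wavelet transform at a single centre frequency.
# Returns |CWT| over the signal. omega0 = 6 cycles (standard Morlet).
.morletCWTmod <- function(x, fs, f0, omega0 = 6) {
  s <- omega0 / (2 * pi * f0)                # scale in seconds
  half <- ceiling(4 * s * fs)
  t <- (-half:half) / fs
  psi <- pi^(-0.25) * exp(1i * omega0 * t / s) * exp(-t^2 / (2 * s^2))
  psi <- psi / sqrt(s * fs)                  # L2-ish normalisation
  n <- length(x)
  m <- length(psi)
  L <- stats::nextn(n + m - 1L, 2)
  X <- fft(c(x, numeric(L - n)))
  P <- fft(c(psi, numeric(L - m)))
  conv <- fft(X * P, inverse = TRUE) / L
  Mod(conv[(half + 1L):(half + n)])
}
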