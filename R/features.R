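# Per-epoch feature extraction. Each derivation contributes 33 features
# drawn from four filtered views of the full-night signal:
#   EEG path  2-32 Hz   (time-domain F1-F7, spectral F13-F28, events F29-F33)
#   EOG proxy 0.5-30 Hz (F11-F12; eye-movement surrogates from ear data)
#   EMG proxy 32-80 Hz  (F8-F10; muscle-tone surrogates from ear data)
#   sigma     11-16 Hz  (spindle envelope for F29/F33)
# plus a 50 Hz mains notch applied before everything. Filters run once on
# the full-night derivation; epochs are cut afterwards, avoiding per-epoch
# edge transients. The three derivations yield 99 features, derivation-major
# (F1..F33 for LR, then L, then R).

EEG_BAND <- c(2, 32)
EOG_BAND <- c(0.5, 30)
EMG_BAND <- c(32, 80)
SIGMA_BAND <- c(11, 16)
RATIO_EPS <- 1e-30   # V^2; guards ratio denominators at microvolt scales

#' The 99 canonical feature names
#'
#' Feature names in the fixed matrix order: `F1_LR` .. `F33_LR`, then
#' `F1_L` .. `F33_L`, then `F1_R` .. `F33_R`.
#'
#' @return Character vector of length 99.
#' @export
featureNames99 <- function() {
  as.vector(vapply(c("LR", "L", "R"),
                   function(d) paste0("F", 1:33, "_", d), character(33)))
}

# ---------------------------------------------------------------------------
# spectral helpers
# ---------------------------------------------------------------------------

# Spectral edge frequency: frequency below which fraction q of the power in
# the selected bins lies. Bins are treated as cells of width `dF` centred on
# their frequency; the cumulative distribution is linear within each cell.
.spectralEdge <- function(freqs, density, q) {
  tot <- sum(density)
  if (tot <= 0) return(0)
  dF <- if (length(freqs) > 1L) freqs[2] - freqs[1] else 1
  cum <- cumsum(density)
  target <- q * tot
  k <- which(cum >= target - 1e-15 * tot)[1]
  lowEdge <- freqs[k] - dF / 2
  prev <- if (k > 1L) cum[k - 1L] else 0
  lowEdge + dF * (target - prev) / (cum[k] - prev)
}

# Hann periodograms of consecutive non-overlapping `segS`-second windows,
# restricted to the EEG band. Returns list(freqs=, density= bins x nseg).
.subSegmentSpectra <- function(x, fs, segS = 2, band = EEG_BAND) {
  n <- as.integer(round(segS * fs))
  nseg <- length(x) %/% n
  w <- signal::hanning(n)
  wnorm <- sum(w^2)
  freqs <- (0:(n %/% 2L)) * fs / n
  sel <- freqs >= band[1] & freqs <= band[2]
  dens <- vapply(seq_len(nseg), function(k) {
    seg <- x[((k - 1L) * n + 1L):(k * n)]
    .segmentPeriodogram(seg, fs, w, wnorm)[sel]
  }, numeric(sum(sel)))
  list(freqs = freqs[sel], density = dens)
}

# ---------------------------------------------------------------------------
# feature groups (exported per-group for testing and reuse)
# ---------------------------------------------------------------------------

#' Time-domain features F1-F7 of one epoch
#'
#' F1 skewness and F2 kurtosis (third/fourth standardised population
#' moments; a normal signal has kurtosis 3), F3 zero-crossing rate in
#' crossings per second (sign changes, exact zeros skipped), F4 Hjorth
#' mobility `sqrt(var(x')/var(x))` with `x'` the first difference scaled by
#' `fs` (units 1/s), F5 Hjorth complexity `mobility(x')/mobility(x)`,
#' F6 the 75th percentile of `|x|` in volts, and F7 the correlation between
#' the two electrode-group means whose difference forms the derivation.
#' Degenerate (flat) epochs return 0 for every undefined feature.
#'
#' @param x EEG-band (2-32 Hz) epoch, volts.
#' @param groupA,groupB The derivation's minuend and subtrahend group-mean
#'   signals over the same epoch (for F7); `NULL` gives F7 = 0.
#' @param fs Sampling rate in Hz.
#' @return Named numeric vector `F1`..`F7`.
#' @export
timeDomainFeatures <- function(x, groupA = NULL, groupB = NULL, fs) {
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  f1 <- if (m2 > 0) mean((x - mu)^3) / m2^1.5 else 0
  f2 <- if (m2 > 0) mean((x - mu)^4) / m2^2 else 0
  s <- sign(x); s <- s[s != 0]
  f3 <- if (length(s) > 1L) sum(diff(s) != 0) / (n / fs) else 0
  mob <- function(v) {
    vv <- var(v)
    if (!is.finite(vv) || vv <= 0) return(0)
    d <- diff(v) * fs
    sqrt(var(d) / vv)
  }
  f4 <- mob(x)
  f5 <- if (f4 > 0) {
    md <- mob(diff(x) * fs)
    if (md > 0) md / f4 else 0
  } else 0
  f7 <- if (!is.null(groupA) && !is.null(groupB) &&
            sd(groupA) > 0 && sd(groupB) > 0) cor(groupA, groupB) else 0
  c(F1 = f1, F2 = f2, F3 = f3, F4 = f4, F5 = f5,
    F6 = unname(quantile(abs(x), 0.75)), F7 = f7)
}

#' EMG-proxy features F8-F10 of one epoch
#'
#' Computed on the 32-80 Hz path, which carries muscle tone at the ear.
#' F8 epoch variance (V^2); F9 the minimum variance over the thirty
#' non-overlapping 1-s windows; F10 the relative burst amplitude
#' `(P95 - median)/median` of the 1-s window RMS sequence (0 when the
#' median is 0).
#'
#' @param x EMG-band epoch, volts.
#' @param fs Sampling rate in Hz.
#' @return Named numeric vector `F8`..`F10`.
#' @export
emgProxyFeatures <- function(x, fs) {
  wlen <- as.integer(round(fs))
  nwin <- length(x) %/% wlen
  wins <- matrix(x[seq_len(nwin * wlen)], nrow = wlen)
  msq <- colMeans(wins^2)
  wvar <- (msq - colMeans(wins)^2) * wlen / (wlen - 1)
  wrms <- sqrt(msq)
  med <- median(wrms)
  c(F8 = var(x), F9 = min(wvar),
    F10 = if (med > 0) unname(quantile(wrms, 0.95) - med) / med else 0)
}

#' EOG-proxy features F11-F12 of one epoch
#'
#' Computed on the 0.5-30 Hz path. F11 is the mean Welch density over
#' 0.5-1.5 Hz (slow eye movements); F12 over 1.5-4 Hz (rapid eye
#' movements).
#'
#' @param x EOG-band epoch, volts.
#' @param fs Sampling rate in Hz.
#' @return Named numeric vector `F11`, `F12`.
#' @export
eogProxyFeatures <- function(x, fs) {
  psd <- welchPSD(x, fs)
  f <- psdFreqs(psd); p <- psdDensity(psd)
  selS <- f >= 0.5 & f <= 1.5
  selR <- f > 1.5 & f <= 4
  c(F11 = mean(p[selS]), F12 = mean(p[selR]))
}

#' Spectral features F13-F28 of one epoch
#'
#' Based on the Welch PSD of the 2-32 Hz path, with band powers integrated
#' over delta 2-4, theta 4-8, alpha 8-13 and beta 13-32 Hz. F13-F16 are the
#' relative alpha/beta/theta/delta powers; F17-F22 the ratios alpha/delta,
#' delta/beta, delta/theta, theta/alpha, theta/beta, alpha/beta; F23
#' `(theta+delta)/(alpha+beta)`; F24/F25 the 95% and 50% spectral edge
#' frequencies (linear interpolation within bins); F26 the mean absolute
#' SEF95 difference across consecutive 2-s sub-segments; F27 the peak-power
#' frequency; F28 the Shannon entropy of the bin-normalised density divided
#' by `log(nbins)` (in \[0, 1\]). Ratio denominators are guarded by
#' `1e-30` V^2.
#'
#' @param x EEG-band epoch, volts (needed for the sub-segment feature F26).
#' @param fs Sampling rate in Hz.
#' @param psd Optional precomputed [WelchPSD-class] of `x`.
#' @return Named numeric vector `F13`..`F28`.
#' @export
spectralFeatures <- function(x, fs, psd = NULL) {
  if (is.null(psd)) psd <- welchPSD(x, fs)
  f <- psdFreqs(psd); p <- psdDensity(psd)
  sel <- f >= EEG_BAND[1] & f <= EEG_BAND[2]
  f <- f[sel]; p <- p[sel]
  dF <- f[2] - f[1]
  bp <- function(lo, hi, closed) sum(p[f >= lo & (if (closed) f <= hi else f < hi)]) * dF
  delta <- bp(2, 4, FALSE); theta <- bp(4, 8, FALSE)
  alpha <- bp(8, 13, FALSE); beta <- bp(13, 32, TRUE)
  tot <- delta + theta + alpha + beta
  rel <- function(a) a / (tot + RATIO_EPS)
  rat <- function(a, b) a / (b + RATIO_EPS)

  sub <- .subSegmentSpectra(x, fs)
  sef95s <- apply(sub$density, 2, function(d) .spectralEdge(sub$freqs, d, 0.95))
  f26 <- if (length(sef95s) > 1L) mean(abs(diff(sef95s))) else 0

  q <- p / (sum(p) + RATIO_EPS)
  qpos <- q[q > 0]
  f28 <- if (length(qpos) > 1L && sum(p) > 0)
    -sum(qpos * log(qpos)) / log(length(q)) else 0

  c(F13 = rel(alpha), F14 = rel(beta), F15 = rel(theta), F16 = rel(delta),
    F17 = rat(alpha, delta), F18 = rat(delta, beta), F19 = rat(delta, theta),
    F20 = rat(theta, alpha), F21 = rat(theta, beta), F22 = rat(alpha, beta),
    F23 = rat(theta + delta, alpha + beta),
    F24 = .spectralEdge(f, p, 0.95), F25 = .spectralEdge(f, p, 0.50),
    F26 = f26,
    F27 = if (sum(p) > 0) f[which.max(p)] else 0,
    F28 = f28)
}

#' Sleep-event features F29-F33 of one epoch
#'
#' Spindle- and stationarity-oriented descriptors. The sigma envelope is
#' the sliding 0.25-s RMS of the 11-16 Hz band-passed epoch; the spindle
#' threshold is twice the epoch-median envelope. F29 is the fraction of
#' supra-threshold samples ("spindle probability"); F30 the standard
#' deviation of the per-2-s-sub-segment median power frequency (frequency
#' stationarity, Hz); F31 the minimum correlation between adjacent 2-s
#' sub-segment spectra; F32 the largest absolute Morlet (centre 13 Hz)
#' continuous-wavelet-transform value over the epoch; F33 the duration in
#' seconds of the longest contiguous supra-threshold envelope run.
#'
#' @param x EEG-band epoch, volts.
#' @param fs Sampling rate in Hz.
#' @param xSigma Optional 11-16 Hz band-passed version of the same epoch
#'   (computed from `x` if missing).
#' @return Named numeric vector `F29`..`F33`.
#' @export
sleepEventFeatures <- function(x, fs, xSigma = NULL) {
  if (is.null(xSigma)) xSigma <- bandpassFilter(x, fs, SIGMA_BAND[1], SIGMA_BAND[2])
  env <- .slidingRMS(xSigma, as.integer(round(0.25 * fs)))
  thr <- 2 * median(env)
  above <- env > thr & thr > 0
  f29 <- mean(above)
  runs <- rle(above)
  f33 <- if (any(runs$values)) max(runs$lengths[runs$values]) / fs else 0

  sub <- .subSegmentSpectra(x, fs)
  mpf <- apply(sub$density, 2, function(d) .spectralEdge(sub$freqs, d, 0.50))
  f30 <- if (length(mpf) > 1L) sd(mpf) else 0
  nseg <- ncol(sub$density)
  f31 <- if (nseg > 1L) {
    cors <- vapply(seq_len(nseg - 1L), function(k) {
      a <- sub$density[, k]; b <- sub$density[, k + 1L]
      if (sd(a) > 0 && sd(b) > 0) cor(a, b) else 0
    }, numeric(1))
    min(cors)
  } else 0
  f32 <- if (any(x != 0)) max(.morletCWTmod(x, fs, 13)) else 0
  c(F29 = f29, F30 = f30, F31 = f31, F32 = f32, F33 = f33)
}

# All 33 features of one epoch from its four filtered views.
.epochFeatures33 <- function(xe, xo, xm, xs, ga, gb, fs) {
  psd <- welchPSD(xe, fs)
  c(timeDomainFeatures(xe, ga, gb, fs),
    emgProxyFeatures(xm, fs),
    eogProxyFeatures(xo, fs),
    spectralFeatures(xe, fs, psd = psd),
    sleepEventFeatures(xe, fs, xSigma = xs))
}

# ---------------------------------------------------------------------------
# SleepFeatures container (SummarizedExperiment: 99 features x epochs)
# ---------------------------------------------------------------------------

#' @rdname extractFeatures
#' @export
setClass("SleepFeatures", contains = "SummarizedExperiment")

setValidity("SleepFeatures", function(object) {
  if (!identical(rownames(object), featureNames99()))
    return("rows must be the 99 canonical feature names in order")
  if (!all(is.finite(SummarizedExperiment::assay(object))))
    return("feature values must be finite")
  TRUE
})

#' @describeIn extractFeatures epochs-by-features numeric matrix (the
#'   classifier's input orientation).
#' @param x A `SleepFeatures` object.
#' @export
featureValues <- function(x) t(SummarizedExperiment::assay(x, "features"))

#' @describeIn extractFeatures per-epoch stage labels stored alongside the
#'   features (`NA` when no hypnogram was supplied).
#' @export
epochStages <- function(x) SummarizedExperiment::colData(x)$stage

#' @describeIn extractFeatures per-epoch subject ids.
#' @export
epochSubjects <- function(x) SummarizedExperiment::colData(x)$subject

#' Assemble a SleepFeatures object from a feature matrix
#'
#' @param values Numeric matrix, epochs x 99, columns in [featureNames99()]
#'   order.
#' @param subject Subject id (single value or per epoch).
#' @param stage Optional per-epoch stage labels.
#' @param meta Free-form metadata list.
#' @return A `SleepFeatures` object.
#' @export
SleepFeatures <- function(values, subject = "s1", stage = NULL, meta = list()) {
  n <- nrow(values)
  stopifnot(ncol(values) == 99L)
  colnames(values) <- featureNames99()
  cd <- S4Vectors::DataFrame(
    epoch = seq_len(n),
    subject = rep(as.character(subject), length.out = n),
    stage = if (is.null(stage)) rep(NA_character_, n)
            else rep(as.character(stage), length.out = n))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = t(values)), colData = cd,
    metadata = meta)
  colnames(se) <- sprintf("%s_e%04d", cd$subject, cd$epoch)
  new("SleepFeatures", se)
}

#' Combine SleepFeatures objects from several subjects
#'
#' @param ... `SleepFeatures` objects.
#' @return A single `SleepFeatures` with epochs concatenated in input order.
#' @export
bindFeatures <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && is.list(xs[[1]]) && !is(xs[[1]], "SleepFeatures"))
    xs <- xs[[1]]
  out <- do.call(BiocGenerics::cbind, xs)
  new("SleepFeatures", out)
}

#' Extract the 99-feature matrix from a derivation set
#'
#' Applies the 50 Hz notch and the four band-pass paths to each full-night
#' derivation, cuts aligned 30-s epochs, computes F1-F33 per derivation and
#' assembles the 99-column matrix in derivation-major order. A substituted
#' derivation's 33 columns duplicate its source derivation's columns
#' exactly.
#'
#' @param deriv A [DerivationSet-class] from [buildDerivations()].
#' @param epochs An `EpochIndex` from [segmentEpochs()]; computed from
#'   `deriv` if missing.
#' @param hyp Optional [SleepHypnogram-class] supplying per-epoch stage
#'   labels (truncated/aligned as in [segmentEpochs()]).
#' @param subject Subject id recorded in the output.
#' @return A `SleepFeatures` object (99 features x epochs
#'   SummarizedExperiment); see [featureValues()].
#' @aliases SleepFeatures-class
#' @export
extractFeatures <- function(deriv, epochs = NULL, hyp = NULL, subject = "s1") {
  fs <- deriv@fs
  if (is.null(epochs)) epochs <- segmentEpochs(deriv, hyp)
  n <- nEpochs(epochs)
  len <- epochs@epochLenSamples
  series <- derivationSeries(deriv)

  uniqueSources <- c("LR", "L", "R")[vapply(deriv@substituted[c("LR", "L", "R")],
                                            is.null, logical(1))]
  blocks <- list()
  for (d in uniqueSources) {
    xn <- notchFilter50(series[, d], fs)
    xe <- bandpassFilter(xn, fs, EEG_BAND[1], EEG_BAND[2])
    xo <- bandpassFilter(xn, fs, EOG_BAND[1], EOG_BAND[2])
    xm <- bandpassFilter(xn, fs, EMG_BAND[1], EMG_BAND[2])
    xs <- bandpassFilter(xn, fs, SIGMA_BAND[1], SIGMA_BAND[2])
    gm <- deriv@groupMeans[[d]]
    ga <- bandpassFilter(notchFilter50(gm$minuend, fs), fs, EEG_BAND[1], EEG_BAND[2])
    gb <- bandpassFilter(notchFilter50(gm$subtrahend, fs), fs, EEG_BAND[1], EEG_BAND[2])
    blk <- matrix(0, n, 33)
    for (k in seq_len(n)) {
      i <- epochs@start[k] + seq_len(len)
      blk[k, ] <- .epochFeatures33(xe[i], xo[i], xm[i], xs[i],
                                   ga[i], gb[i], fs)
    }
    blocks[[d]] <- blk
  }
  for (d in c("LR", "L", "R")) {
    if (is.null(blocks[[d]])) blocks[[d]] <- blocks[[deriv@substituted[[d]]]]
  }
  values <- cbind(blocks$LR, blocks$L, blocks$R)
  stage <- if (!is.null(hyp)) stageLabels(hyp)[seq_len(n)] else NULL
  SleepFeatures(values, subject = subject, stage = stage,
                meta = list(substituted = deriv@substituted,
                            usedElectrodes = deriv@usedElectrodes, fs = fs))
}

#' Write/read a features CSV
#'
#' The CSV carries columns `subject`, `epoch`, `stage`, then the 99 feature
#' columns in canonical order, in a deterministic column order.
#'
#' @param x A `SleepFeatures` object.
#' @param path File path.
#' @return `path` (write) or a `SleepFeatures` (read).
#' @export
writeFeaturesCSV <- function(x, path) {
  df <- data.frame(subject = epochSubjects(x),
                   epoch = SummarizedExperiment::colData(x)$epoch,
                   stage = epochStages(x),
                   featureValues(x), check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeaturesCSV
#' @export
readFeaturesCSV <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  vals <- as.matrix(df[, featureNames99(), drop = FALSE])
  st <- df$stage
  SleepFeatures(vals, subject = df$subject,
                stage = if (all(is.na(st))) NULL else st)
}
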