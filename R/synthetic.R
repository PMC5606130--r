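# Synthetic sleep ear-EEG. The generator emulates the signal phenomenology
# the staging pipeline relies on: stage-dependent band-limited spectra
# (alpha in wake, theta in N1/REM, spindles and K-complexes in N2, delta in
# N3, stage-dependent 32-80 Hz muscle tone), a 1/f background, microvolt
# amplitudes, per-channel sensor noise, optional high-noise "bad"
# electrodes, and a slow AR(1) drift of the band amplitudes that makes
# neighbouring epochs more alike than distant ones (the temporal
# autocorrelation behind the neighbor effect). Everything is determined by
# the seed.

.simBands <- list(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 13),
                  beta = c(13, 30), emg = c(32, 80),
                  sem = c(0.5, 1.5), rem = c(1.5, 4))

#' Default stage-dependent band amplitudes
#'
#' Root-mean-square source amplitudes in volts, per stage and per spectral
#' component: `delta` 1-4, `theta` 4-8, `alpha` 8-13, `beta` 13-30 and
#' `emg` 32-80 Hz, plus slow (`sem`, 0.5-1.5 Hz) and rapid (`rem`,
#' 1.5-4 Hz) eye-movement surrogates. The ordering encodes the
#' physiological contrasts the features exploit: delta N3 > N2 > W, alpha
#' strongest in wake, muscle tone W > REM (REM atonia), rapid eye
#' movements in REM.
#'
#' @return Named list (one entry per stage) of named amplitude vectors.
#' @export
defaultStageProfiles <- function() {
  uv <- 1e-6
  list(
    W   = c(delta = 2, theta = 2, alpha = 10, beta = 3, emg = 8,  sem = 3, rem = 1) * uv,
    REM = c(delta = 3, theta = 7, alpha = 2,  beta = 2, emg = 0.8, sem = 1, rem = 6) * uv,
    N1  = c(delta = 3, theta = 7, alpha = 3,  beta = 2, emg = 4,  sem = 4, rem = 2) * uv,
    N2  = c(delta = 6, theta = 6, alpha = 2,  beta = 2, emg = 2,  sem = 1, rem = 1) * uv,
    N3  = c(delta = 18, theta = 5, alpha = 1.5, beta = 1, emg = 1, sem = 1, rem = 0.5) * uv)
}

#' Default stage-transition matrix
#'
#' Row-stochastic first-order Markov transitions over W, REM, N1, N2, N3
#' with self-transition probability 0.9 and physiologically ordered
#' off-diagonal moves (wake enters sleep through N1, N3 is reached via N2,
#' ...). Real sleep has longer memory than one epoch; first-order dynamics
#' are enough to give hypnograms realistic bout structure and the temporal
#' autocorrelation the validation tests need.
#'
#' @return 5x5 row-stochastic matrix with stage dimnames.
#' @export
defaultTransitionMatrix <- function() {
  st <- sleepStages()
  tm <- matrix(0, 5, 5, dimnames = list(st, st))
  tm["W", ]   <- c(W = 0.90, REM = 0.01, N1 = 0.07, N2 = 0.02, N3 = 0.00)
  tm["REM", ] <- c(W = 0.04, REM = 0.90, N1 = 0.05, N2 = 0.01, N3 = 0.00)
  tm["N1", ]  <- c(W = 0.03, REM = 0.01, N1 = 0.90, N2 = 0.06, N3 = 0.00)
  tm["N2", ]  <- c(W = 0.01, REM = 0.01, N1 = 0.03, N2 = 0.90, N3 = 0.05)
  tm["N3", ]  <- c(W = 0.01, REM = 0.00, N1 = 0.00, N2 = 0.09, N3 = 0.90)
  tm
}

.defaultChannelGains <- function() {
  g <- c(rep(1.00, 2), rep(0.40, 4),   # left concha / canal
         rep(0.95, 2), rep(0.38, 4))   # right, slightly asymmetric
  names(g) <- earElectrodes()
  g
}

#' @rdname simSpec
#' @export
setClass("SimSpec",
  representation(
    nSubjects = "integer", epochsPerSubject = "integer", fs = "numeric",
    transitionMatrix = "matrix", stageProfiles = "list",
    eventRates = "numeric", badChannels = "data.frame",
    backgroundRMS = "numeric", sensorNoiseRMS = "numeric",
    channelGains = "numeric", driftRho = "numeric", driftSD = "numeric",
    seed = "integer"
  )
)

setValidity("SimSpec", function(object) {
  msg <- character()
  tm <- object@transitionMatrix
  if (!identical(dimnames(tm), list(sleepStages(), sleepStages())))
    msg <- c(msg, "transition matrix must be 5x5 with stage dimnames")
  else if (any(tm < 0) || any(abs(rowSums(tm) - 1) > 1e-9))
    msg <- c(msg, "transition rows must be nonnegative and sum to 1")
  if (object@fs <= 160)
    msg <- c(msg, "fs must exceed 160 Hz so the 32-80 Hz band fits")
  amps <- unlist(object@stageProfiles)
  if (any(amps < 0)) msg <- c(msg, "stage amplitudes must be nonnegative")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SimSpec", function(object) {
  cat(sprintf("SimSpec: %d subject(s) x %d epochs @ %g Hz, seed %d\n",
              object@nSubjects, object@epochsPerSubject, object@fs,
              object@seed))
  if (nrow(object@badChannels))
    cat("  bad channels:",
        paste(sprintf("s%d:%s", object@badChannels$subject,
                      object@badChannels$electrode), collapse = " "), "\n")
})

#' Specification of a synthetic sleep-EEG cohort
#'
#' Collects every knob of the generator: cohort size, epoch counts,
#' sampling rate, stage-transition dynamics, stage spectral profiles,
#' spindle/K-complex rates for N2, planted bad electrodes, amplitude
#' scales and the seed. Defaults: 5 uV-RMS 1/f background, 2 uV-RMS
#' independent sensor noise per electrode, 50 uV-RMS bad-channel noise
#' (about two orders of magnitude above the clean pairwise level, so the
#' rejection threshold bisects the two groups), and a slow log-AR(1)
#' band-amplitude drift (`rho` 0.95, stationary sd 0.3) shared by all
#' channels.
#'
#' @param nSubjects Number of subjects (default 9).
#' @param epochsPerSubject 30-s epochs per subject (default 120).
#' @param fs Sampling rate in Hz (default 200; must exceed 160).
#' @param transitionMatrix 5x5 row-stochastic stage-transition matrix
#'   (default [defaultTransitionMatrix()]).
#' @param stageProfiles Per-stage component amplitudes in volts RMS
#'   (default [defaultStageProfiles()]).
#' @param eventRates Named vector: `spindlesPerMin` and `kComplexesPerMin`
#'   in N2 (defaults 3 and 1).
#' @param badChannels `data.frame(subject, electrode, noiseRMS)` of
#'   planted bad electrodes; default none.
#' @param backgroundRMS,sensorNoiseRMS,channelGains Amplitude scales.
#' @param driftRho,driftSD Log-AR(1) drift of band amplitudes across
#'   epochs.
#' @param seed Master seed; every simulated quantity derives from it.
#' @return A `SimSpec` object.
#' @aliases SimSpec-class
#' @export
simSpec <- function(nSubjects = 9, epochsPerSubject = 120, fs = 200,
                    transitionMatrix = defaultTransitionMatrix(),
                    stageProfiles = defaultStageProfiles(),
                    eventRates = c(spindlesPerMin = 3, kComplexesPerMin = 1),
                    badChannels = NULL,
                    backgroundRMS = 5e-6, sensorNoiseRMS = 2e-6,
                    channelGains = .defaultChannelGains(),
                    driftRho = 0.95, driftSD = 0.3, seed = 1) {
  if (is.null(badChannels))
    badChannels <- data.frame(subject = integer(), electrode = character(),
                              noiseRMS = numeric())
  new("SimSpec", nSubjects = as.integer(nSubjects),
      epochsPerSubject = as.integer(epochsPerSubject), fs = fs,
      transitionMatrix = transitionMatrix, stageProfiles = stageProfiles,
      eventRates = eventRates, badChannels = badChannels,
      backgroundRMS = backgroundRMS, sensorNoiseRMS = sensorNoiseRMS,
      channelGains = channelGains, driftRho = driftRho, driftSD = driftSD,
      seed = as.integer(seed))
}

.subjectSeed <- function(spec, subject, stream)
  as.integer((as.numeric(spec@seed) * 10000 + subject * 100 + stream) %%
               2147483647)

#' Simulate a hypnogram
#'
#' First-order Markov chain over the five stages, starting in W, seeded
#' per subject from the spec's master seed.
#'
#' @param spec A [SimSpec-class].
#' @param subject Subject index (1-based).
#' @return A [SleepHypnogram-class].
#' @export
simulateHypnogram <- function(spec, subject = 1) {
  set.seed(.subjectSeed(spec, subject, 1L))
  st <- sleepStages()
  tm <- spec@transitionMatrix
  n <- spec@epochsPerSubject
  out <- character(n)
  cur <- "W"
  for (k in seq_len(n)) {
    out[k] <- cur
    cur <- sample(st, 1L, prob = tm[cur, ])
  }
  SleepHypnogram(out)
}

# Hermitian mirror of a one-sided spectrum (length n%/%2 + 1) to length n.
.mirrorSpectrum <- function(Z, n) {
  half <- n %/% 2L
  tailIdx <- if (n %% 2L == 0L) seq(2L, half) else seq(2L, half + 1L)
  c(Z, Conj(Z[rev(tailIdx)]))
}

# Band-limited Gaussian noise via Fourier synthesis: random phases on the
# bins inside [lo, hi], scaled to unit RMS (zero if the band holds no bin).
.bandNoise <- function(n, fs, lo, hi) {
  freqs <- (0:(n %/% 2L)) * fs / n
  sel <- which(freqs >= lo & freqs <= hi & freqs > 0)
  if (!length(sel)) return(numeric(n))
  Z <- complex(length.out = n %/% 2L + 1L)
  Z[sel] <- complex(real = rnorm(length(sel)), imaginary = rnorm(length(sel)))
  x <- Re(fft(.mirrorSpectrum(Z, n), inverse = TRUE)) / n
  r <- sqrt(mean(x^2))
  if (r > 0) x / r else x
}

# 1/f-amplitude background over 0.3-48 Hz, unit RMS.
.pinkNoise <- function(n, fs) {
  freqs <- (0:(n %/% 2L)) * fs / n
  sel <- which(freqs >= 0.3 & freqs <= 48 & freqs > 0)
  Z <- complex(length.out = n %/% 2L + 1L)
  Z[sel] <- complex(real = rnorm(length(sel)), imaginary = rnorm(length(sel))) /
    sqrt(freqs[sel])
  x <- Re(fft(.mirrorSpectrum(Z, n), inverse = TRUE)) / n
  x / sqrt(mean(x^2))
}

.hannWin <- function(n) 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))

#' Simulate a multichannel ear-EEG recording
#'
#' Renders the hypnogram into a 12-channel recording named per
#' [earElectrodes()]. Each epoch is a 1/f background plus stage-profile
#' band-limited components, shared across channels through per-channel
#' gains (concha and canal electrodes see different gains, so the
#' within-ear derivations retain the signal while pairwise differences of
#' same-group electrodes cancel it), plus independent sensor noise. N2
#' epochs receive Poisson-placed 0.5-2 s spindle bursts (11-16 Hz) and
#' isolated biphasic K-complexes; designated bad channels receive added
#' broadband noise at the configured RMS. Band amplitudes drift slowly
#' across epochs (log-AR(1)), so neighbouring epochs are more alike than
#' distant ones.
#'
#' @param hyp A [SleepHypnogram-class] (from [simulateHypnogram()]).
#' @param spec A [SimSpec-class].
#' @param subject Subject index, used for seeding and bad-channel lookup.
#' @return An [EarRecording-class]; `meta` holds the ground truth (stages,
#'   bad channels, per-epoch spindle and K-complex counts and times).
#' @export
simulateRecording <- function(hyp, spec, subject = 1) {
  set.seed(.subjectSeed(spec, subject, 2L))
  fs <- spec@fs
  len <- as.integer(round(30 * fs))
  stages <- stageLabels(hyp)
  n <- length(stages)
  chans <- earElectrodes()
  gains <- spec@channelGains[chans]
  bands <- names(.simBands)

  # log-AR(1) amplitude drift per band, shared by all channels
  drift <- matrix(0, length(bands), n, dimnames = list(bands, NULL))
  for (b in seq_along(bands)) {
    l <- numeric(n)
    l[1] <- rnorm(1, 0, spec@driftSD)
    if (n > 1L) for (k in 2:n)
      l[k] <- spec@driftRho * l[k - 1L] +
        sqrt(1 - spec@driftRho^2) * spec@driftSD * rnorm(1)
    drift[b, ] <- exp(l)
  }

  bad <- spec@badChannels[spec@badChannels$subject == subject, , drop = FALSE]
  spindleRate <- unname(spec@eventRates["spindlesPerMin"]) / 2   # per epoch
  kcRate <- unname(spec@eventRates["kComplexesPerMin"]) / 2
  spindleCount <- integer(n); kcCount <- integer(n)
  spindleTimes <- vector("list", n)

  x <- matrix(0, n * len, length(chans), dimnames = list(NULL, chans))
  tEpoch <- seq_len(len) / fs
  for (k in seq_len(n)) {
    amp <- spec@stageProfiles[[stages[k]]]
    shared <- .pinkNoise(len, fs) * spec@backgroundRMS
    for (b in names(amp)) {
      if (amp[[b]] <= 0) next
      e <- .simBands[[b]]
      shared <- shared + .bandNoise(len, fs, e[1], e[2]) * amp[[b]] * drift[b, k]
    }
    if (stages[k] == "N2") {
      ns <- stats::rpois(1, spindleRate)
      spindleCount[k] <- ns
      if (ns > 0) {
        starts <- sort(runif(ns, 0, 28))
        spindleTimes[[k]] <- starts
        for (s0 in starts) {
          dur <- runif(1, 0.5, 2)
          i <- which(tEpoch >= s0 & tEpoch < s0 + dur)
          f <- runif(1, 11, 16)
          shared[i] <- shared[i] + 20e-6 *
            sin(2 * pi * f * tEpoch[i] + runif(1, 0, 2 * pi)) *
            .hannWin(length(i))
        }
      }
      nk <- stats::rpois(1, kcRate)
      kcCount[k] <- nk
      if (nk > 0) for (s0 in runif(nk, 0, 29)) {
        i <- which(tEpoch >= s0 & tEpoch < s0 + 1)
        shared[i] <- shared[i] - 100e-6 *
          sin(2 * pi * (tEpoch[i] - s0)) * .hannWin(length(i))
      }
    }
    rows <- ((k - 1L) * len + 1L):(k * len)
    x[rows, ] <- outer(shared, gains) +
      matrix(rnorm(len * length(chans), 0, spec@sensorNoiseRMS), len)
    if (nrow(bad)) for (j in seq_len(nrow(bad))) {
      ch <- bad$electrode[j]
      x[rows, ch] <- x[rows, ch] + rnorm(len, 0, bad$noiseRMS[j])
    }
  }
  EarRecording(x, fs = fs,
               meta = list(subject = subject, stages = stages,
                           badChannels = bad$electrode,
                           spindleCount = spindleCount,
                           spindleTimes = spindleTimes,
                           kComplexCount = kcCount,
                           seed = .subjectSeed(spec, subject, 2L)))
}

#' Count sigma-band bursts in a signal
#'
#' Simple spindle-burst detector used to check the simulator against its
#' Poisson ground truth: the sliding 0.25-s RMS envelope of the 11-16 Hz
#' band-passed signal is thresholded at `thresholdFactor` times its
#' median, and supra-threshold runs of at least `minDurS` seconds
#' (merging gaps shorter than `gapS`) are counted.
#'
#' @param x Numeric signal in volts.
#' @param fs Sampling rate in Hz.
#' @param thresholdFactor Envelope threshold as a multiple of the median.
#' @param minDurS Minimum burst duration in seconds.
#' @param gapS Sub-threshold gaps shorter than this are bridged.
#' @return Integer burst count.
#' @export
countSigmaBursts <- function(x, fs, thresholdFactor = 2, minDurS = 0.3,
                             gapS = 0.1) {
  xs <- bandpassFilter(x, fs, SIGMA_BAND[1], SIGMA_BAND[2])
  env <- .slidingRMS(xs, as.integer(round(0.25 * fs)))
  thr <- thresholdFactor * median(env)
  above <- env > thr & thr > 0
  r <- rle(above)
  # bridge short gaps
  short <- !r$values & r$lengths < gapS * fs &
    seq_along(r$values) > 1L & seq_along(r$values) < length(r$values)
  r$values[short] <- TRUE
  above <- inverse.rle(r)
  r <- rle(above)
  sum(r$values & r$lengths >= minDurS * fs)
}

#' Write a synthetic cohort to disk
#'
#' Generates the full cohort of the spec and writes one EDF and one
#' hypnogram CSV per subject plus a JSON manifest of the ground truth
#' (per-subject files, planted bad channels, spindle/K-complex counts).
#' Fully determined by the spec's seed: regenerating yields byte-identical
#' CSVs and sample-identical EDFs.
#'
#' @param spec A [SimSpec-class].
#' @param dir Output directory (created if needed).
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
makeFixture <- function(spec, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  subjects <- vector("list", spec@nSubjects)
  for (s in seq_len(spec@nSubjects)) {
    hyp <- simulateHypnogram(spec, s)
    rec <- simulateRecording(hyp, spec, s)
    edf <- file.path(dir, sprintf("subject%02d.edf", s))
    csv <- file.path(dir, sprintf("subject%02d_hypnogram.csv", s))
    writeEDF(rec, edf)
    writeHypnogram(hyp, csv)
    subjects[[s]] <- list(
      id = s, edf = basename(edf), hypnogram = basename(csv),
      badChannels = as.character(rec@meta$badChannels),
      spindleCount = rec@meta$spindleCount,
      kComplexCount = rec@meta$kComplexCount)
  }
  manifest <- list(seed = spec@seed, fs = spec@fs,
                   nSubjects = spec@nSubjects,
                   epochsPerSubject = spec@epochsPerSubject,
                   subjects = subjects)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
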