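# Shared fixture builders. Everything is generated in code; no binary data.

FS <- 200
EPOCH_N <- 30L * FS

# time axis for one 30-s epoch
epochTime <- function(fs = FS, durS = 30) seq_len(durS * fs) / fs

# unit-amplitude sinusoid epoch
sineEpoch <- function(freq, fs = FS, durS = 30, amp = 1)
  amp * sin(2 * pi * freq * epochTime(fs, durS))

# a 12-channel recording of independent white noise at `rms` volts
whiteNoiseRecording <- function(rms = 5e-6, nEpochs = 2, fs = FS, seed = 1) {
  set.seed(seed)
  n <- nEpochs * 30 * fs
  x <- matrix(rnorm(n * 12, sd = rms), n, 12,
              dimnames = list(NULL, earElectrodes()))
  EarRecording(x, fs = fs)
}

# tiny simulated subject with optional planted bad electrodes
tinySpec <- function(seed = 1, nEpochs = 6, bad = NULL, nSubjects = 1) {
  badDF <- if (is.null(bad)) NULL else
    data.frame(subject = 1L, electrode = bad, noiseRMS = 50e-6)
  simSpec(nSubjects = nSubjects, epochsPerSubject = nEpochs,
          badChannels = badDF, seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# two well-separated Gaussian classes in feature space
.twoClassData <- function(n = 60, p = 8, sep = 6, seed = 41) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  y <- rep(c("W", "N2"), each = n / 2)
  X[y == "N2", 1] <- X[y == "N2", 1] + sep
  list(X = X, y = y)
}

# brute-force Cohen's kappa, independent of the package implementation
bruteKappa <- function(m) {
  tot <- sum(m)
  po <- sum(diag(m)) / tot
  pe <- sum(rowSums(m) * colSums(m)) / tot^2
  if (abs(1 - pe) < 1e-15) return(0)
  (po - pe) / (1 - pe)
}

# minimal hand-rolled EDF with per-channel samples-per-record, for testing
# the reader against files the package writer refuses to produce
writeRawEDF <- function(path, labels, sprs, recDur = 1, nrec = 1,
                        physMin = -200, physMax = 200) {
  ns <- length(labels)
  pad <- earsleep:::.edfPad
  num <- earsleep:::.edfNum
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(pad("0", 8), pad("X", 80), pad("X", 80),
                   pad("01.01.00", 8), pad("00.00.00", 8),
                   num(256 + 256 * ns, 8), pad("", 44), num(nrec, 8),
                   num(recDur, 8), num(ns, 4)), con, eos = NULL)
  for (f in list(vapply(labels, pad, "", width = 16),
                 rep(pad("", 80), ns), rep(pad("uV", 8), ns),
                 rep(num(physMin, 8), ns), rep(num(physMax, 8), ns),
                 rep(num(-32768, 8), ns), rep(num(32767, 8), ns),
                 rep(pad("", 80), ns), vapply(sprs, num, "", width = 8),
                 rep(pad("", 32), ns)))
    writeChar(paste(f, collapse = ""), con, eos = NULL)
  for (r in seq_len(nrec)) for (i in seq_len(ns))
    writeBin(rep(32767L, sprs[i]), con, size = 2L, endian = "little")
  invisible(path)
}

flatPSD <- function(value = 1e-12) {
  new("WelchPSD", freqs = seq(0, 100, by = 0.5),
      density = rep(value, 201),
      settings = list(segmentS = 2, overlapS = 1, window = "hann", fs = 200))
}

singleBinPSD <- function(freq = 10, value = 1e-10) {
  d <- numeric(201)
  d[freq / 0.5 + 1] <- value
  new("WelchPSD", freqs = seq(0, 100, by = 0.5), density = d,
      settings = list(segmentS = 2, overlapS = 1, window = "hann", fs = 200))
}
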