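# Recording and hypnogram I/O. EDF (European Data Format) is the de-facto
# container for polysomnography; the reader/writer below implements the
# standard 16-bit EDF layout (fixed-width ASCII header, int16 records,
# physical/digital linear scaling).

.edfPad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

.edfNum <- function(x, width) {
  s <- formatC(x, format = "fg", width = 1)
  if (nchar(s) > width) s <- substr(formatC(x, format = "g"), 1, width)
  .edfPad(s, width)
}

# densest decimal representation of `x` that fits the 8-char header field;
# returns the string and the exactly representable value it parses back to
.edfPhys <- function(x, width = 8) {
  for (d in 7:1) {
    s <- formatC(x, format = "g", digits = d)
    if (nchar(s) <= width) break
  }
  list(text = .edfPad(s, width), value = as.numeric(s))
}

#' Write a recording to an EDF file
#'
#' Writes 16-bit EDF with one-second data records. Physical units are
#' microvolts with a symmetric physical range per channel chosen to cover
#' the signal; digital range is -32768..32767. The sampling rate must be a
#' whole number of samples per second.
#'
#' @param rec An [EarRecording-class].
#' @param path Output file path.
#' @param physMaxUV Optional physical range bound in microvolts (single
#'   number applied to all channels). Defaults to the per-channel maximum
#'   absolute amplitude (at least 1 uV).
#' @return `path`, invisibly.
#' @seealso [readEDF()]
#' @export
writeEDF <- function(rec, path, physMaxUV = NULL) {
  x <- signalMatrix(rec)
  fs <- samplingRate(rec)
  if (abs(fs - round(fs)) > 1e-9)
    stop("EDF writer requires an integer number of samples per second")
  fs <- as.integer(round(fs))
  ns <- ncol(x)
  nrec <- nrow(x) %/% fs
  if (nrec < 1L) stop("recording shorter than one 1-s data record")
  if (nrec * fs < nrow(x))
    warning("trailing ", nrow(x) - nrec * fs, " samples do not fill a record and are dropped")
  uv <- x[seq_len(nrec * fs), , drop = FALSE] * 1e6
  pmaxs <- if (is.null(physMaxUV)) pmax(apply(abs(uv), 2, max), 1) else
    rep(physMaxUV, length.out = ns)
  phys <- lapply(pmaxs, .edfPhys)
  pmaxs <- vapply(phys, `[[`, numeric(1), "value")   # scale with the header values

  con <- file(path, "wb")
  on.exit(close(con))
  hdrBytes <- 256L + 256L * ns
  writeChar(paste0(
    .edfPad("0", 8), .edfPad("X X X X", 80), .edfPad("Startdate X X X X", 80),
    .edfPad("01.01.00", 8), .edfPad("00.00.00", 8), .edfNum(hdrBytes, 8),
    .edfPad("", 44), .edfNum(nrec, 8), .edfNum(1, 8), .edfNum(ns, 4)),
    con, eos = NULL)
  lab <- channelLabels(rec)
  fields <- list(
    vapply(lab, .edfPad, "", width = 16),
    rep(.edfPad("", 80), ns),
    rep(.edfPad("uV", 8), ns),
    vapply(phys, function(p) .edfPad(paste0("-", trimws(p$text)), 8), ""),
    vapply(phys, `[[`, "", "text"),
    rep(.edfNum(-32768, 8), ns),
    rep(.edfNum(32767, 8), ns),
    rep(.edfPad("", 80), ns),
    rep(.edfNum(fs, 8), ns),
    rep(.edfPad("", 32), ns))
  for (f in fields) writeChar(paste(f, collapse = ""), con, eos = NULL)

  # same affine convention the reader applies: -32768..32767 <-> -pmax..pmax
  dig <- round(sweep(sweep(uv, 2, pmaxs, `+`), 2, 2 * pmaxs / 65535, `/`)) - 32768
  dig <- pmin(pmax(dig, -32768), 32767)
  # record-major layout: all samples of channel 1 in record r, then channel 2, ...
  for (r in seq_len(nrec)) {
    rows <- ((r - 1L) * fs + 1L):(r * fs)
    writeBin(as.integer(dig[rows, ]), con, size = 2L, endian = "little")
  }
  invisible(path)
}

.edfDimToVolts <- function(dim) {
  switch(tolower(trimws(dim)), "uv" = 1e-6, "µv" = 1e-6,
         "mv" = 1e-3, "v" = 1, NA_real_)
}

#' Read an EDF recording
#'
#' Parses the standard EDF header and 16-bit data records and converts
#' samples to volts via the physical/digital linear scaling recorded in the
#' header. All selected channels must share one sampling rate.
#'
#' @param path Path to an EDF file.
#' @param channels Optional character vector of channel labels to read;
#'   default all.
#' @return An [EarRecording-class] whose `meta` holds the header fields.
#' @examples
#' \dontrun{rec <- readEDF("night1.edf", channels = earElectrodes())}
#' @export
readEDF <- function(path, channels = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  version <- trimws(rd(8))
  patient <- trimws(rd(80)); recid <- trimws(rd(80))
  startdate <- trimws(rd(8)); starttime <- trimws(rd(8))
  hdrBytes <- suppressWarnings(as.integer(trimws(rd(8))))
  reserved <- rd(44)
  nrec <- suppressWarnings(as.integer(trimws(rd(8))))
  recDur <- suppressWarnings(as.numeric(trimws(rd(8))))
  ns <- suppressWarnings(as.integer(trimws(rd(4))))
  if (is.na(ns) || ns < 1L || is.na(nrec) || is.na(recDur) || recDur <= 0)
    stop("corrupt EDF header in ", path)
  rdn <- function(w) vapply(seq_len(ns), function(i) trimws(rd(w)), "")
  lab <- rdn(16); transducer <- rdn(80); dim <- rdn(8)
  physMin <- as.numeric(rdn(8)); physMax <- as.numeric(rdn(8))
  digMin <- as.numeric(rdn(8)); digMax <- as.numeric(rdn(8))
  prefilt <- rdn(80); spr <- as.integer(rdn(8)); rdn(32)
  if (anyNA(physMin) || anyNA(physMax) || anyNA(digMin) || anyNA(digMax) ||
      anyNA(spr))
    stop("corrupt EDF signal headers in ", path)

  sel <- if (is.null(channels)) seq_len(ns) else match(channels, lab)
  if (anyNA(sel))
    stop("channel(s) not in file: ",
         paste(channels[is.na(sel)], collapse = ", "))
  fsAll <- spr / recDur
  if (length(unique(fsAll[sel])) != 1L)
    stop("selected channels have mismatched sampling rates: ",
         paste(sprintf("%s=%g Hz", lab[sel], fsAll[sel]), collapse = ", "))
  fs <- fsAll[sel[1]]

  raw <- readBin(con, "integer", n = nrec * sum(spr), size = 2L,
                 signed = TRUE, endian = "little")
  if (length(raw) < nrec * sum(spr)) stop("truncated EDF data in ", path)
  offs <- cumsum(c(0L, spr))
  totalPerRec <- sum(spr)
  out <- matrix(0, nrow = nrec * spr[sel[1]], ncol = length(sel),
                dimnames = list(NULL, lab[sel]))
  for (k in seq_along(sel)) {
    i <- sel[k]
    idx <- as.vector(outer(seq_len(spr[i]) + offs[i],
                           (seq_len(nrec) - 1L) * totalPerRec, `+`))
    dig <- raw[idx]
    phys <- (dig - digMin[i]) * (physMax[i] - physMin[i]) /
      (digMax[i] - digMin[i]) + physMin[i]
    tov <- .edfDimToVolts(dim[i])
    out[, k] <- if (is.na(tov)) phys else phys * tov
  }
  EarRecording(out, fs = fs,
               meta = list(version = version, patient = patient,
                           recording = recid, startdate = startdate,
                           starttime = starttime, reserved = trimws(reserved),
                           dimensions = dim[sel], prefiltering = prefilt[sel],
                           transducer = transducer[sel], path = path))
}

.canonStage <- function(s) {
  s <- toupper(trimws(s))
  map <- c(W = "W", WAKE = "W", REM = "REM",
           N1 = "N1", N2 = "N2", N3 = "N3",
           NREM1 = "N1", NREM2 = "N2", NREM3 = "N3")
  unname(map[s])
}

#' Read a hypnogram file
#'
#' Accepts either one stage label per line or CSV with columns
#' `epoch,stage` (header optional). Labels are matched case-insensitively
#' against `W`, `REM`, `N1`, `N2`, `N3`, with `NREM1`/`NREM2`/`NREM3`
#' accepted as synonyms and canonicalised.
#'
#' @param path Path to the hypnogram text file.
#' @return A [SleepHypnogram-class].
#' @seealso [writeHypnogram()]
#' @export
readHypnogram <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  if (!any(keep)) stop("empty hypnogram file: ", path)
  lineNo <- which(keep)
  lines <- lines[keep]
  hasComma <- grepl(",", lines[1], fixed = TRUE)
  if (hasComma) {
    parts <- strsplit(lines, ",", fixed = TRUE)
    raw <- vapply(parts, function(p) trimws(p[length(p)]), "")
    if (tolower(raw[1]) == "stage") { raw <- raw[-1]; lineNo <- lineNo[-1] }
  } else {
    raw <- trimws(lines)
  }
  stages <- .canonStage(raw)
  if (anyNA(stages)) {
    i <- which(is.na(stages))[1]
    stop("unknown stage label '", raw[i], "' at line ", lineNo[i],
         " of ", path)
  }
  SleepHypnogram(stages)
}

#' Write a hypnogram as CSV
#'
#' Canonical output dialect: header `epoch,stage`, 1-based epoch numbers.
#'
#' @param hyp A [SleepHypnogram-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeHypnogram <- function(hyp, path) {
  st <- stageLabels(hyp)
  writeLines(c("epoch,stage",
               paste(seq_along(st), st, sep = ",")), path)
  invisible(path)
}

#' Segment a recording into aligned 30-s epochs
#'
#' Cuts the recording into non-overlapping, contiguous 30-second epochs
#' (0-based sample indexing, half-open intervals). Trailing samples shorter
#' than one epoch are discarded. When a hypnogram is supplied and its length
#' disagrees with the number of signal epochs, both are truncated to the
#' shorter with a warning — real PSG exports routinely disagree by an epoch.
#'
#' @param rec An [EarRecording-class] (or a [DerivationSet-class]).
#' @param hyp Optional [SleepHypnogram-class] to align with.
#' @param epochLenS Epoch length in seconds (default 30).
#' @return An `EpochIndex` object; see [nEpochs()].
#' @aliases EpochIndex-class
#' @export
segmentEpochs <- function(rec, hyp = NULL, epochLenS = 30) {
  nsamp <- if (is(rec, "DerivationSet")) nrow(derivationSeries(rec)) else nSamples(rec)
  fs <- if (is(rec, "DerivationSet")) rec@fs else samplingRate(rec)
  len <- as.integer(round(epochLenS * fs))
  n <- nsamp %/% len
  if (n < 1L) stop("recording shorter than one ", epochLenS, "-s epoch")
  if (!is.null(hyp) && nEpochsScored(hyp) != n) {
    m <- min(n, nEpochsScored(hyp))
    warning("signal provides ", n, " epochs but hypnogram has ",
            nEpochsScored(hyp), "; truncating to ", m)
    n <- m
  }
  new("EpochIndex", nEpochs = as.integer(n), epochLenSamples = len,
      start = as.integer((seq_len(n) - 1L) * len))
}
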