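#' @import methods
#' @importFrom stats median var sd cor quantile fft rnorm runif approx
#' @importFrom utils read.csv write.csv head tail
NULL

#' Sleep stage vocabulary
#'
#' The five AASM stage labels used throughout the package, in the fixed
#' order used for deterministic tie-breaking: W, REM, N1, N2, N3.
#'
#' @return Character vector of the five stage labels.
#' @examples
#' sleepStages()
#' @export
sleepStages <- function() c("W", "REM", "N1", "N2", "N3")

#' Ear-EEG electrode naming convention
#'
#' The twelve in-ear electrode labels: six per ear, with `A`/`B` sited in
#' the concha and `E`/`I`/`G`/`K` in the ear canal. The prefix `EL`/`ER`
#' marks the left/right ear.
#'
#' @param ear `"both"` (default), `"left"` or `"right"`.
#' @return Character vector of electrode labels.
#' @examples
#' earElectrodes("left")
#' @export
earElectrodes <- function(ear = c("both", "left", "right")) {
  ear <- match.arg(ear)
  left <- paste0("EL", c("A", "B", "E", "I", "G", "K"))
  right <- paste0("ER", c("A", "B", "E", "I", "G", "K"))
  switch(ear, both = c(left, right), left = left, right = right)
}

.conchaOf <- function(ear) paste0(if (ear == "left") "EL" else "ER", c("A", "B"))
.canalOf <- function(ear) paste0(if (ear == "left") "EL" else "ER", c("E", "I", "G", "K"))

# ---------------------------------------------------------------------------
# EarRecording: multichannel time series in volts
# ---------------------------------------------------------------------------

#' @rdname EarRecording
#' @export
setClass("EarRecording",
  representation(
    signals = "matrix",   # samples x channels, volts
    fs = "numeric",       # Hz, shared by all channels
    meta = "list"
  )
)

setValidity("EarRecording", function(object) {
  msg <- character()
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "'fs' must be a single positive number")
  lab <- colnames(object@signals)
  if (is.null(lab) || anyDuplicated(lab))
    msg <- c(msg, "channel labels must be present and unique")
  if (length(object@signals) && !all(is.finite(object@signals)))
    msg <- c(msg, "signal values must be finite")
  if (length(msg)) msg else TRUE
})

#' Multichannel ear-EEG recording
#'
#' Container for a multichannel EEG time series in volts with a single
#' sampling rate. Channel labels follow the twelve-name ear-EEG convention
#' where applicable (see [earElectrodes()]).
#'
#' @param signals Numeric matrix, samples by channels, in volts. Column
#'   names are the channel labels.
#' @param fs Sampling rate in Hz.
#' @param meta Free-form provenance list (file header fields, simulation
#'   ground truth, ...).
#' @return An `EarRecording` object.
#' @examples
#' x <- matrix(rnorm(400 * 2) * 1e-6, ncol = 2,
#'             dimnames = list(NULL, c("ELA", "ELB")))
#' rec <- EarRecording(x, fs = 200)
#' nSamples(rec)
#' @aliases EarRecording-class
#' @export
EarRecording <- function(signals, fs, meta = list()) {
  new("EarRecording", signals = signals, fs = fs, meta = meta)
}

#' @describeIn EarRecording number of samples per channel.
#' @param x,object An `EarRecording`.
#' @export
nSamples <- function(x) nrow(x@signals)

#' @describeIn EarRecording sampling rate in Hz.
#' @export
samplingRate <- function(x) x@fs

#' @describeIn EarRecording ordered channel labels.
#' @export
channelLabels <- function(x) colnames(x@signals)

#' @describeIn EarRecording samples-by-channels signal matrix in volts.
#' @export
signalMatrix <- function(x) x@signals

#' @describeIn EarRecording recording duration in seconds.
#' @export
durationSeconds <- function(x) nrow(x@signals) / x@fs

setMethod("show", "EarRecording", function(object) {
  cat(sprintf("EarRecording: %d channel(s), %d samples @ %g Hz (%.1f s)\n",
              ncol(object@signals), nrow(object@signals), object@fs,
              durationSeconds(object)))
  cat("  channels:", paste(channelLabels(object), collapse = " "), "\n")
})

# ---------------------------------------------------------------------------
# SleepHypnogram: per-epoch stage labels
# ---------------------------------------------------------------------------

#' @rdname SleepHypnogram
#' @export
setClass("SleepHypnogram",
  representation(stages = "character", epochLenS = "numeric")
)

setValidity("SleepHypnogram", function(object) {
  bad <- setdiff(unique(object@stages), sleepStages())
  if (length(bad))
    return(paste("unknown stage label(s):", paste(bad, collapse = ", ")))
  if (length(object@epochLenS) != 1L || object@epochLenS <= 0)
    return("'epochLenS' must be a single positive number")
  TRUE
})

#' Hypnogram: one sleep-stage label per scoring epoch
#'
#' Ordered sequence of AASM stage labels (`W`, `REM`, `N1`, `N2`, `N3`),
#' one per 30-second epoch.
#'
#' @param stages Character vector of stage labels.
#' @param epochLenS Epoch length in seconds (30 by convention).
#' @return A `SleepHypnogram` object.
#' @examples
#' hyp <- SleepHypnogram(c("W", "N1", "N2"))
#' stageLabels(hyp)
#' @aliases SleepHypnogram-class
#' @export
SleepHypnogram <- function(stages, epochLenS = 30) {
  new("SleepHypnogram", stages = as.character(stages), epochLenS = epochLenS)
}

#' @describeIn SleepHypnogram the stage label vector.
#' @param x,object A `SleepHypnogram`.
#' @export
stageLabels <- function(x) x@stages

#' @describeIn SleepHypnogram number of scored epochs.
#' @export
nEpochsScored <- function(x) length(x@stages)

setMethod("show", "SleepHypnogram", function(object) {
  tab <- table(factor(object@stages, levels = sleepStages()))
  cat(sprintf("SleepHypnogram: %d epochs of %g s\n",
              length(object@stages), object@epochLenS))
  print(tab)
})

setMethod("length", "SleepHypnogram", function(x) length(x@stages))

# ---------------------------------------------------------------------------
# EpochIndex: aligned 30-s epoch grid over a recording
# ---------------------------------------------------------------------------

#' @rdname segmentEpochs
#' @export
setClass("EpochIndex",
  representation(
    nEpochs = "integer",
    epochLenSamples = "integer",
    start = "integer"        # 0-based start sample of each epoch
  )
)

setValidity("EpochIndex", function(object) {
  if (length(object@start) != object@nEpochs)
    return("'start' must have one entry per epoch")
  if (object@nEpochs > 1L &&
      any(diff(object@start) != object@epochLenSamples))
    return("epochs must be contiguous and non-overlapping")
  TRUE
})

#' @describeIn segmentEpochs number of epochs in an `EpochIndex`.
#' @export
nEpochs <- function(x) x@nEpochs

setMethod("show", "EpochIndex", function(object) {
  cat(sprintf("EpochIndex: %d epochs x %d samples (0-based, half-open)\n",
              object@nEpochs, object@epochLenSamples))
})

# ---------------------------------------------------------------------------
# ChannelQuality: pairwise-power based electrode rejection
# ---------------------------------------------------------------------------

#' @rdname rejectChannels
#' @export
setClass("ChannelQuality",
  representation(
    pairwisePower = "matrix",   # symmetric, V^2/Hz; NA for cross-ear pairs
    medianPower = "numeric",    # named, V^2/Hz
    rejected = "character",
    unusable = "character",     # electrodes in ears with < 2 electrodes
    threshold = "numeric",
    band = "numeric"
  )
)

setValidity("ChannelQuality", function(object) {
  p <- object@pairwisePower
  if (nrow(p) != ncol(p) || !identical(rownames(p), colnames(p)))
    return("'pairwisePower' must be square with matching dimnames")
  ok <- !is.na(p)
  if (any(p[ok] < 0)) return("pairwise powers must be nonnegative")
  if (!isTRUE(all.equal(p[ok], t(p)[t(ok)]))) return("'pairwisePower' must be symmetric")
  TRUE
})

#' @describeIn rejectChannels electrodes rejected by the median rule.
#' @param x A `ChannelQuality`.
#' @export
rejectedChannels <- function(x) x@rejected

#' @describeIn rejectChannels named vector of per-electrode median pairwise
#'   band-power densities (V^2/Hz).
#' @export
medianPower <- function(x) x@medianPower

#' @describeIn rejectChannels electrodes surviving rejection (and not marked
#'   unusable).
#' @export
keptChannels <- function(x)
  setdiff(names(x@medianPower)[!is.na(x@medianPower)],
          c(x@rejected, x@unusable))

setMethod("show", "ChannelQuality", function(object) {
  cat(sprintf("ChannelQuality: threshold %.3g V^2/Hz over %g-%g Hz\n",
              object@threshold, object@band[1], object@band[2]))
  m <- object@medianPower
  verdict <- ifelse(names(m) %in% object@rejected, "reject",
                    ifelse(names(m) %in% object@unusable, "unusable", "keep"))
  print(data.frame(electrode = names(m), median_power = signif(m, 3),
                   verdict = verdict, row.names = NULL))
})

# ---------------------------------------------------------------------------
# DerivationSet: the three analysis derivations L-R, L, R
# ---------------------------------------------------------------------------

#' @rdname buildDerivations
#' @export
setClass("DerivationSet",
  representation(
    series = "matrix",          # samples x 3 (LR, L, R), volts
    groupMeans = "list",        # per derivation: list(minuend=, subtrahend=)
    usedElectrodes = "list",    # per derivation: list(minuend=, subtrahend=)
    substituted = "list",       # per derivation: NULL or source name
    fs = "numeric"
  )
)

setValidity("DerivationSet", function(object) {
  if (!identical(colnames(object@series), c("LR", "L", "R")))
    return("'series' columns must be LR, L, R")
  TRUE
})

#' @describeIn buildDerivations samples-by-3 matrix of the LR, L and R
#'   derivation signals in volts.
#' @param x A `DerivationSet`.
#' @export
derivationSeries <- function(x) x@series

#' @describeIn buildDerivations per-derivation substitution provenance:
#'   `NULL` if computed from its own electrodes, otherwise the name of the
#'   derivation it copies.
#' @export
substitutionInfo <- function(x) x@substituted

setMethod("show", "DerivationSet", function(object) {
  cat(sprintf("DerivationSet: %d samples @ %g Hz\n",
              nrow(object@series), object@fs))
  for (d in c("LR", "L", "R")) {
    sub <- object@substituted[[d]]
    if (is.null(sub)) {
      u <- object@usedElectrodes[[d]]
      cat(sprintf("  %-2s : [%s] - [%s]\n", d,
                  paste(u$minuend, collapse = ","),
                  paste(u$subtrahend, collapse = ",")))
    } else {
      cat(sprintf("  %-2s : substituted (copy of %s)\n", d, sub))
    }
  }
})

# ---------------------------------------------------------------------------
# CVPlan and EvaluationReport (validation module)
# ---------------------------------------------------------------------------

#' @rdname makeCVPlan
#' @export
setClass("CVPlan",
  representation(
    scheme = "character",
    folds = "list",            # each: list(train = int, test = int) 1-based
    subjectOf = "character"    # per-epoch subject id
  )
)

setValidity("CVPlan", function(object) {
  n <- length(object@subjectOf)
  test <- unlist(lapply(object@folds, `[[`, "test"))
  if (anyDuplicated(test)) return("test sets must be pairwise disjoint")
  if (!setequal(test, seq_len(n))) return("test sets must cover all epochs")
  TRUE
})

#' @describeIn makeCVPlan list of folds, each a list with integer `train`
#'   and `test` epoch indices.
#' @param x A `CVPlan`.
#' @export
cvFolds <- function(x) x@folds

setMethod("show", "CVPlan", function(object) {
  sz <- vapply(object@folds, function(f) length(f$test), integer(1))
  cat(sprintf("CVPlan '%s': %d folds over %d epochs (test sizes %s)\n",
              object@scheme, length(object@folds), length(object@subjectOf),
              paste(range(sz), collapse = "-")))
})

#' @rdname evaluateStaging
#' @export
setClass("EvaluationReport",
  representation(
    confusion = "matrix",      # manual rows x automatic columns
    kappa = "numeric",
    accuracy = "numeric",
    sensitivity = "numeric",   # named per class
    specificity = "numeric",
    level = "integer"
  )
)

setValidity("EvaluationReport", function(object) {
  if (any(object@confusion < 0)) return("confusion counts must be nonnegative")
  if (object@kappa < -1 - 1e-12 || object@kappa > 1 + 1e-12)
    return("kappa must lie in [-1, 1]")
  TRUE
})

#' @describeIn evaluateStaging confusion matrix (manual labels in rows,
#'   automatic labels in columns).
#' @param x An `EvaluationReport`.
#' @export
confusionMatrix <- function(x) x@confusion

#' @describeIn evaluateStaging pooled Cohen's kappa.
#' @export
kappaValue <- function(x) x@kappa

#' @describeIn evaluateStaging pooled accuracy (trace over total).
#' @export
accuracyValue <- function(x) x@accuracy

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf("EvaluationReport (%d-stage): kappa = %.3f, accuracy = %.3f\n",
              object@level, object@kappa, object@accuracy))
  cat("Confusion (rows manual, columns automatic):\n")
  print(object@confusion)
  print(data.frame(class = names(object@sensitivity),
                   sensitivity = round(object@sensitivity, 3),
                   specificity = round(object@specificity, 3),
                   row.names = NULL))
})
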