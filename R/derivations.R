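# The twelve ear electrodes are distilled into three analysis derivations:
#   L-R : mean(left six)  - mean(right six)
#   L   : mean(ELA, ELB)  - mean(ELE, ELI, ELG, ELK)   (concha - canal)
#   R   : mean(ERA, ERB)  - mean(ERE, ERI, ERG, ERK)
# Rejected electrodes are excluded from the averages; a derivation whose
# minuend or subtrahend group is left empty is substituted with a copy of
# another derivation (the one-eared-subject rule).

.groupMean <- function(x, electrodes) {
  if (length(electrodes) == 1L) x[, electrodes] else
    rowMeans(x[, electrodes, drop = FALSE])
}

#' Build the three ear-EEG analysis derivations
#'
#' Constructs the left-minus-right (`LR`), left within-ear (`L`) and right
#' within-ear (`R`) derivations from the electrodes surviving quality
#' control. Each derivation is a difference of group means; rejected or
#' unusable electrodes are excluded from the averages, and a one-electrode
#' "mean" is that electrode itself.
#'
#' When a group is emptied entirely, the affected derivation is substituted
#' with a byte-identical copy of another: a missing `L` copies `R`, a
#' missing `R` copies `L`, and a missing `LR` copies `L` (or `R` if `L` is
#' itself missing). `LR` is deemed uncomputable whenever a whole ear is
#' missing, since a one-sided "difference" is meaningless; for a subject
#' with one working ear all three derivations are therefore identical.
#'
#' @param rec An [EarRecording-class] with ear-EEG channels.
#' @param qc A `ChannelQuality` from [rejectChannels()], or `NULL` to use
#'   all present electrodes.
#' @return A `DerivationSet`; see [derivationSeries()],
#'   [substitutionInfo()].
#' @aliases DerivationSet-class
#' @export
buildDerivations <- function(rec, qc = NULL) {
  labs <- intersect(channelLabels(rec), earElectrodes())
  if (!length(labs)) stop("no ear-EEG channels present")
  dropped <- if (is.null(qc)) character() else
    c(rejectedChannels(qc), qc@unusable)
  alive <- setdiff(labs, dropped)
  x <- signalMatrix(rec)

  groups <- list(
    LR = list(minuend = intersect(alive, earElectrodes("left")),
              subtrahend = intersect(alive, earElectrodes("right"))),
    L = list(minuend = intersect(alive, .conchaOf("left")),
             subtrahend = intersect(alive, .canalOf("left"))),
    R = list(minuend = intersect(alive, .conchaOf("right")),
             subtrahend = intersect(alive, .canalOf("right"))))
  computable <- vapply(groups, function(g)
    length(g$minuend) > 0L && length(g$subtrahend) > 0L, logical(1))
  if (!any(computable)) stop("no derivation computable: all electrodes rejected")

  n <- nrow(x)
  series <- matrix(0, n, 3, dimnames = list(NULL, c("LR", "L", "R")))
  gm <- list(); used <- list(); subst <- list(LR = NULL, L = NULL, R = NULL)
  for (d in c("LR", "L", "R")) {
    if (computable[[d]]) {
      g <- groups[[d]]
      a <- .groupMean(x, g$minuend)
      b <- .groupMean(x, g$subtrahend)
      series[, d] <- a - b
      gm[[d]] <- list(minuend = a, subtrahend = b)
      used[[d]] <- g
    }
  }
  # substitution priority: L <- R, R <- L, LR <- L else R
  pickFor <- list(LR = c("L", "R"), L = c("R", "LR"), R = c("L", "LR"))
  for (d in c("L", "R", "LR")) {
    if (computable[[d]]) next
    src <- pickFor[[d]][computable[pickFor[[d]]]][1]
    if (is.na(src)) src <- names(which(computable))[1]
    series[, d] <- series[, src]
    gm[[d]] <- gm[[src]]
    used[[d]] <- used[[src]]
    subst[[d]] <- src
  }
  new("DerivationSet", series = series, groupMeans = gm[c("LR", "L", "R")],
      usedElectrodes = used[c("LR", "L", "R")], substituted = subst,
      fs = samplingRate(rec))
}
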