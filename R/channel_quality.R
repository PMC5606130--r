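# Electrode rejection. In-ear electrodes deteriorate overnight (drying gel,
# ear deformation on the pillow); a high-impedance electrode carries excess
# high-frequency noise in every derivation it takes part in. The rejection
# rule therefore forms all intra-ear pairwise derivations, measures their
# 10-35 Hz spectral density, and rejects an electrode whose median pairwise
# density exceeds 5e-12 V^2/Hz. No reference ("ground truth") electrode is
# needed.

#' Reject deteriorated ear-EEG electrodes
#'
#' For every same-ear electrode pair (i, j), computes the mean Welch PSD
#' density of the difference signal over the quality-control band
#' (10-35 Hz by default), on the whole recording without epoching. Each
#' electrode's score `m_i` is the median of its pairwise densities; the
#' electrode is rejected when `m_i` exceeds the threshold (default
#' 5e-12 V^2/Hz). Pairwise differencing cancels the common recording
#' reference, so the rule is invariant to any signal shared by all
#' channels.
#'
#' An ear contributing fewer than two electrodes cannot form intra-ear
#' pairs; its electrodes are marked unusable (with a warning) rather than
#' silently kept.
#'
#' @param rec An [EarRecording-class] containing ear-EEG channels named per
#'   [earElectrodes()]. Non-ear channels are ignored.
#' @param threshold Rejection threshold in V^2/Hz (default `5e-12`).
#' @param band Quality-control band in Hz (default `c(10, 35)`). The band
#'   limitation exists only inside this rule; unfiltered data proceed to
#'   the rest of the pipeline.
#' @return A `ChannelQuality` object; see [rejectedChannels()],
#'   [medianPower()], [keptChannels()].
#' @examples
#' spec <- simSpec(nSubjects = 1, epochsPerSubject = 4, seed = 1,
#'                 badChannels = data.frame(subject = 1, electrode = "ELA",
#'                                          noiseRMS = 50e-6))
#' rec <- simulateRecording(simulateHypnogram(spec, 1), spec, 1)
#' rejectedChannels(rejectChannels(rec))
#' @aliases ChannelQuality-class
#' @export
rejectChannels <- function(rec, threshold = 5e-12, band = c(10, 35)) {
  labs <- intersect(channelLabels(rec), earElectrodes())
  if (!length(labs)) stop("no ear-EEG channels present")
  fs <- samplingRate(rec)
  x <- signalMatrix(rec)
  ears <- list(left = intersect(labs, earElectrodes("left")),
               right = intersect(labs, earElectrodes("right")))
  unusable <- character()
  p <- matrix(NA_real_, length(labs), length(labs),
              dimnames = list(labs, labs))
  for (ear in names(ears)) {
    el <- ears[[ear]]
    if (length(el) == 0L) next
    if (length(el) < 2L) {
      warning(ear, " ear has fewer than 2 electrodes; marking ",
              paste(el, collapse = ", "), " unusable")
      unusable <- c(unusable, el)
      next
    }
    for (a in seq_len(length(el) - 1L)) {
      for (b in (a + 1L):length(el)) {
        d <- x[, el[a]] - x[, el[b]]
        pv <- bandPowerDensity(d, fs, band)
        p[el[a], el[b]] <- pv
        p[el[b], el[a]] <- pv
      }
    }
  }
  m <- vapply(labs, function(i) {
    vals <- p[i, !is.na(p[i, ])]
    if (length(vals)) median(vals) else NA_real_
  }, numeric(1))
  rejected <- labs[!is.na(m) & m > threshold]
  new("ChannelQuality", pairwisePower = p, medianPower = m,
      rejected = rejected, unusable = unusable,
      threshold = threshold, band = band)
}
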