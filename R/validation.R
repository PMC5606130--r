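# Cross-validation and agreement metrics. Three schemes are provided, all
# with CONTIGUOUS test blocks where the scheme partitions within a sequence:
# adjacent 30-s epochs are highly correlated, and scattering test epochs
# between training neighbours leaks label information (the "neighbor
# effect"), inflating agreement. A deliberately leaky interleaved mode
# exists solely to demonstrate that bias and is labelled as such.

.levelVocab <- function(level) {
  switch(as.character(level),
         "5" = sleepStages(),
         "3" = c("W", "REM", "NREM"),
         "2" = c("W", "Sleep"),
         stop("level must be 5, 3 or 2"))
}

# contiguous near-equal blocks; earlier blocks take the extra epoch
.blockSizes <- function(n, k) {
  q <- n %/% k; r <- n %% k
  c(rep(q + 1L, r), rep(q, k - r))
}

.splitContiguous <- function(idx, k) {
  sizes <- .blockSizes(length(idx), k)
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  lapply(seq_len(k), function(i) idx[starts[i]:ends[i]])
}

# round-robin interleaving: epoch i lands in fold (i-1) mod k + 1, so every
# test epoch has train neighbours on both sides -- the leaky layout
.splitInterleaved <- function(idx, k) {
  lapply(seq_len(k), function(i) idx[seq_along(idx) %% k == i %% k])
}

#' Build a cross-validation plan
#'
#' Three schemes over the pooled epoch sequence (subjects concatenated in
#' input order):
#' \describe{
#'   \item{`leave_one_out`}{one fold per subject; the test set is all of
#'     that subject's epochs, training is everyone else.}
#'   \item{`total`}{the pooled sequence is cut into `nFolds` (default 20)
#'     contiguous near-equal blocks (sizes differ by at most 1, earlier
#'     blocks take the extra epoch); each block is tested against a model
#'     trained on the rest.}
#'   \item{`individual`}{each subject's own sequence is cut into `nFolds`
#'     (default 10) contiguous blocks; each block is tested against a model
#'     trained on the remaining blocks of the same subject only.}
#' }
#' With `scattered = TRUE` the `total`/`individual` blocks are replaced by
#' a deterministic round-robin interleaving, so test epochs sit between
#' training neighbours. This layout is leaky and exists only to quantify
#' the neighbor effect; the plan's scheme is suffixed `"_leaky"`.
#'
#' @param scheme `"leave_one_out"`, `"total"` or `"individual"`.
#' @param epochsPerSubject Named integer vector of epoch counts, one per
#'   subject, in input order.
#' @param nFolds Folds per partitioned sequence; defaults 20 for `total`,
#'   10 for `individual`, ignored for `leave_one_out`.
#' @param scattered Use the leaky interleaved layout (default `FALSE`).
#' @return A `CVPlan`; see [cvFolds()].
#' @examples
#' plan <- makeCVPlan("total", c(s1 = 12, s2 = 13), nFolds = 5)
#' lengths(lapply(cvFolds(plan), `[[`, "test"))
#' @aliases CVPlan-class
#' @export
makeCVPlan <- function(scheme = c("leave_one_out", "total", "individual"),
                       epochsPerSubject, nFolds = NULL, scattered = FALSE) {
  scheme <- match.arg(scheme)
  counts <- as.integer(epochsPerSubject)
  if (any(counts < 1L)) stop("epoch counts must be positive")
  subj <- names(epochsPerSubject)
  if (is.null(subj)) subj <- paste0("s", seq_along(counts))
  subjectOf <- rep(subj, counts)
  n <- sum(counts)
  allIdx <- seq_len(n)
  splitter <- if (scattered) .splitInterleaved else .splitContiguous

  if (scheme == "leave_one_out") {
    if (scattered) stop("'leave_one_out' has no scattered variant")
    folds <- lapply(subj, function(s) {
      test <- allIdx[subjectOf == s]
      list(train = setdiff(allIdx, test), test = test)
    })
  } else if (scheme == "total") {
    if (is.null(nFolds)) nFolds <- 20L
    if (nFolds > n) stop("more folds (", nFolds, ") than epochs (", n, ")")
    blocks <- splitter(allIdx, as.integer(nFolds))
    folds <- lapply(blocks, function(b)
      list(train = setdiff(allIdx, b), test = b))
  } else {
    if (is.null(nFolds)) nFolds <- 10L
    folds <- list()
    for (s in subj) {
      mine <- allIdx[subjectOf == s]
      if (nFolds > length(mine))
        stop("more folds (", nFolds, ") than epochs (", length(mine),
             ") for subject ", s)
      blocks <- splitter(mine, as.integer(nFolds))
      folds <- c(folds, lapply(blocks, function(b)
        list(train = setdiff(mine, b), test = b)))
    }
  }
  new("CVPlan",
      scheme = if (scattered) paste0(scheme, "_leaky") else scheme,
      folds = folds, subjectOf = subjectOf)
}

#' Run cross-validated staging
#'
#' For each fold of the plan, trains a fresh stager on the training epochs
#' and predicts the test epochs, so every epoch receives exactly one
#' prediction. Fold seeds are derived deterministically from the master
#' seed.
#'
#' @param features A `SleepFeatures` object or epochs-by-features matrix.
#' @param labels Stage label per epoch (taken from `features` if omitted).
#' @param plan A `CVPlan` from [makeCVPlan()].
#' @param seed Master RNG seed.
#' @param nTrees,mtry Passed to [trainStager()].
#' @return Character vector: the predicted stage of every epoch.
#' @export
runCV <- function(features, labels = NULL, plan, seed = 1L, nTrees = 100,
                  mtry = NULL) {
  X <- if (is(features, "SleepFeatures")) featureValues(features) else
    as.matrix(features)
  if (is.null(labels) && is(features, "SleepFeatures"))
    labels <- epochStages(features)
  labels <- as.character(labels)
  if (length(labels) != nrow(X) || length(plan@subjectOf) != nrow(X))
    stop("features, labels and plan must agree in epoch count")
  pred <- rep(NA_character_, nrow(X))
  for (k in seq_along(plan@folds)) {
    f <- plan@folds[[k]]
    fit <- trainStager(X[f$train, , drop = FALSE], labels[f$train],
                       nTrees = nTrees, mtry = mtry,
                       seed = (as.integer(seed) + 104729L * k) %% .Machine$integer.max)
    pred[f$test] <- predictStages(fit, X[f$test, , drop = FALSE])
  }
  pred
}

#' Collapse stage labels to a coarser resolution
#'
#' Level 5 is the identity; level 3 relabels `N1`, `N2`, `N3` to `NREM`
#' (W-REM-NREM scoring); level 2 relabels `REM` and all NREM stages to
#' `Sleep` (sleep-wake scoring). Collapsing is pure relabelling, applied to
#' manual and automatic labels alike -- classifiers are never retrained for
#' coarser levels. Collapsing commutes: going 5 to 3 to 2 equals going
#' straight to 2.
#'
#' @param labels Character vector of stage labels.
#' @param level 5, 3 or 2.
#' @return Relabelled character vector.
#' @examples
#' collapseStages(c("W", "N1", "REM"), 2)
#' @export
collapseStages <- function(labels, level) {
  level <- as.integer(level)
  labels <- as.character(labels)
  known <- c(sleepStages(), "NREM", "Sleep")
  bad <- setdiff(unique(labels), known)
  if (length(bad)) stop("unknown stage label(s): ", paste(bad, collapse = ", "))
  if (level == 5L) return(labels)
  if (level == 3L) {
    labels[labels %in% c("N1", "N2", "N3")] <- "NREM"
    return(labels)
  }
  if (level == 2L) {
    labels[labels %in% c("REM", "N1", "N2", "N3", "NREM")] <- "Sleep"
    return(labels)
  }
  stop("level must be 5, 3 or 2")
}

#' Cohen's kappa from a confusion matrix
#'
#' Chance-corrected agreement: `kappa = (p_o - p_e) / (1 - p_e)` with
#' `p_o` the observed agreement (trace over total) and `p_e` the chance
#' agreement expected from the row and column marginals. The degenerate
#' single-cell case (`p_e = 1`, `p_o = 1`) returns 0.
#'
#' @param confusion Square nonnegative count matrix (manual rows,
#'   automatic columns).
#' @return Kappa in `[-1, 1]`.
#' @examples
#' cohenKappa(matrix(c(45, 15, 5, 35), 2))  # 0.6
#' @export
cohenKappa <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (!length(confusion) || nrow(confusion) != ncol(confusion))
    stop("confusion must be a nonempty square matrix")
  if (any(confusion < 0)) stop("confusion counts must be nonnegative")
  total <- sum(confusion)
  if (total <= 0) stop("empty confusion matrix")
  po <- sum(diag(confusion)) / total
  pe <- sum(rowSums(confusion) * colSums(confusion)) / total^2
  if (abs(1 - pe) < 1e-15) return(0)
  (po - pe) / (1 - pe)
}

#' Evaluate automatic against manual staging
#'
#' Collapses both label sequences to the requested level, tabulates the
#' confusion matrix over the full level vocabulary (manual labels in rows,
#' automatic in columns), and computes pooled Cohen's kappa, accuracy, and
#' one-vs-rest per-class sensitivity `TP/(TP+FN)` and specificity
#' `TN/(TN+FP)` (0 when undefined).
#'
#' @param manual,automatic Equal-length stage label vectors.
#' @param level 5, 3 or 2 (default 5).
#' @return An `EvaluationReport`; see [confusionMatrix()], [kappaValue()],
#'   [accuracyValue()].
#' @aliases EvaluationReport-class
#' @export
evaluateStaging <- function(manual, automatic, level = 5) {
  if (length(manual) != length(automatic))
    stop("label sequences differ in length")
  vocab <- .levelVocab(level)
  m <- factor(collapseStages(manual, level), levels = vocab)
  a <- factor(collapseStages(automatic, level), levels = vocab)
  conf <- table(manual = m, automatic = a)
  conf <- matrix(as.integer(conf), nrow(conf), ncol(conf),
                 dimnames = list(manual = vocab, automatic = vocab))
  total <- sum(conf)
  sens <- spec <- numeric(length(vocab))
  names(sens) <- names(spec) <- vocab
  for (k in seq_along(vocab)) {
    tp <- conf[k, k]
    fn <- sum(conf[k, ]) - tp
    fp <- sum(conf[, k]) - tp
    tn <- total - tp - fn - fp
    sens[k] <- if (tp + fn > 0) tp / (tp + fn) else 0
    spec[k] <- if (tn + fp > 0) tn / (tn + fp) else 0
  }
  new("EvaluationReport", confusion = conf, kappa = cohenKappa(conf),
      accuracy = sum(diag(conf)) / total, sensitivity = sens,
      specificity = spec, level = as.integer(level))
}

#' Per-subject kappa table and its unweighted average
#'
#' Computes Cohen's kappa separately for each subject's epochs at the
#' requested level, plus the plain unweighted mean across subjects (each
#' subject counts once, regardless of epoch count).
#'
#' @param manual,automatic Stage label vectors.
#' @param subjects Per-epoch subject ids.
#' @param level 5, 3 or 2.
#' @return List with `kappa` (named per-subject vector) and `average`.
#' @export
perSubjectKappa <- function(manual, automatic, subjects, level = 5) {
  subjects <- as.character(subjects)
  ids <- unique(subjects)
  k <- vapply(ids, function(s) {
    sel <- subjects == s
    kappaValue(evaluateStaging(manual[sel], automatic[sel], level))
  }, numeric(1))
  list(kappa = k, average = subjectAverage(k))
}

#' Unweighted across-subject average
#'
#' The averaging convention used for per-subject summaries: the plain mean
#' of the per-subject values, never weighted by each subject's epoch count.
#'
#' @param x Numeric vector of per-subject values.
#' @return Their unweighted mean.
#' @export
subjectAverage <- function(x) mean(x)
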