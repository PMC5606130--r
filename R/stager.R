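# Stage classifier: an ensemble of 100 bagged decision trees. Each tree is
# grown on a bootstrap resample of the training set of the same size
# (duplicates allowed), splitting on Gini impurity until leaves are pure or
# reach the minimum size of 1, with ALL features candidate at every split
# (pure bagging -- a random feature subspace would be a different method;
# a knob exists but defaults to everything). Prediction is an unweighted
# majority vote over the trees, with a deterministic tie-break.

#' @rdname trainStager
#' @export
setClass("SleepStager",
  representation(
    forest = "ANY",             # randomForest fit
    classes = "character",      # stage vocabulary, fixed order
    prevalence = "numeric",     # training-set class counts, named
    featureNames = "character",
    nTrees = "integer",
    seed = "integer"
  )
)

setValidity("SleepStager", function(object) {
  if (object@nTrees < 1L) return("'nTrees' must be positive")
  if (!length(object@featureNames)) return("feature names missing")
  TRUE
})

setMethod("show", "SleepStager", function(object) {
  cat(sprintf("SleepStager: %d bagged trees over %d features, classes: %s\n",
              object@nTrees, length(object@featureNames),
              paste(object@classes, collapse = " ")))
  prev <- object@prevalence
  cat("  training prevalence:",
      paste(sprintf("%s=%d", names(prev), prev), collapse = " "), "\n")
})

#' Train the bagged decision-tree sleep stager
#'
#' Fits `nTrees` classification trees, each on a bootstrap resample of the
#' training set of the same size with duplicates allowed, splitting by Gini
#' impurity down to a minimum leaf size of 1. By default every feature is a
#' candidate at every split (pure bagging); `mtry` can be lowered to a
#' random-subspace forest if desired. Fully seeded and reproducible.
#'
#' @param features A `SleepFeatures` object or an epochs-by-features
#'   numeric matrix.
#' @param labels Stage label per epoch (taken from `features` if omitted
#'   and available).
#' @param nTrees Number of trees (default 100).
#' @param mtry Number of features tried at each split; default all of them.
#' @param seed RNG seed controlling the bootstrap draws.
#' @return A `SleepStager` object.
#' @examples
#' X <- matrix(rnorm(60 * 99), 60, 99,
#'             dimnames = list(NULL, featureNames99()))
#' X[1:30, 1] <- X[1:30, 1] + 5
#' fit <- trainStager(X, rep(c("W", "N2"), each = 30), seed = 1)
#' predictStages(fit, X)[1:3]
#' @aliases SleepStager-class
#' @export
trainStager <- function(features, labels = NULL, nTrees = 100, mtry = NULL,
                        seed = 1L) {
  X <- if (is(features, "SleepFeatures")) featureValues(features) else
    as.matrix(features)
  if (is.null(labels) && is(features, "SleepFeatures"))
    labels <- epochStages(features)
  if (is.null(labels) || anyNA(labels))
    stop("stage labels are required for training")
  labels <- as.character(labels)
  if (length(labels) != nrow(X))
    stop("row/label count mismatch: ", nrow(X), " feature rows vs ",
         length(labels), " labels")
  present <- intersect(sleepStages(), unique(labels))
  bad <- setdiff(unique(labels), sleepStages())
  if (length(bad)) stop("unknown stage label(s): ", paste(bad, collapse = ", "))
  if (length(present) < 2L)
    stop("single-class training set (only '", present, "'); need >= 2 classes")
  if (is.null(mtry)) mtry <- ncol(X)
  y <- factor(labels, levels = present)
  set.seed(as.integer(seed))
  fit <- randomForest::randomForest(
    x = X, y = y, ntree = nTrees, mtry = mtry, nodesize = 1,
    replace = TRUE, sampsize = nrow(X))
  new("SleepStager", forest = fit, classes = present,
      prevalence = vapply(present, function(cl) sum(labels == cl), 0),
      featureNames = colnames(X), nTrees = as.integer(nTrees),
      seed = as.integer(seed))
}

#' Predict sleep stages with a trained stager
#'
#' Per epoch, the unweighted majority vote over the ensemble's trees. Ties
#' are broken deterministically: first toward the class with the higher
#' training prevalence, then by the fixed stage order W, REM, N1, N2, N3.
#'
#' @param model A `SleepStager` from [trainStager()].
#' @param features A `SleepFeatures` object or an epochs-by-features
#'   matrix whose column names match the training features.
#' @return Character vector of predicted stage labels, one per epoch.
#' @export
predictStages <- function(model, features) {
  X <- if (is(features, "SleepFeatures")) featureValues(features) else
    as.matrix(features)
  if (!identical(colnames(X), model@featureNames)) {
    missing <- setdiff(model@featureNames, colnames(X))
    extra <- setdiff(colnames(X), model@featureNames)
    if (length(missing) || length(extra) ||
        !setequal(colnames(X), model@featureNames))
      stop("feature columns do not match training: missing [",
           paste(missing, collapse = ", "), "], unexpected [",
           paste(extra, collapse = ", "), "]")
    X <- X[, model@featureNames, drop = FALSE]  # same set, wrong order
  }
  votes <- predict(model@forest, X, type = "vote", norm.votes = FALSE)
  .voteDecide(votes[, model@classes, drop = FALSE], model@classes,
              model@prevalence[model@classes])
}

# Majority vote with the deterministic tie-break: higher training
# prevalence first, then the fixed stage order W > REM > N1 > N2 > N3.
.voteDecide <- function(votes, classes, prevalence) {
  ord <- match(classes, sleepStages())
  apply(votes, 1, function(v) {
    cand <- which(v == max(v))
    if (length(cand) > 1L)
      cand <- cand[prevalence[cand] == max(prevalence[cand])]
    if (length(cand) > 1L) cand <- cand[which.min(ord[cand])]
    classes[cand[1L]]
  })
}

#' Serialize / restore a trained stager
#'
#' Writes a versioned single-file representation (base R serialization) of
#' the ensemble and restores it.
#'
#' @param model A `SleepStager`.
#' @param path File path.
#' @return `path` (save) or the restored `SleepStager` (load).
#' @export
saveStager <- function(model, path) {
  saveRDS(list(format = "earsleep-stager", version = 1L, model = model), path)
  invisible(path)
}

#' @rdname saveStager
#' @export
loadStager <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "earsleep-stager"))
    stop("not an earsleep stager file: ", path)
  obj$model
}
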