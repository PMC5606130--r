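test_that("leave-one-out folds partition epochs by subject", {
  plan <- makeCVPlan("leave_one_out", c(a = 3, b = 4, c = 5))
  folds <- cvFolds(plan)
  expect_length(folds, 3)
  expect_identical(folds[[1]]$test, 1:3)
  expect_identical(folds[[2]]$test, 4:7)
  expect_identical(folds[[3]]$test, 8:12)
  expect_identical(folds[[2]]$train, c(1:3, 8:12))
  expect_setequal(unlist(lapply(folds, `[[`, "test")), 1:12)
})

test_that("pooled 20-fold splitting of 7411 epochs gives 11 blocks of 371 and 9 of 370", {
  counts <- c(1040, 964, 932, 1150, 491, 926, 758, 293, 857)
  plan <- makeCVPlan("total", counts, nFolds = 20)
  sizes <- vapply(cvFolds(plan), function(f) length(f$test), integer(1))
  expect_identical(sizes, c(rep(371L, 11), rep(370L, 9)))
  # each test set is one contiguous run
  for (f in cvFolds(plan))
    expect_identical(f$test, seq(min(f$test), max(f$test)))
  expect_setequal(unlist(lapply(cvFolds(plan), `[[`, "test")), 1:7411)
})

test_that("individual folds stay within subject and cover each sequence in order", {
  plan <- makeCVPlan("individual", c(s1 = 10), nFolds = 10)
  folds <- cvFolds(plan)
  expect_length(folds, 10)
  expect_identical(lapply(folds, `[[`, "test"), as.list(1:10))
  plan2 <- makeCVPlan("individual", c(a = 25, b = 13), nFolds = 5)
  expect_length(cvFolds(plan2), 10)
  for (f in cvFolds(plan2)) {
    subjects <- unique(plan2@subjectOf[c(f$train, f$test)])
    expect_length(subjects, 1)    # training never crosses subjects
  }
  expect_error(makeCVPlan("individual", c(a = 5), nFolds = 10), "more folds")
  expect_error(makeCVPlan("total", c(a = 5), nFolds = 10), "more folds")
})

test_that("the scattered layout interleaves and is labelled leaky", {
  plan <- makeCVPlan("total", c(a = 10), nFolds = 5, scattered = TRUE)
  expect_identical(plan@scheme, "total_leaky")
  expect_identical(cvFolds(plan)[[1]]$test, c(1L, 6L))
  expect_identical(cvFolds(plan)[[5]]$test, c(5L, 10L))
  expect_error(makeCVPlan("leave_one_out", c(a = 5), scattered = TRUE),
               "no scattered variant")
})

test_that("stage collapsing relabels and commutes", {
  expect_identical(collapseStages(c("W", "N1", "N2", "N3", "REM"), 3),
                   c("W", "NREM", "NREM", "NREM", "REM"))
  expect_identical(collapseStages(c("W", "N1", "REM"), 2),
                   c("W", "Sleep", "Sleep"))
  x <- c("W", "REM", "N1", "N2", "N3", "W")
  expect_identical(collapseStages(x, 5), x)
  expect_identical(collapseStages(collapseStages(x, 3), 2),
                   collapseStages(x, 2))
  expect_error(collapseStages("S4", 3), "unknown stage")
  expect_error(collapseStages("W", 4), "level must be")
})

test_that("kappa matches hand-computed and brute-force values", {
  expect_equal(cohenKappa(diag(c(10, 20, 30))), 1)
  expect_equal(cohenKappa(matrix(c(45, 15, 5, 35), 2)), 0.6, tolerance = 1e-12)
  # chance agreement with matched marginals
  m <- outer(c(30, 70), c(30, 70)) / 100
  expect_equal(cohenKappa(m), 0, tolerance = 1e-12)
  # degenerate single-cell table
  expect_equal(cohenKappa(matrix(5, 1, 1)), 0)
  expect_error(cohenKappa(matrix(0, 2, 2)), "empty")
  expect_error(cohenKappa(matrix(-1, 2, 2) + 2 * diag(2)), "nonnegative")

  set.seed(51)
  for (i in 1:200) {
    k <- sample(2:5, 1)
    m <- matrix(rpois(k * k, 8), k)
    if (sum(m) == 0) next
    expect_equal(cohenKappa(m), bruteKappa(m), tolerance = 1e-12)
  }
})

test_that("kappa agrees with an independent library implementation", {
  skip_if_not_installed("e1071")
  set.seed(52)
  for (i in 1:50) {
    m <- matrix(rpois(25, 10), 5)
    expect_equal(cohenKappa(m), e1071::classAgreement(m)$kappa,
                 tolerance = 1e-10)
  }
})

test_that("kappa increases with diagonal mass at fixed marginals", {
  prev <- -Inf
  for (a in seq(10, 40, by = 5)) {
    m <- matrix(c(a, 50 - a, 50 - a, a), 2)   # marginals fixed at 50/50
    k <- cohenKappa(m)
    expect_gt(k, prev)
    prev <- k
  }
})

test_that("evaluation reports confusion, kappa and one-vs-rest rates", {
  manual <- c("W", "W", "N1", "N2", "N3", "REM")
  rep1 <- evaluateStaging(manual, manual, 5)
  expect_equal(kappaValue(rep1), 1)
  expect_equal(accuracyValue(rep1), 1)
  expect_true(all(rep1@sensitivity == 1))
  expect_identical(rownames(confusionMatrix(rep1)), sleepStages())

  rep2 <- evaluateStaging(manual, rep("W", 6), 5)
  expect_equal(unname(rep2@sensitivity["W"]), 1)
  expect_true(all(rep2@sensitivity[c("REM", "N1", "N2", "N3")] == 0))
  expect_equal(unname(rep2@specificity["W"]), 0)
  expect_equal(sum(confusionMatrix(rep2)), 6)
  expect_error(evaluateStaging(manual, manual[-1]), "differ in length")
})

test_that("pooled kappa equals kappa of summed per-fold confusions", {
  set.seed(53)
  manual <- sample(sleepStages(), 200, replace = TRUE)
  auto <- ifelse(runif(200) < 0.6, manual,
                 sample(sleepStages(), 200, replace = TRUE))
  folds <- split(1:200, rep(1:4, each = 50))
  summed <- Reduce(`+`, lapply(folds, function(i)
    confusionMatrix(evaluateStaging(manual[i], auto[i], 5))))
  pooled <- evaluateStaging(manual, auto, 5)
  expect_identical(unname(summed), unname(confusionMatrix(pooled)))
  expect_equal(cohenKappa(summed), kappaValue(pooled), tolerance = 1e-12)
})

test_that("per-subject kappa averages subjects without epoch weighting", {
  manual <- c(rep("W", 4), rep(c("W", "N2"), 8))
  auto <- manual
  auto[1] <- "N2"                      # one error in the small subject
  subjects <- c(rep("a", 4), rep("b", 16))
  ps <- perSubjectKappa(manual, auto, subjects, 5)
  expect_equal(ps$average, mean(ps$kappa))
  expect_equal(unname(ps$kappa["b"]), 1)
  expect_equal(subjectAverage(c(0.05, 0.36, 0.57)), mean(c(0.05, 0.36, 0.57)))
})

test_that("cross-validation assigns exactly one prediction per epoch", {
  d <- .twoClassData(n = 40, seed = 54)
  plan <- makeCVPlan("total", c(a = 40), nFolds = 4)
  pred <- runCV(d$X, d$y, plan, seed = 2, nTrees = 25)
  expect_length(pred, 40)
  expect_false(anyNA(pred))
  expect_gt(mean(pred == d$y), 0.9)    # separable classes
  # degenerate single fold with train = test returns training predictions
  degen <- new("CVPlan", scheme = "total",
               folds = list(list(train = 1:40, test = 1:40)),
               subjectOf = rep("a", 40))
  predDegen <- runCV(d$X, d$y, degen, seed = 2, nTrees = 25)
  expect_identical(unname(predDegen), d$y)
})
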