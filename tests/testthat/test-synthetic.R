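test_that("hypnogram simulation follows the transition matrix", {
  ident <- diag(5)
  dimnames(ident) <- list(sleepStages(), sleepStages())
  spec <- simSpec(nSubjects = 1, epochsPerSubject = 50,
                  transitionMatrix = ident, seed = 1)
  expect_identical(stageLabels(simulateHypnogram(spec, 1)), rep("W", 50))

  spec9 <- simSpec(nSubjects = 1, epochsPerSubject = 960, seed = 2)
  st <- stageLabels(simulateHypnogram(spec9, 1))
  selfRate <- mean(head(st, -1) == tail(st, -1))
  expect_equal(selfRate, 0.9, tolerance = 0.034)   # 0.9 +/- 0.03

  expect_identical(stageLabels(simulateHypnogram(spec9, 1)),
                   stageLabels(simulateHypnogram(spec9, 1)))
  badTM <- defaultTransitionMatrix(); badTM[1, 1] <- 0.5
  expect_error(simSpec(transitionMatrix = badTM), "sum to 1")
  expect_error(simSpec(fs = 100), "exceed 160")
})

test_that("recordings are seed-deterministic with 12 conventionally named channels", {
  spec <- tinySpec(seed = 3, nEpochs = 2)
  hyp <- simulateHypnogram(spec, 1)
  r1 <- simulateRecording(hyp, spec, 1)
  r2 <- simulateRecording(hyp, spec, 1)
  expect_identical(signalMatrix(r1), signalMatrix(r2))
  expect_identical(channelLabels(r1), earElectrodes())
  expect_equal(samplingRate(r1), 200)
  expect_equal(nSamples(r1), 2 * 6000)
  # microvolt scale
  expect_lt(max(abs(signalMatrix(r1))), 1e-3)
  expect_gt(sd(signalMatrix(r1)), 1e-7)
})

test_that("stage-conditional spectra have the orderings the features rely on", {
  spec <- tinySpec(seed = 4, nEpochs = 4)
  dens <- function(stage, band) {
    rec <- simulateRecording(SleepHypnogram(rep(stage, 4)), spec, 1)
    d <- derivationSeries(buildDerivations(rec))[, "L"]
    bandPowerDensity(d, 200, band)
  }
  deltaBand <- c(2, 4); alphaBand <- c(8, 13); emgBand <- c(32, 80)
  expect_gt(dens("N3", deltaBand), dens("N2", deltaBand))
  expect_gt(dens("N2", deltaBand), dens("W", deltaBand))
  expect_gt(dens("W", alphaBand), dens("N3", alphaBand))
  expect_gt(dens("W", emgBand), dens("REM", emgBand))
})

test_that("planted bad electrodes are recovered by the rejection rule", {
  spec <- tinySpec(seed = 5, nEpochs = 4, bad = c("ELK", "ERB"))
  rec <- simulateRecording(simulateHypnogram(spec, 1), spec, 1)
  expect_setequal(rejectedChannels(rejectChannels(rec)), c("ELK", "ERB"))
  expect_identical(sort(rec@meta$badChannels), c("ELK", "ERB"))
})

test_that("N2 spindle bursts occur at the configured Poisson rate", {
  spec <- tinySpec(seed = 6, nEpochs = 120)
  hyp <- SleepHypnogram(rep("N2", 120))
  rec <- simulateRecording(hyp, spec, 1)
  truth <- sum(rec@meta$spindleCount)
  lambda <- 3 / 2 * 120                     # 3 per minute, 0.5 min epochs
  expect_lt(abs(truth - lambda), 3 * sqrt(lambda))
  d <- derivationSeries(buildDerivations(rec))[, "L"]
  detected <- sum(vapply(seq_len(120), function(k)
    countSigmaBursts(d[((k - 1) * 6000 + 1):(k * 6000)], 200), integer(1)))
  expect_lt(abs(detected - lambda), 3 * sqrt(lambda))
})

test_that("fixture generation writes EDF + hypnogram + manifest deterministically", {
  spec <- simSpec(nSubjects = 2, epochsPerSubject = 2, seed = 7,
                  badChannels = data.frame(subject = 2, electrode = "ERA",
                                           noiseRMS = 50e-6))
  dir1 <- withr::local_tempdir()
  man <- makeFixture(spec, dir1)
  files <- list.files(dir1)
  expect_setequal(files, c("subject01.edf", "subject01_hypnogram.csv",
                           "subject02.edf", "subject02_hypnogram.csv",
                           "manifest.json"))
  expect_identical(man$subjects[[2]]$badChannels, "ERA")
  rec <- readEDF(file.path(dir1, "subject02.edf"))
  expect_identical(channelLabels(rec), earElectrodes())
  hyp <- readHypnogram(file.path(dir1, "subject02_hypnogram.csv"))
  expect_identical(stageLabels(hyp),
                   stageLabels(simulateHypnogram(spec, 2)))
  # regeneration is byte-identical for text, sample-identical for EDF
  dir2 <- withr::local_tempdir()
  makeFixture(spec, dir2)
  expect_identical(readLines(file.path(dir1, "subject01_hypnogram.csv")),
                   readLines(file.path(dir2, "subject01_hypnogram.csv")))
  expect_identical(signalMatrix(readEDF(file.path(dir1, "subject01.edf"))),
                   signalMatrix(readEDF(file.path(dir2, "subject01.edf"))))
})
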