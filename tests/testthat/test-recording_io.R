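test_that("EDF write/read round-trip reproduces samples within one quantization step", {
  rec <- whiteNoiseRecording(rms = 5e-6, nEpochs = 1, seed = 42)
  path <- withr::local_tempfile(fileext = ".edf")
  writeEDF(rec, path)
  back <- readEDF(path)
  expect_identical(channelLabels(back), earElectrodes())
  expect_equal(samplingRate(back), 200)
  step <- max(abs(signalMatrix(rec))) * 2 / 65535
  expect_lt(max(abs(signalMatrix(back) - signalMatrix(rec))), step)
})

test_that("EDF physical/digital scaling maps full-scale digital to the physical range", {
  # +/-200 uV physical over +/-32767 digital: digital 32767 must read 200e-6 V
  n <- 400
  x <- matrix(rep(200e-6, n), ncol = 1, dimnames = list(NULL, "ELA"))
  path <- withr::local_tempfile(fileext = ".edf")
  writeEDF(EarRecording(x, fs = 200), path, physMaxUV = 200)
  back <- readEDF(path)
  expect_equal(unname(signalMatrix(back)[1, 1]), 200e-6, tolerance = 1e-12)
})

test_that("EDF reader errors on missing files and mismatched sampling rates", {
  expect_error(readEDF(file.path(tempdir(), "no_such.edf")), "not found")
  path <- withr::local_tempfile(fileext = ".edf")
  writeRawEDF(path, labels = c("ELA", "ELB"), sprs = c(200L, 100L))
  expect_error(readEDF(path, channels = c("ELA", "ELB")),
               "mismatched sampling rates.*ELA.*ELB")
  one <- readEDF(path, channels = "ELB")   # single-rate subset still reads
  expect_equal(samplingRate(one), 100)
  expect_error(readEDF(path, channels = "OZ"), "not in file")
})

test_that("hypnogram parsing canonicalises labels and reports bad lines", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("W", "n1", "N2"), path)
  expect_identical(stageLabels(readHypnogram(path)), c("W", "N1", "N2"))
  writeLines(c("NREM3", "rem", "Wake"), path)
  expect_identical(stageLabels(readHypnogram(path)), c("N3", "REM", "W"))
  writeLines(c("W", "S4"), path)
  expect_error(readHypnogram(path), "unknown stage label 'S4' at line 2")
  writeLines(character(), path)
  expect_error(readHypnogram(path), "empty")
})

test_that("hypnogram CSV write/read round-trip is the identity", {
  hyp <- SleepHypnogram(c("W", "N1", "N2", "N3", "REM", "N2"))
  path <- withr::local_tempfile(fileext = ".csv")
  writeHypnogram(hyp, path)
  expect_identical(readLines(path)[1], "epoch,stage")
  expect_identical(stageLabels(readHypnogram(path)), stageLabels(hyp))
})

test_that("epoch segmentation floors to whole 30-s epochs with 0-based half-open spans", {
  rec <- EarRecording(matrix(rnorm(65 * 200) * 1e-6, ncol = 1,
                             dimnames = list(NULL, "ELA")), fs = 200)
  idx <- segmentEpochs(rec)   # 65 s -> 2 epochs, 5 s dropped
  expect_equal(nEpochs(idx), 2L)
  expect_identical(idx@start, c(0L, 6000L))         # epoch k starts at 6000k
  expect_equal(idx@epochLenSamples, 6000L)
  expect_equal(nEpochs(idx) * idx@epochLenSamples, 12000L)
  expect_error(segmentEpochs(EarRecording(
    matrix(rnorm(100) * 1e-6, ncol = 1, dimnames = list(NULL, "ELA")),
    fs = 200)), "shorter than one")
})

test_that("label/signal length disagreement truncates to the shorter with a warning", {
  rec <- whiteNoiseRecording(nEpochs = 4, seed = 7)
  hyp <- SleepHypnogram(rep("N2", 3))
  expect_warning(idx <- segmentEpochs(rec, hyp), "truncating to 3")
  expect_equal(nEpochs(idx), 3L)
  hyp6 <- SleepHypnogram(rep("W", 6))
  expect_warning(idx <- segmentEpochs(rec, hyp6), "truncating to 4")
  expect_equal(nEpochs(idx), 4L)
})

test_that("recording invariants are enforced", {
  expect_error(EarRecording(matrix(c(1, NA), 2, 1,
                                   dimnames = list(NULL, "ELA")), fs = 200),
               "finite")
  expect_error(EarRecording(matrix(0, 2, 2,
                                   dimnames = list(NULL, c("ELA", "ELA"))),
                            fs = 200), "unique")
  expect_error(SleepHypnogram(c("W", "S4")), "unknown stage")
})
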