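test_that("time-domain features match analytic sinusoid and Gaussian oracles", {
  x <- sineEpoch(10)
  td <- timeDomainFeatures(x, fs = FS)
  expect_equal(unname(td["F3"]), 20, tolerance = 0.01)       # 20 crossings/s
  expect_equal(unname(td["F4"]), 2 * pi * 10, tolerance = 0.02)
  expect_equal(unname(td["F5"]), 1, tolerance = 0.02)
  expect_equal(unname(td["F2"]), 1.5, tolerance = 0.01)      # sine kurtosis

  set.seed(21)
  g <- rnorm(EPOCH_N)
  tg <- timeDomainFeatures(g, fs = FS)
  expect_equal(unname(tg["F1"]), 0, tolerance = 0.1)
  expect_equal(unname(tg["F2"]), 3, tolerance = 0.3)
  expect_equal(unname(tg["F6"]), unname(quantile(abs(g), 0.75)))

  expect_equal(unname(timeDomainFeatures(g, g, g, FS)["F7"]), 1)
  expect_equal(unname(timeDomainFeatures(g, g, -g, FS)["F7"]), -1)
})

test_that("EMG-proxy features match a brute-force window oracle", {
  set.seed(22)
  x <- rnorm(EPOCH_N, sd = 2e-6)
  burst <- rep(0, EPOCH_N)
  burst[2001:2400] <- rnorm(400, sd = sqrt(24) * 2e-6)  # 2-s burst at 5x RMS
  xb <- x + burst
  fb <- emgProxyFeatures(xb, FS)
  wins <- matrix(xb, nrow = FS)
  expect_equal(unname(fb["F8"]), var(xb))
  expect_equal(unname(fb["F9"]), min(apply(wins, 2, var)), tolerance = 1e-12)
  expect_lt(fb["F9"], 1.5 * (2e-6)^2)      # quiet-window variance
  expect_gt(fb["F10"], 1)                  # relative burst amplitude
  f0 <- emgProxyFeatures(x, FS)
  expect_lt(f0["F10"], 0.5)                # stationary noise: near zero
  expect_identical(unname(emgProxyFeatures(numeric(EPOCH_N), FS)),
                   c(0, 0, 0))
})

test_that("EOG-proxy features select the slow and rapid eye-movement bands", {
  slow <- eogProxyFeatures(sineEpoch(1, amp = 1e-5), FS)
  expect_gt(slow["F11"], 10 * slow["F12"])
  rapid <- eogProxyFeatures(sineEpoch(3, amp = 1e-5), FS)
  expect_gt(rapid["F12"], 10 * rapid["F11"])
  expect_identical(unname(eogProxyFeatures(numeric(EPOCH_N), FS)), c(0, 0))
})

test_that("spectral features on a degenerate single-bin spectrum", {
  sp <- spectralFeatures(numeric(EPOCH_N), FS, psd = singleBinPSD(10))
  expect_equal(unname(sp["F13"]), 1)                    # all power in alpha
  expect_equal(unname(sp[c("F14", "F15", "F16")]), c(0, 0, 0))
  expect_equal(unname(sp["F27"]), 10)
  expect_lt(abs(sp["F24"] - 10), 0.5)     # within one bin of the line
  expect_lt(abs(sp["F25"] - 10), 0.5)
  expect_equal(unname(sp["F28"]), 0)
})

test_that("spectral features on a flat spectrum: maximal entropy, midpoint edges", {
  sp <- spectralFeatures(numeric(EPOCH_N), FS, psd = flatPSD())
  expect_equal(unname(sp["F28"]), 1, tolerance = 1e-9)
  expect_equal(unname(sp["F25"]), 17, tolerance = 1e-9)   # midpoint of 2-32
  # 95% edge of a flat band spanning cell edges 1.75-32.25 Hz
  expect_equal(unname(sp["F24"]), 1.75 + 0.95 * 30.5, tolerance = 1e-9)
  expect_equal(unname(sum(sp[c("F13", "F14", "F15", "F16")])), 1,
               tolerance = 1e-9)
})

test_that("band-power ratios follow hand-computed values on a two-line spectrum", {
  # 80% of power at 3 Hz (delta), 20% at 10 Hz (alpha)
  x <- sineEpoch(3, amp = 2e-6) + sineEpoch(10, amp = 1e-6)
  sp <- spectralFeatures(x, FS)
  expect_equal(unname(sp["F17"]), 0.25, tolerance = 0.03)  # alpha/delta
  expect_equal(unname(sp["F23"]), 4, tolerance = 0.15)     # (t+d)/(a+b)
  expect_equal(unname(sp["F16"]), 0.8, tolerance = 0.02)
  expect_equal(unname(sum(sp[c("F13", "F14", "F15", "F16")])), 1,
               tolerance = 1e-9)
})

test_that("sleep-event features detect an injected sigma burst", {
  set.seed(23)
  bg <- rnorm(EPOCH_N, sd = 2e-6)
  burst <- numeric(EPOCH_N)
  i <- 2001:2200   # 1 s burst at 5x background RMS
  burst[i] <- 5 * 2e-6 * sqrt(2) * sin(2 * pi * 13 * i / FS) *
    earsleep:::.hannWin(length(i))
  f0 <- sleepEventFeatures(bg, FS)
  f1 <- sleepEventFeatures(bg + burst, FS)
  expect_gte(f1["F33"], 0.5)
  expect_lte(f1["F33"], 1.5)
  expect_gt(f1["F29"], 0.015)
  expect_lt(f1["F29"], 0.08)               # about 1/30 of the samples
  expect_gt(f1["F32"], 2 * f0["F32"])
})

test_that("a stationary tone has stationary sub-segment spectra", {
  f <- sleepEventFeatures(sineEpoch(10, amp = 5e-6), FS)
  expect_lt(f["F30"], 0.05)
  expect_gt(f["F31"], 0.99)
})

test_that("all features are finite and zero-sentineled on degenerate epochs", {
  for (x in list(numeric(EPOCH_N), rep(1e-5, EPOCH_N),
                 c(1e-4, numeric(EPOCH_N - 1)))) {
    v <- earsleep:::.epochFeatures33(x, x, x, x, x, x, FS)
    expect_length(v, 33)
    expect_true(all(is.finite(v)))
  }
  z <- earsleep:::.epochFeatures33(numeric(EPOCH_N), numeric(EPOCH_N),
                                   numeric(EPOCH_N), numeric(EPOCH_N),
                                   numeric(EPOCH_N), numeric(EPOCH_N), FS)
  expect_true(all(z == 0))
})

test_that("features transform correctly under amplitude scaling", {
  set.seed(24)
  x <- bandpassFilter(rnorm(EPOCH_N, sd = 5e-6), FS, 2, 32)
  xo <- bandpassFilter(rnorm(EPOCH_N, sd = 5e-6), FS, 0.5, 30)
  xm <- bandpassFilter(rnorm(EPOCH_N, sd = 5e-6), FS, 32, 80)
  xs <- bandpassFilter(x, FS, 11, 16)
  ga <- x + rnorm(EPOCH_N, sd = 1e-6)
  gb <- rnorm(EPOCH_N, sd = 5e-6)
  v1 <- earsleep:::.epochFeatures33(x, xo, xm, xs, ga, gb, FS)
  cc <- 3.7
  v2 <- earsleep:::.epochFeatures33(cc * x, cc * xo, cc * xm, cc * xs,
                                    cc * ga, cc * gb, FS)
  inv <- c(1:5, 7, 10:31, 33)
  expect_equal(v2[inv], v1[inv], tolerance = 1e-8)
  expect_equal(unname(v2["F6"]), cc * unname(v1["F6"]), tolerance = 1e-8)
  expect_equal(unname(v2[c("F8", "F9")]), cc^2 * unname(v1[c("F8", "F9")]),
               tolerance = 1e-8)
  expect_equal(unname(v2["F32"]), cc * unname(v1["F32"]), tolerance = 1e-8)
})

test_that("the assembled matrix has 99 named columns in derivation-major order", {
  spec <- tinySpec(seed = 31, nEpochs = 3)
  hyp <- simulateHypnogram(spec, 1)
  rec <- simulateRecording(hyp, spec, 1)
  feats <- extractFeatures(buildDerivations(rec), hyp = hyp)
  vals <- featureValues(feats)
  expect_identical(dim(vals), c(3L, 99L))
  expect_identical(colnames(vals), featureNames99())
  expect_identical(featureNames99()[1:34], c(paste0("F", 1:33, "_LR"), "F1_L"))
  expect_true(all(is.finite(vals)))
  expect_identical(epochStages(feats), stageLabels(hyp))
})

test_that("a substituted derivation duplicates its source columns exactly", {
  spec <- tinySpec(seed = 32, nEpochs = 3, bad = earElectrodes("right"))
  hyp <- simulateHypnogram(spec, 1)
  rec <- simulateRecording(hyp, spec, 1)
  qc <- rejectChannels(rec)
  expect_setequal(rejectedChannels(qc), earElectrodes("right"))
  feats <- extractFeatures(buildDerivations(rec, qc), hyp = hyp)
  vals <- featureValues(feats)
  expect_identical(unname(vals[, paste0("F", 1:33, "_R")]),
                   unname(vals[, paste0("F", 1:33, "_L")]))
  expect_identical(unname(vals[, paste0("F", 1:33, "_LR")]),
                   unname(vals[, paste0("F", 1:33, "_L")]))
})

test_that("simulated N3 epochs are delta-dominant relative to wake", {
  spec <- tinySpec(seed = 33, nEpochs = 3)
  recN3 <- simulateRecording(SleepHypnogram(rep("N3", 3)), spec, 1)
  recW <- simulateRecording(SleepHypnogram(rep("W", 3)), spec, 2)
  fN3 <- featureValues(extractFeatures(buildDerivations(recN3)))
  fW <- featureValues(extractFeatures(buildDerivations(recW)))
  expect_gt(mean(fN3[, "F16_L"]), mean(fW[, "F16_L"]))   # relative delta
  expect_gt(mean(fW[, "F13_L"]), mean(fN3[, "F13_L"]))   # relative alpha
})

test_that("features CSV round-trips", {
  spec <- tinySpec(seed = 34, nEpochs = 2)
  hyp <- simulateHypnogram(spec, 1)
  feats <- extractFeatures(buildDerivations(simulateRecording(hyp, spec, 1)),
                           hyp = hyp, subject = "s7")
  path <- withr::local_tempfile(fileext = ".csv")
  writeFeaturesCSV(feats, path)
  back <- readFeaturesCSV(path)
  expect_equal(featureValues(back), featureValues(feats), tolerance = 1e-12)
  expect_identical(epochStages(back), epochStages(feats))
  expect_identical(epochSubjects(back), epochSubjects(feats))
})
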