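# Filtering, trial-matrix assembly, windowing and splitting.

test_that("low-pass filter has unit DC gain", {
  x <- rep(2.5, 400)
  expect_lt(max(abs(lowpassFilter(x) - 2.5)) / 2.5, 1e-6)
})

test_that("cardiac-band sinusoid is attenuated by at least 40 dB", {
  t <- (0:4999) / 10
  for (phase in c(0, 1.1)) {
    s <- sin(2 * pi * 1.2 * t + phase)
    atten <- 20 * log10(sqrt(mean(lowpassFilter(s)^2)) / sqrt(mean(s^2)))
    expect_lt(atten, -40)
  }
  # the analytic zero-phase response at 1.2 Hz is far below that bound
  expect_lt(20 * log10(filterGain(1.2)), -40)
})

test_that("deep passband content is preserved within 2%", {
  t <- (0:4999) / 10
  s <- sin(2 * pi * 0.01 * t + 0.4)
  ratio <- sqrt(mean(lowpassFilter(s)^2)) / sqrt(mean(s^2))
  expect_lt(abs(ratio - 1), 0.02)
  expect_lt(abs(filterGain(0.01) - 1), 0.02)
})

test_that("filter rejects invalid cutoffs and too-short series", {
  expect_error(lowpassFilter(rnorm(100), cutoff = 5), "Nyquist")
  expect_error(lowpassFilter(rnorm(100), cutoff = 7), "Nyquist")
  expect_error(lowpassFilter(rnorm(10), cutoff = 0.09), "too short")
})

test_that("filtering a hemoglobin series preserves shape and smooths both chromophores", {
  hs <- randomHemoglobin(nChannels = 2L, nTime = 500L)
  out <- lowpassFilter(hs)
  expect_s4_class(out, "HemoglobinSeries")
  expect_identical(dim(hbo2(out)), dim(hbo2(hs)))
  expect_lt(stats::var(hbo2(out)[1, ]), stats::var(hbo2(hs)[1, ]))
  expect_lt(stats::var(hb(out)[2, ]), stats::var(hb(hs)[2, ]))
})

test_that("trial matrix has the documented column layout", {
  nt <- 50L
  hbo2m <- matrix(0, 8, nt); hbm <- matrix(0, 8, nt)
  hbo2m[1, ] <- 1:nt       # distinctive channel-1 HbO2
  hbm[1, ] <- -(1:nt)      # distinctive channel-1 Hb
  hbo2m[8, ] <- 100
  hs <- hemoglobinSeries((0:(nt - 1)) / 10, hbo2m, hbm)
  prot <- data.frame(label = 0L, start_s = 0, end_s = nt / 10)
  tm <- assembleTrialMatrix(hs, prot)
  v <- trialValues(tm)
  expect_identical(ncol(v), 16L)
  expect_equal(v[, 1], as.numeric(1:nt))    # col 1 = ch1 dHbO2
  expect_equal(v[, 9], as.numeric(-(1:nt))) # col 9 = ch1 dHb
  expect_equal(v[, 8], rep(100, nt))        # col 8 = ch8 dHbO2
  expect_identical(colnames(v)[c(1, 9)], c("ch1_hbo2", "ch1_hb"))
})

test_that("assembly rejects a wrong channel count with a shape error", {
  hs <- randomHemoglobin(nChannels = 7L, nTime = 20L)
  prot <- data.frame(label = 0L, start_s = 0, end_s = 2)
  expect_error(assembleTrialMatrix(hs, prot), "8 channels, got 7")
})

test_that("trial matrix write/read roundtrip is bit-exact", {
  tm <- standardTrialMatrix(seed = 9)
  path <- withr::local_tempfile(fileext = ".csv")
  writeTrialMatrix(tm, path)
  back <- readTrialMatrix(path)
  expect_identical(unname(trialValues(back)), unname(trialValues(tm)))
  expect_equal(protocol(back), protocol(tm))
  expect_identical(back@trialId, tm@trialId)
})

test_that("splitNum = 8 yields 24 windows of 300 samples (30 s) per trial", {
  ds <- segmentWindows(standardTrialMatrix(), 8L)
  expect_identical(nWindows(ds), 24L)
  expect_identical(windowLength(ds), 300L)
  expect_equal(windowLength(ds) / 10, 30)   # seconds
  # each emotion contributes splitNum windows
  expect_equal(as.vector(table(windowLabels(ds))), c(8L, 8L, 8L))
})

test_that("splitNum = 1 keeps each full emotion segment as one window", {
  ds <- segmentWindows(standardTrialMatrix(), 1L)
  expect_identical(nWindows(ds), 3L)
  expect_identical(windowLength(ds), 2400L)
  expect_identical(sort(windowLabels(ds)), 0:2)
})

test_that("windows are contiguous, non-overlapping and conserve samples", {
  tm <- standardTrialMatrix(seed = 4)
  for (splitNum in c(2L, 4L, 8L)) {
    ds <- segmentWindows(tm, splitNum)
    expect_identical(windowLength(ds) * splitNum, 2400L)
    # stitching windows of segment 1 back together reproduces the segment
    seg1 <- do.call(rbind, ds@windows[provenance(ds)$segment == 1])
    expect_identical(unname(seg1), unname(trialValues(tm)[601:3000, ]))
  }
})

test_that("a non-divisor splitNum is rejected naming the constraint", {
  expect_error(segmentWindows(standardTrialMatrix(), 7L),
               "does not divide.*2400")
})

test_that("stratified split gives 1280 train / 320 test from 1600 windows", {
  n <- 1600L
  windows <- lapply(seq_len(n), function(i) matrix(0, 2, 16))
  ds <- windowDataset(windows, labels = rep(0:2, length.out = n))
  sp <- splitTrainTest(ds, 0.2, seed = 7)
  expect_identical(nWindows(sp$train), 1280L)
  expect_identical(nWindows(sp$test), 320L)
  # conservation and disjointness via provenance
  expect_identical(nWindows(sp$train) + nWindows(sp$test), n)
  # stratification: test-class counts differ by at most 1
  tcounts <- table(windowLabels(sp$test))
  expect_lte(diff(range(tcounts)), 1)
})

test_that("splits are reproducible under a fixed seed and vary across seeds", {
  ds <- separableWindows(60, len = 4L)
  a <- splitTrainTest(ds, 0.25, seed = 123)
  b <- splitTrainTest(ds, 0.25, seed = 123)
  expect_identical(provenance(a$test), provenance(b$test))
  different <- vapply(1:20, function(s) {
    !identical(provenance(splitTrainTest(ds, 0.25, seed = s)$test),
               provenance(a$test))
  }, logical(1))
  expect_true(any(different))
})

test_that("trial-level splitting keeps whole trials on one side", {
  trials <- lapply(1:10, function(s) standardTrialMatrix(seed = s,
                                                         trialId = sprintf("trial%02d", s)))
  ds <- segmentWindows(trials, 4L)
  sp <- splitByTrial(ds, 0.2, seed = 3)
  expect_length(intersect(unique(provenance(sp$train)$trial),
                          unique(provenance(sp$test)$trial)), 0)
  expect_identical(nWindows(sp$train) + nWindows(sp$test), nWindows(ds))
  expect_identical(length(unique(provenance(sp$test)$trial)), 2L)
  # reproducible
  sp2 <- splitByTrial(ds, 0.2, seed = 3)
  expect_identical(provenance(sp$test), provenance(sp2$test))
})

test_that("split errors on an empty class stratum", {
  windows <- lapply(1:20, function(i) matrix(0, 2, 16))
  ds <- windowDataset(windows, labels = rep(0:1, 10))  # no class 2
  expect_error(splitTrainTest(ds, 0.2), "empty class stratum")
})

test_that("channel averaging matches a brute-force element mean", {
  trials <- lapply(1:5, function(s) standardTrialMatrix(seed = s))
  avg <- channelAverageWaveforms(trials)
  arr <- simplify2array(lapply(trials, trialValues))
  expect_equal(unname(avg), unname(apply(arr, c(1, 2), mean)), tolerance = 1e-12)
  # single trial is its own average; x and -x cancel
  expect_equal(channelAverageWaveforms(trials[1]), trialValues(trials[[1]]))
  neg <- trials[[1]]
  neg@values <- -neg@values
  expect_true(all(channelAverageWaveforms(list(trials[[1]], neg)) == 0))
})

test_that("window exclusion drops exactly the requested windows", {
  ds <- segmentWindows(standardTrialMatrix(), 8L)
  kept <- excludeWindows(ds, c(1L, 24L))
  expect_identical(nWindows(kept), 22L)
  expect_false(any(provenance(kept)$segment == 1 & provenance(kept)$window == 1))
  expect_error(excludeWindows(ds, 99L), "out of range")
})
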