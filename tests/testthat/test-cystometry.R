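test_that("smoothing window matches the acquisition rate", {
  s500 <- smoothPressure(rnorm(2000), samplingRate = 500)
  expect_identical(attr(s500, "windowSamples"), 50L)
  s5000 <- smoothPressure(rnorm(20000), samplingRate = 5000)
  expect_identical(attr(s5000, "windowSamples"), 500L)
  const <- smoothPressure(rep(7, 1000), samplingRate = 500)
  expect_equal(as.numeric(const), rep(7, 1000))
  expect_error(smoothPressure(rnorm(10), samplingRate = 500), "longer")
})

test_that("a linear ramp thresholds at the start of the lookback window", {
  fs <- 100
  x <- seq(0, 50, by = 0.1)  # constant slope
  res <- computePthresh(x, samplingRate = fs, tPmax = 5, lookbackS = 2)
  expect_equal(res$tThresh, 3)  # 5 - 2
  expect_false(res$flagged)
})

test_that("a two-slope ramp thresholds at the slope change", {
  fs <- 100
  tt <- (0:999) / fs
  tStar <- 6
  s <- 1
  x <- ifelse(tt <= tStar, s * tt, s * tStar + 2 * s * (tt - tStar))
  res <- computePthresh(x, samplingRate = fs, tPmax = 9.99, lookbackS = 8)
  expect_equal(res$tThresh, tStar)  # 0.5 < 0.65 so only the steep part passes
})

test_that("the threshold rule is invariant to pressure rescaling", {
  set.seed(101)
  for (i in 1:25) {
    x <- cumsum(rnorm(400))
    k <- runif(1, 0.01, 100)
    a <- computePthresh(x, samplingRate = 50, tPmax = 7.98, lookbackS = 5)
    b <- computePthresh(k * x, samplingRate = 50, tPmax = 7.98, lookbackS = 5)
    expect_identical(a$tThresh, b$tThresh)
    expect_identical(a$flagged, b$flagged)
  }
})

test_that("threshold detection matches the brute-force scan oracle", {
  set.seed(202)
  fs <- 100
  for (i in 1:200) {
    n <- sample(60:400, 1)
    x <- cumsum(rnorm(n))
    lookback <- sample(10:(n - 2), 1) / fs
    tPmax <- (n - 1) / fs
    res <- computePthresh(x, samplingRate = fs, tPmax = tPmax,
                          lookbackS = lookback)
    i1 <- n
    i0 <- n - as.integer(round(lookback * fs))
    oracle <- bruteThreshIndex(x, i0, i1)
    if (is.na(oracle)) {
      expect_true(res$flagged)
    } else {
      expect_equal(res$tThresh, (oracle - 1) / fs)
      expect_equal(res$pThresh, x[oracle])
    }
  }
})

test_that("a non-increasing window flags the cycle", {
  x <- seq(100, 0, length.out = 500)
  res <- computePthresh(x, samplingRate = 50, tPmax = 9.9, lookbackS = 5)
  expect_true(res$flagged)
  expect_true(is.na(res$tThresh))
})

test_that("filling volume follows rate x elapsed time", {
  expect_equal(computeFillingVolume(120, 0, 10), 20)
  expect_equal(computeFillingVolume(50, 50, 20), 0)
  set.seed(3)
  for (i in 1:50) {
    t0 <- runif(1, 0, 100); dt <- runif(1, 0, 500); r <- runif(1, 1, 30)
    expect_equal(computeFillingVolume(t0 + dt, t0, r), r / 60 * dt,
                 tolerance = 1e-9)
  }
  expect_error(computeFillingVolume(10, 20, 10), "precedes")
})

test_that("sham cycles are recovered with accurate peak times", {
  sim <- simulateRecording(simParams("sham", durationS = 900,
                                     noiseSd = lowNoiseSd, seed = 31))
  cyc <- detectCycles(sim$recording)
  expect_identical(nrow(cyc), 3L)
  expect_true(all(abs(cyc$tPmaxS - sim$truth@pmaxTimes) <= 0.2))
  expect_true(all(abs(cyc$tThreshS - sim$truth@threshTimes) <= 0.2))
})

test_that("no-cycle and flat recordings yield empty cycle lists", {
  sci <- simulateRecording(sciParams(7))
  expect_identical(nrow(detectCycles(sci$recording)), 0L)
  n <- 30000
  flat <- UDIRecording((0:(n - 1)) / 500, rnorm(n, 10, 0.05),
                       samplingRate = 500)
  expect_identical(nrow(detectCycles(flat)), 0L)
})

test_that("detected cycles satisfy the ordering invariants", {
  for (seed in 1:10) {
    sim <- simulateRecording(simParams("sham", durationS = 600,
                                       intercycleIntervalS = 200,
                                       noiseSd = lowNoiseSd, seed = seed))
    cyc <- detectCycles(sim$recording)
    expect_gt(nrow(cyc), 0)
    ok <- !cyc$flagged
    expect_true(all(cyc$startTimeS[ok] <= cyc$tThreshS[ok]))
    expect_true(all(cyc$tThreshS[ok] <= cyc$tPmaxS[ok]))
    expect_true(all(cyc$tPmaxS <= cyc$endTimeS))
    expect_true(all(cyc$tPmaxS[ok] - cyc$tThreshS[ok] <= 20))
    expect_true(all(cyc$pthreshCmH2O[ok] <= cyc$pmaxCmH2O[ok]))
    expect_true(all(cyc$vFillingUl[ok] >= 0))
  }
})

test_that("no-cycle normalization subtracts the recording minimum", {
  n <- 20000
  const <- UDIRecording((0:(n - 1)) / 500, rep(30, n), samplingRate = 500)
  res <- normalizeNoCycle(const)
  expect_equal(res$pressure, rep(0, n))
  expect_equal(res$pmaxCmH2O, 0)
  expect_identical(nrow(res$events), 0L)

  sci <- simulateRecording(sciParams(13))
  res <- normalizeNoCycle(sci$recording)
  expect_equal(min(res$pressure), 0)
  planted <- diff(sci$truth@pressureRange)
  expect_lt(abs(res$pmaxCmH2O - planted), 15 * lowNoiseSd)
  expect_gt(nrow(res$events), 0)
})

test_that("recording summaries average the first cycles only", {
  cyc <- data.frame(pmaxCmH2O = c(20, 22, 24), pthreshCmH2O = c(10, 11, 12),
                    vFillingUl = c(40, 50, 60), flagged = FALSE)
  expect_equal(summarizeRecording(cyc)$pmaxMean, 22)
  five <- data.frame(pmaxCmH2O = 1:5, pthreshCmH2O = 1:5,
                     vFillingUl = 1:5, flagged = FALSE)
  s <- summarizeRecording(five)
  expect_identical(s$nUsed, 3L)
  expect_equal(s$pmaxMean, 2)
  two <- five[1:2, ]
  expect_warning(s2 <- summarizeRecording(two), "fewer")
  expect_true(s2$fewerThanRequested)
  expect_equal(s2$pmaxMean, 1.5)
})
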