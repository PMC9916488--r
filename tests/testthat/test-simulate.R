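test_that("identical parameters produce bit-identical recordings", {
  p <- simParams("sham", durationS = 300, intercycleIntervalS = 100, seed = 11)
  a <- simulateRecording(p)
  b <- simulateRecording(p)
  expect_identical(a$recording@pressure, b$recording@pressure)
  expect_identical(a$recording@emg, b$recording@emg)
  expect_identical(a$recording@volume, b$recording@volume)
  expect_identical(a$truth@threshTimes, b$truth@threshTimes)
})

test_that("sample count equals duration times sampling rate", {
  p <- simParams("sham", durationS = 123, intercycleIntervalS = 60, seed = 1)
  sim <- simulateRecording(p)
  expect_identical(length(sim$recording@time), as.integer(123 * 500))
})

test_that("requested cycles are conserved and void trapping works", {
  base <- list(durationS = 300, intercycleIntervalS = 100, seed = 5)
  noTrap <- simulateRecording(do.call(simParams,
    c(list("sham", voidTrapProbability = 0), base)))
  expect_length(noTrap$truth@voidTimes, 3L)
  expect_length(noTrap$truth@recordedVoidVolumes, 3L)
  expect_false(any(noTrap$truth@trappedVoidFlags))

  allTrap <- simulateRecording(do.call(simParams,
    c(list("sham", voidTrapProbability = 1), base)))
  expect_length(allTrap$truth@recordedVoidVolumes, 0L)
  expect_true(all(allTrap$recording@volume == 0))
})

test_that("SCI recordings contract without voiding or baseline return", {
  sim <- simulateRecording(sciParams(3))
  expect_length(sim$truth@voidTimes, 0L)
  expect_gt(length(sim$truth@pmaxTimes), 0L)
  # after the first plateau crest, pressure never returns near baseline
  p <- simParams("SCI", durationS = 160, riseTimeS = 60, seed = 3)
  onset <- sim$truth@pmaxTimes[1]
  after <- sim$recording@pressure[sim$recording@time > onset]
  expect_gt(min(after), p@baselinePressure + p@noiseSd)
})

test_that("noiseless sham pressure equals the closed-form template", {
  T <- 100; W <- 5; b <- 8; s <- 0.01; A <- 12; fs <- 500
  p <- simParams("sham", durationS = 200, intercycleIntervalS = T,
                 contractionWidthS = W, baselinePressure = b,
                 complianceSlope = s, contractionAmplitude = A,
                 noiseSd = 0, emgPattern = "none",
                 voidTrapProbability = 0, seed = 1)
  sim <- simulateRecording(p)
  tt <- sim$recording@time
  # direct evaluation of the documented piecewise ramp + pulse template
  expected <- rep(b, length(tt))
  for (i in 1:2) {
    ci <- (i - 1) * T
    tPeak <- ci + T - W
    inC <- tt >= ci & tt < ci + T
    u <- tt - ci
    ramp <- numeric(length(tt))
    ramp[u <= T - W] <- s * u[u <= T - W]
    mid <- u > T - W & u <= T - W / 2
    ramp[mid] <- s * (T - W) * (1 - (u[mid] - (T - W)) / (W / 2))
    v <- tt - tPeak
    pulse <- ifelse(abs(v) <= W / 2, A / 2 * (1 + cos(2 * pi * v / W)), 0)
    expected[inC] <- b + ramp[inC] + pulse[inC]
  }
  expect_equal(sim$recording@pressure, expected, tolerance = 1e-12)
  expect_equal(sim$truth@pmaxTimes, c(95, 195))
})

test_that("ground-truth threshold precedes its peak in all phenotypes", {
  for (ph in c("sham", "SCI")) {
    p <- if (ph == "sham")
      simParams(ph, durationS = 300, intercycleIntervalS = 100, seed = 2)
    else sciParams(2)
    sim <- simulateRecording(p)
    expect_true(all(sim$truth@threshTimes < sim$truth@pmaxTimes))
  }
})

test_that("too-short recordings are rejected as degenerate", {
  expect_error(
    simulateRecording(simParams("sham", durationS = 50,
                                intercycleIntervalS = 100, seed = 1)),
    "no full cycle")
  expect_error(simParams("bogus"), "arg")
  expect_error(simParams("sham", emgPattern = "wiggly"), "emgPattern")
})

test_that("planted DEG-table overlaps are recovered exactly across seeds", {
  for (seed in 1:20) {
    sim <- simulateDegTables(100, nShared = 10, nConcordant = 5,
                             effectSizeSd = 3, seed = seed)
    fa <- do.call(filterDegs, c(list(sim$tableA), degPreset("sci_inclusion")))
    fb <- do.call(filterDegs, c(list(sim$tableB), degPreset("sci_inclusion")))
    gs <- intersectDegs(fa$passed, fb$passed)
    expect_setequal(sharedGenes(gs), sim$annotation$shared)
    expect_setequal(concordantGenes(gs), sim$annotation$concordant)
    expect_setequal(discordantGenes(gs), sim$annotation$discordant)
  }
})

test_that("zero planted overlap yields an empty intersection", {
  sim <- simulateDegTables(200, nShared = 0, nConcordant = 0, seed = 4)
  fa <- do.call(filterDegs, c(list(sim$tableA), degPreset("sci_inclusion")))
  fb <- do.call(filterDegs, c(list(sim$tableB), degPreset("sci_inclusion")))
  gs <- intersectDegs(fa$passed, fb$passed)
  expect_length(sharedGenes(gs), 0L)
})

test_that("inconsistent DEG planting counts are rejected", {
  expect_error(simulateDegTables(100, nShared = 5, nConcordant = 9, seed = 1),
               "nConcordant")
  expect_error(simulateDegTables(10, nShared = 20, nConcordant = 1, seed = 1),
               "exceed")
})
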