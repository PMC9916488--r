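test_that("the notch removes a mains sinusoid", {
  fs <- 5000
  tt <- (0:(2 * fs - 1)) / fs
  x <- sin(2 * pi * 50 * tt)
  y <- suppressWarnings(preprocessEmg(x, samplingRate = fs))
  core <- seq(fs * 0.2, length(tt) - fs * 0.2)
  expect_lt(max(abs(y[core])), 0.05)
})

test_that("zero signal stays zero and the band clips below Nyquist", {
  fs <- 5000
  expect_warning(y <- preprocessEmg(numeric(10000), samplingRate = fs),
                 "Nyquist")
  expect_equal(y, numeric(10000), ignore_attr = TRUE, tolerance = 1e-12)
  expect_lt(attr(y, "bandHz")[2], 2500)
  expect_equal(attr(y, "bandHz")[1], 10)
})

test_that("stationary noise splits energy roughly evenly across sections", {
  set.seed(21)
  fs <- 2000
  x <- as.numeric(signal::filtfilt(signal::butter(4, c(50, 450) / (fs / 2),
                                                  "pass"), rnorm(4 * fs)))
  hs <- hilbertHuang(x, fs)
  se <- sectionEnergies(hs, 0.5, 3.5)
  pct <- sectionPercentages(se)
  expect_true(all(abs(pct - 100 / 3) < 5))
  expect_equal(sum(pct), 100, tolerance = 1e-6)
})

test_that("a planted v-shape envelope makes the during section the minimum", {
  set.seed(22)
  fs <- 2000
  n <- 4 * fs
  carrier <- as.numeric(signal::filtfilt(
    signal::butter(4, c(50, 450) / (fs / 2), "pass"), rnorm(n)))
  tt <- (0:(n - 1)) / fs
  t0 <- 0.5; t1 <- 3.5
  env <- rep(1, n)
  mid <- tt >= t0 + 2 / 5 * (t1 - t0) & tt < t0 + 3 / 5 * (t1 - t0)
  env[mid] <- 0.2
  hs <- hilbertHuang(env * carrier, fs)
  se <- sectionEnergies(hs, t0, t1)
  pct <- sectionPercentages(se)
  expect_lt(pct["during"], pct["before"])
  expect_lt(pct["during"], pct["after"])
  expect_true(classifyVshape(se))
})

test_that("section percentages are invariant to amplitude scaling", {
  set.seed(23)
  fs <- 2000
  x <- as.numeric(signal::filtfilt(signal::butter(4, c(50, 450) / (fs / 2),
                                                  "pass"), rnorm(2 * fs)))
  a <- sectionEnergies(hilbertHuang(x, fs), 0.2, 1.8)
  b <- sectionEnergies(hilbertHuang(2 * x, fs), 0.2, 1.8)
  expect_equal(sectionPercentages(a), sectionPercentages(b),
               tolerance = 1e-9)
  expect_equal(sectionEnergyValues(b), 4 * sectionEnergyValues(a),
               tolerance = 1e-9)
})

test_that("zero-energy contractions are flagged and percentages undefined", {
  fs <- 2000
  hs <- hilbertHuang(c(numeric(fs)), fs)
  se <- sectionEnergies(hs, 0.1, 0.9)
  expect_true(se@flagged)
  expect_false(classifyVshape(se))
})

test_that("v-shape means strictly lowest during-voiding energy", {
  expect_true(classifyVshape(makeSection(40, 20, 40)))
  expect_false(classifyVshape(makeSection(30, 40, 30)))
  expect_false(classifyVshape(makeSection(30, 30, 40)))  # tie is not lowest
  # exhaustive 3-way comparison over a grid of compositions
  grid <- seq(10, 80, by = 10)
  for (b in grid) for (d in grid) for (a in grid) {
    expect_identical(classifyVshape(makeSection(b, d, a)),
                     d < b && d < a)
  }
})

test_that("v-shape percentage applies the exclusion rule", {
  vs <- replicate(5, makeSection(40, 10, 50), simplify = FALSE)
  nv <- replicate(2, makeSection(20, 50, 30), simplify = FALSE)
  res <- vshapePercentage(c(vs, nv))
  expect_equal(res$percentage, 71)   # 5 of 7
  expect_false(res$excluded)

  few <- vshapePercentage(c(vs[1:2], nv))  # 4 analyzable
  expect_true(few$excluded)
  expect_true(is.na(few$percentage))

  ten <- c(replicate(2, makeSection(40, 10, 50), simplify = FALSE),
           replicate(8, makeSection(20, 50, 30), simplify = FALSE))
  expect_equal(vshapePercentage(ten)$percentage, 20)  # 2 of 10

  # contractions outside the 10-min window do not count
  late <- replicate(3, makeSection(40, 10, 50, startS = 700, endS = 701),
                    simplify = FALSE)
  res <- vshapePercentage(c(vs, late))
  expect_identical(res$nAnalyzable, 5L)
})

test_that("mean activity pattern averages percentages then classifies", {
  two <- list(makeSection(40, 20, 40), makeSection(20, 40, 40))
  m <- meanActivityPattern(two)
  expect_equal(unname(m$pctMean), c(30, 30, 40))
  expect_false(m$meanVshape)

  same <- replicate(3, makeSection(45, 10, 45), simplify = FALSE)
  expect_true(meanActivityPattern(same)$meanVshape)

  set.seed(30)
  rnd <- replicate(6, {
    e <- runif(3, 1, 10)
    makeSection(e[1], e[2], e[3])
  }, simplify = FALSE)
  m <- meanActivityPattern(rnd)
  byHand <- rowMeans(vapply(rnd, sectionPercentages, numeric(3)))
  expect_equal(m$pctMean, byHand, tolerance = 1e-9)
})

test_that("planted EMG patterns are recovered through the full pipeline", {
  # v-shape on one sham recording in the EMG acquisition arm
  sim <- simulateRecording(shamEmgParams(41))
  cyc <- detectCycles(sim$recording)
  se <- suppressWarnings(analyzeEmgContractions(sim$recording, cyc))
  expect_gt(length(se), 0)
  expect_true(all(vapply(se, classifyVshape, logical(1))))
  # dyssynergic on one SCI recording
  sci <- simulateRecording(sciParams(42))
  ev <- normalizeNoCycle(sci$recording)$events
  se2 <- suppressWarnings(analyzeEmgContractions(sci$recording, ev))
  expect_gt(length(se2), 0)
  expect_true(all(!vapply(se2, classifyVshape, logical(1))))
})
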