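test_that("DEG filtering reports counts and two-significant-digit fractions", {
  tbl <- simulateDegTable(21751, nUp = 174, nDown = 151, seed = 17)
  res <- do.call(filterDegs, c(list(tbl), degPreset("sci_inclusion")))
  expect_equal(res$nUp, 174)
  expect_equal(res$nDown, 151)
  expect_equal(res$nNonzero, 21751)
  expect_equal(res$fractionUpPct, 0.8)
  expect_equal(res$fractionDownPct, 0.69)
})

test_that("an empty pass-set yields zero fractions", {
  tbl <- data.frame(geneId = c("a", "b"), log2fc = c(0.1, -0.1),
                    pvalue = c(0.9, 0.8), padj = c(0.95, 0.9),
                    meanCount = c(10, 20))
  res <- filterDegs(tbl, padjThresh = 0.1)
  expect_equal(res$nUp + res$nDown, 0)
  expect_equal(res$fractionUpPct, 0)
  expect_equal(res$fractionDownPct, 0)
})

test_that("filtering is monotone in every threshold", {
  set.seed(50)
  for (i in 1:10) {
    n <- 500
    tbl <- data.frame(geneId = sprintf("g%03d", 1:n),
                      log2fc = rnorm(n, 0, 1.5),
                      pvalue = runif(n), padj = runif(n),
                      meanCount = rlnorm(n, 3, 1))
    loose <- filterDegs(tbl, padjThresh = 0.3, minAbsLog2fc = 0.2,
                        minMeanCount = 5)
    tightFc <- filterDegs(tbl, padjThresh = 0.3, minAbsLog2fc = 0.8,
                          minMeanCount = 5)
    tightP <- filterDegs(tbl, padjThresh = 0.05, minAbsLog2fc = 0.2,
                         minMeanCount = 5)
    tightCount <- filterDegs(tbl, padjThresh = 0.3, minAbsLog2fc = 0.2,
                             minMeanCount = 50)
    for (tight in list(tightFc, tightP, tightCount)) {
      expect_lte(tight$nUp, loose$nUp)
      expect_lte(tight$nDown, loose$nDown)
      expect_true(all(tight$passed$geneId %in% loose$passed$geneId))
    }
    # fractions equal count / total at 2 significant digits
    expect_equal(loose$fractionUpPct, signif(100 * loose$nUp / n, 2))
  }
})

test_that("exactly one significance criterion must be chosen", {
  tbl <- data.frame(geneId = "a", log2fc = 1, pvalue = 0.01, padj = 0.02,
                    meanCount = 10)
  expect_error(filterDegs(tbl), "exactly one")
  expect_error(filterDegs(tbl, pThresh = 0.1, padjThresh = 0.1),
               "exactly one")
  expect_error(filterDegs(tbl, pThresh = 1.5), "pThresh")
})

test_that("intersections partition shared genes by fold-change sign", {
  a <- data.frame(geneId = c("g1", "g2", "g3"), log2fc = c(1, -2, 0.5))
  b <- data.frame(geneId = c("g2", "g3", "g4"), log2fc = c(2, 1, -1))
  gs <- intersectDegs(a, b)
  expect_setequal(sharedGenes(gs), c("g2", "g3"))
  expect_setequal(concordantGenes(gs), "g3")
  expect_setequal(discordantGenes(gs), "g2")
  expect_setequal(uniqueGenes(gs, "A"), "g1")
  expect_setequal(uniqueGenes(gs, "B"), "g4")

  disjoint <- intersectDegs(a, data.frame(geneId = "x1", log2fc = 1))
  expect_length(sharedGenes(disjoint), 0L)

  dup <- data.frame(geneId = c("g1", "g1"), log2fc = c(1, 2))
  expect_error(intersectDegs(dup, b), "duplicate")

  zero <- data.frame(geneId = "g2", log2fc = 0)
  expect_warning(gz <- intersectDegs(zero, b), "zero log2")
  expect_setequal(discordantGenes(gz), "g2")
})

test_that("keyword counts match a brute-force nested loop", {
  terms <- c("muscle contraction", "B cell activation")
  expect_equal(keywordTermCounts(terms, c("muscle", "B cell")),
               c(muscle = 1L, `B cell` = 1L))
  expect_length(keywordTermCounts(terms, character(0)), 0L)
  set.seed(51)
  vocab <- c("muscle", "immune", "calcium", "neuron", "matrix", "growth")
  for (i in 1:10) {
    trm <- replicate(30, paste(sample(vocab, sample(1:3, 1)), collapse = " "))
    kw <- sample(vocab, 4)
    fast <- keywordTermCounts(trm, kw)
    slow <- integer(length(kw))
    for (ki in seq_along(kw)) {
      for (t in trm) {
        if (grepl(tolower(kw[ki]), tolower(t), fixed = TRUE))
          slow[ki] <- slow[ki] + 1L
      }
    }
    expect_equal(unname(fast), slow)
  }
})

test_that("delta-delta-Ct fold changes follow the definition", {
  expect_equal(qpcrLog2fc(20, 10, 21, 10), 1)   # ddCt = -1 -> +1
  expect_equal(qpcrLog2fc(c(20, 21), c(10, 11), c(20, 21), c(10, 11)), 0)
  set.seed(52)
  for (i in 1:20) {
    tc <- runif(5, 18, 30); rc <- runif(5, 9, 12)
    tk <- runif(6, 18, 30); rk <- runif(6, 9, 12)
    expect_equal(qpcrLog2fc(tc, rc, tk, rk),
                 -((mean(tc) - mean(rc)) - (mean(tk) - mean(rk))))
  }
  expect_error(qpcrLog2fc(NA, 10, 20, 10), "finite")
})
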