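#' Simulate one DEG table with planted significant genes
#'
#' Builds a full differential-expression table of `nGenes` genes with
#' `nUp` planted upregulated and `nDown` planted downregulated genes. The
#' planted genes pass all shipped significance presets (adjusted p < 0.05,
#' |log2FC| > 0.5, mean count > 50); null genes have uniform p-values on
#' (0, 1), adjusted p-values >= 0.2 and small fold changes. All genes have
#' nonzero mean counts.
#'
#' @param nGenes total genes.
#' @param nUp,nDown planted up-/downregulated counts (`nUp + nDown <=
#'   nGenes`).
#' @param effectSizeSd SD of the planted |log2FC| excess over 0.6.
#' @param seed RNG seed.
#' @return data.frame with columns `geneId`, `log2fc`, `pvalue`, `padj`,
#'   `meanCount` and attribute `"planted"` (list of `up` and `down` ids).
#' @examples
#' tbl <- simulateDegTable(21751, nUp = 174, nDown = 151, seed = 1)
#' res <- do.call(filterDegs, c(list(tbl), degPreset("sci_inclusion")))
#' c(res$fractionUpPct, res$fractionDownPct)  # 0.8, 0.69
#' @export
simulateDegTable <- function(nGenes, nUp, nDown, effectSizeSd = 2,
                             seed = 1L) {
  if (nUp + nDown > nGenes) stop("nUp + nDown must not exceed nGenes")
  set.seed(as.integer(seed))
  ids <- sprintf("gene%06d", seq_len(nGenes))
  log2fc <- rnorm(nGenes, 0, 0.15)
  pvalue <- runif(nGenes)
  padj <- runif(nGenes, 0.2, 1)
  meanCount <- rlnorm(nGenes, meanlog = 4, sdlog = 1.5) + 1
  sig <- seq_len(nUp + nDown)
  signs <- c(rep(1, nUp), rep(-1, nDown))
  log2fc[sig] <- signs * (0.6 + abs(rnorm(nUp + nDown, 0, effectSizeSd)))
  padj[sig] <- runif(nUp + nDown, 1e-8, 0.04)
  pvalue[sig] <- padj[sig] / 2
  meanCount[sig] <- 60 + rlnorm(nUp + nDown, meanlog = 4, sdlog = 1)
  out <- data.frame(geneId = ids, log2fc = log2fc, pvalue = pvalue,
                    padj = padj, meanCount = meanCount,
                    stringsAsFactors = FALSE)
  attr(out, "planted") <- list(up = ids[sig[signs > 0]],
                               down = ids[sig[signs < 0]])
  out
}

#' Simulate a pair of DEG tables with controlled overlap
#'
#' Builds two full DEG tables whose truly shared significant genes number
#' `nShared`, of which exactly `nConcordant` have the same fold-change sign
#' in both conditions and the remainder opposite signs. Optionally plants
#' genes significant in only one condition. Null genes have uniform p-values
#' on (0, 1) and adjusted p-values >= 0.2, so filtering either table at
#' adjusted p < 0.1 recovers exactly the planted sets.
#'
#' @param nGenes total genes per table (`nShared + nUniqueA + nUniqueB <=
#'   nGenes`, `nConcordant <= nShared`).
#' @param nShared planted shared significant genes.
#' @param nConcordant planted sign-concordant shared genes.
#' @param effectSizeSd SD of the planted |log2FC| excess over 0.6.
#' @param nUniqueA,nUniqueB genes significant only in table A / B.
#' @param seed RNG seed.
#' @return A list: `tableA`, `tableB` (DEG data.frames) and `annotation`
#'   with the planted id sets (`shared`, `concordant`, `discordant`,
#'   `uniqueA`, `uniqueB`).
#' @examples
#' sim <- simulateDegTables(2000, nShared = 59, nConcordant = 46, seed = 1)
#' degA <- do.call(filterDegs, c(list(sim$tableA), degPreset("sci_inclusion")))
#' degB <- do.call(filterDegs, c(list(sim$tableB), degPreset("sci_inclusion")))
#' gs <- intersectDegs(degA$passed, degB$passed)
#' length(sharedGenes(gs))  # 59
#' @export
simulateDegTables <- function(nGenes, nShared, nConcordant,
                              effectSizeSd = 2, nUniqueA = 0L,
                              nUniqueB = 0L, seed = 1L) {
  if (nConcordant > nShared)
    stop("nConcordant must not exceed nShared")
  if (nShared + nUniqueA + nUniqueB > nGenes)
    stop("planted genes exceed nGenes")
  set.seed(as.integer(seed))
  ids <- sprintf("gene%06d", seq_len(nGenes))

  nullTable <- function() {
    data.frame(geneId = ids,
               log2fc = rnorm(nGenes, 0, 0.15),
               pvalue = runif(nGenes),
               padj = runif(nGenes, 0.2, 1),
               meanCount = rlnorm(nGenes, meanlog = 4, sdlog = 1.5) + 1,
               stringsAsFactors = FALSE)
  }
  plant <- function(tbl, idx, signs) {
    k <- length(idx)
    tbl$log2fc[idx] <- signs * (0.6 + abs(rnorm(k, 0, effectSizeSd)))
    tbl$padj[idx] <- runif(k, 1e-8, 0.04)
    tbl$pvalue[idx] <- tbl$padj[idx] / 2
    tbl$meanCount[idx] <- 60 + rlnorm(k, meanlog = 4, sdlog = 1)
    tbl
  }
  a <- nullTable()
  b <- nullTable()
  iShared <- seq_len(nShared)
  iA <- seq(nShared + 1L, length.out = nUniqueA)
  iB <- seq(nShared + nUniqueA + 1L, length.out = nUniqueB)
  signsA <- sample(c(-1, 1), nShared, replace = TRUE)
  conc <- seq_len(nConcordant)
  signsB <- -signsA
  signsB[conc] <- signsA[conc]
  a <- plant(a, iShared, signsA)
  b <- plant(b, iShared, signsB)
  if (nUniqueA) a <- plant(a, iA, sample(c(-1, 1), nUniqueA, replace = TRUE))
  if (nUniqueB) b <- plant(b, iB, sample(c(-1, 1), nUniqueB, replace = TRUE))
  list(tableA = a, tableB = b,
       annotation = list(shared = ids[iShared],
                         concordant = ids[iShared[conc]],
                         discordant = ids[setdiff(iShared, iShared[conc])],
                         uniqueA = ids[iA], uniqueB = ids[iB]))
}
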