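#' Significance presets for DEG filtering
#'
#' Named threshold presets: `"pboo_inclusion"` (raw p < 0.1),
#' `"sci_inclusion"` (adjusted p < 0.1) and `"volcano_strict"` (adjusted
#' p < 0.05, |log2FC| > 0.5, mean count > 50). The presets are kept distinct
#' rather than reconciled; pass the result to [filterDegs()] with
#' `do.call`.
#'
#' @param name preset name.
#' @return A list of [filterDegs()] arguments.
#' @examples
#' degPreset("volcano_strict")
#' @export
degPreset <- function(name = c("pboo_inclusion", "sci_inclusion",
                               "volcano_strict")) {
  name <- match.arg(name)
  switch(name,
    pboo_inclusion = list(pThresh = 0.1),
    sci_inclusion = list(padjThresh = 0.1),
    volcano_strict = list(padjThresh = 0.05, minAbsLog2fc = 0.5,
                          minMeanCount = 50))
}

.checkDegTable <- function(table) {
  need <- c("geneId", "log2fc", "pvalue", "padj", "meanCount")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("DEG table lacks columns: ", paste(miss, collapse = ", "))
  invisible(table)
}

#' Threshold filtering of a DEG table
#'
#' A gene passes when its chosen p-statistic (raw `pvalue` with `pThresh`,
#' or `padj` with `padjThresh` -- exactly one of the two) is below the
#' threshold, its |log2 fold change| exceeds `minAbsLog2fc`, and its mean
#' read count is at least `minMeanCount`. Up/down lists split by the sign of
#' the fold change. Fractions of up-/downregulated genes are computed over
#' the genes with nonzero mean counts and reported to two significant digits
#' (e.g. 174/21751 -> 0.8, 151/21751 -> 0.69).
#'
#' @param table data.frame with columns `geneId`, `log2fc`, `pvalue`,
#'   `padj`, `meanCount`.
#' @param pThresh raw p-value threshold (exclusive), or `NULL`.
#' @param padjThresh adjusted p-value threshold (exclusive), or `NULL`.
#' @param minAbsLog2fc minimal |log2FC| (exclusive; default 0).
#' @param minMeanCount minimal mean read count (inclusive; default 0).
#' @return A list: `up` and `down` (gene id vectors), `nUp`, `nDown`,
#'   `fractionUpPct`, `fractionDownPct` (percentages of nonzero-count
#'   genes), `nNonzero`, and `passed` (the filtered sub-table).
#' @examples
#' tbl <- simulateDegTable(1000, nUp = 20, nDown = 10, seed = 1)
#' res <- do.call(filterDegs, c(list(tbl), degPreset("sci_inclusion")))
#' res$nUp
#' @export
filterDegs <- function(table, pThresh = NULL, padjThresh = NULL,
                       minAbsLog2fc = 0, minMeanCount = 0) {
  .checkDegTable(table)
  if (!nrow(table)) stop("empty DEG table")
  if (is.null(pThresh) == is.null(padjThresh))
    stop("supply exactly one of pThresh or padjThresh")
  if (!is.null(pThresh) && (pThresh <= 0 || pThresh > 1))
    stop("pThresh must lie in (0, 1]")
  if (!is.null(padjThresh) && (padjThresh <= 0 || padjThresh > 1))
    stop("padjThresh must lie in (0, 1]")
  stat <- if (is.null(pThresh)) table$padj else table$pvalue
  thr <- if (is.null(pThresh)) padjThresh else pThresh
  pass <- stat < thr & abs(table$log2fc) > minAbsLog2fc &
    table$meanCount >= minMeanCount
  pass[is.na(pass)] <- FALSE
  sub <- table[pass, , drop = FALSE]
  nNonzero <- sum(table$meanCount > 0)
  up <- sub$geneId[sub$log2fc > 0]
  down <- sub$geneId[sub$log2fc < 0]
  frac <- function(n) if (nNonzero > 0) signif(100 * n / nNonzero, 2) else 0
  list(up = up, down = down, nUp = length(up), nDown = length(down),
       fractionUpPct = frac(length(up)),
       fractionDownPct = frac(length(down)),
       nNonzero = nNonzero, passed = sub)
}

#' Intersect two DEG tables with sign-concordance partitioning
#'
#' Set intersection on gene identifiers of two (already filtered) DEG
#' tables. Shared genes are concordant when the product of their log2 fold
#' changes is positive, discordant when negative; a zero fold change is
#' classified discordant with a warning.
#'
#' @param degsA,degsB data.frames with columns `geneId` and `log2fc`
#'   (duplicate gene ids within a table are an error).
#' @return A [SharedGeneSet-class].
#' @examples
#' a <- data.frame(geneId = c("g1", "g2"), log2fc = c(1, -2))
#' b <- data.frame(geneId = c("g2", "g3"), log2fc = c(2, 1))
#' sharedGenes(intersectDegs(a, b))  # "g2" (discordant)
#' @export
intersectDegs <- function(degsA, degsB) {
  for (d in list(degsA, degsB)) {
    if (!all(c("geneId", "log2fc") %in% names(d)))
      stop("DEG tables need geneId and log2fc columns")
    if (anyDuplicated(d$geneId))
      stop("duplicate gene ids within one table")
  }
  shared <- intersect(degsA$geneId, degsB$geneId)
  fa <- degsA$log2fc[match(shared, degsA$geneId)]
  fb <- degsB$log2fc[match(shared, degsB$geneId)]
  prod <- sign(fa) * sign(fb)
  if (any(prod == 0) && length(shared))
    warning("zero log2 fold change among shared genes; classified discordant")
  new("SharedGeneSet",
      shared = shared,
      concordant = shared[prod > 0],
      discordant = shared[prod <= 0],
      uniqueA = setdiff(degsA$geneId, shared),
      uniqueB = setdiff(degsB$geneId, shared))
}

#' Count enrichment terms matching keywords
#'
#' Case-insensitive substring matching of keywords against enrichment-term
#' names (radar-plot arms); a term may count toward several keywords.
#'
#' @param termNames character vector of enriched-term names.
#' @param keywords character vector of keywords.
#' @return Named integer vector of counts, one per keyword.
#' @examples
#' keywordTermCounts(c("muscle contraction", "B cell activation"),
#'                   c("muscle", "B cell"))
#' @export
keywordTermCounts <- function(termNames, keywords) {
  lowTerms <- tolower(termNames)
  vapply(setNames(keywords, keywords), function(k)
    sum(grepl(tolower(k), lowTerms, fixed = TRUE)), integer(1))
}

#' qPCR log2 fold change by the delta-delta-Ct method
#'
#' Target Ct values are normalized to the reference gene (18S-style) within
#' replicate, averaged per group, and the log2 fold change is the negated
#' difference of the group means (amplification efficiency 2):
#' `log2FC = -[(mean dCt case) - (mean dCt control)]`.
#'
#' @param ctTargetCase,ctRefCase paired target/reference Ct replicates in
#'   the case group.
#' @param ctTargetCtrl,ctRefCtrl paired replicates in the control group.
#' @return log2 fold change (numeric(1)).
#' @examples
#' qpcrLog2fc(20, 10, 21, 10)  # ddCt = -1 -> log2FC = +1
#' @export
qpcrLog2fc <- function(ctTargetCase, ctRefCase, ctTargetCtrl, ctRefCtrl) {
  if (length(ctTargetCase) != length(ctRefCase) ||
      length(ctTargetCtrl) != length(ctRefCtrl))
    stop("target and reference replicates must be paired within group")
  allCt <- c(ctTargetCase, ctRefCase, ctTargetCtrl, ctRefCtrl)
  if (any(!is.finite(allCt))) stop("all Ct values must be finite")
  dCase <- mean(ctTargetCase - ctRefCase)
  dCtrl <- mean(ctTargetCtrl - ctRefCtrl)
  -(dCase - dCtrl)
}
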