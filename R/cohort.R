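#' Bladder-to-bodyweight ratio
#'
#' Bladder weight divided by the mean of the animal's bodyweight measured on
#' the last three consecutive days.
#'
#' @param bladderWeightMg bladder weight in mg (>= 0).
#' @param bodyweightsG exactly three daily bodyweights in g (all > 0).
#' @return Ratio in mg/g.
#' @examples
#' bladderBodyweightRatio(30, c(20, 20, 20))  # 1.5
#' @export
bladderBodyweightRatio <- function(bladderWeightMg, bodyweightsG) {
  if (length(bodyweightsG) != 3L)
    stop("exactly three consecutive daily bodyweights are required")
  if (any(!is.finite(bodyweightsG)) || any(bodyweightsG <= 0))
    stop("bodyweights must be positive")
  if (!is.finite(bladderWeightMg) || bladderWeightMg < 0)
    stop("bladder weight must be non-negative")
  bladderWeightMg / mean(bodyweightsG)
}

#' Per-group, per-week summary of an animal-level metric
#'
#' Computes n, mean and sample (n-1) standard deviation of `metric` for each
#' (group, week) cell, the form in which cohort tables report mean +/- SD.
#' Cells with a single animal report SD 0 and are flagged.
#'
#' @param records data.frame with columns `group`, `week` and the metric.
#' @param metric name of the metric column.
#' @return data.frame with columns `group`, `week`, `n`, `mean`, `sd`,
#'   `singleAnimal`.
#' @examples
#' df <- data.frame(group = "sham", week = 0, pmax = c(10, 20, 30))
#' groupSummary(df, "pmax")  # mean 20, sd 10
#' @export
groupSummary <- function(records, metric) {
  stopifnot(metric %in% names(records))
  cells <- split(records,
                 interaction(records$group, records$week, drop = TRUE))
  rows <- lapply(cells, function(d) {
    v <- d[[metric]]
    v <- v[is.finite(v)]
    n <- length(v)
    data.frame(group = d$group[1], week = d$week[1], n = n,
               mean = mean(v), sd = if (n > 1L) sd(v) else 0,
               singleAnimal = n == 1L)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$group, out$week), , drop = FALSE]
}

#' Bonferroni adjustment by multiplication
#'
#' Raw p-values multiplied by the number of comparisons and capped at 1.
#'
#' @param p raw p-values.
#' @param nComparisons number of post-hoc comparisons.
#' @return Adjusted p-values.
#' @examples
#' bonferroniAdjust(0.04, 3)  # 0.12
#' @export
bonferroniAdjust <- function(p, nComparisons) pmin(1, p * nComparisons)

#' Group comparisons: cross-sectional t-tests and repeated-measures ANOVA
#'
#' For `type = "between"`, a two-sample unpaired t-test (Welch by default)
#' compares two groups at each requested week. For `type = "within"`, a
#' one-way repeated-measures ANOVA (subject as error stratum) tests the week
#' effect inside one group, followed by Bonferroni-multiplied pairwise
#' paired t-tests between weeks. Animals with missing cells are dropped
#' listwise from the repeated-measures analysis with a warning.
#'
#' @param records data.frame with columns `animalId`, `group`, `week` and
#'   the metric.
#' @param metric metric column name.
#' @param type "between" or "within".
#' @param groups for "between": the two group labels to contrast.
#' @param weeks weeks to include (default: all weeks present).
#' @param group for "within": the group to analyze.
#' @param welch use the Welch correction for t-tests (default TRUE).
#' @return For "between": data.frame `week`, `contrast`, `statistic`, `df`,
#'   `pValue`. For "within": list with `anova` (data.frame `effect`, `df1`,
#'   `df2`, `F`, `pValue`) and `posthoc` (data.frame `weekA`, `weekB`,
#'   `pRaw`, `pBonferroni`).
#' @export
compareGroups <- function(records, metric, type = c("between", "within"),
                          groups = NULL, weeks = NULL, group = NULL,
                          welch = TRUE) {
  type <- match.arg(type)
  stopifnot(metric %in% names(records))
  if (type == "between") {
    if (is.null(groups) || length(groups) != 2L)
      stop("supply the two group labels to contrast")
    if (is.null(weeks)) weeks <- sort(unique(records$week))
    rows <- lapply(weeks, function(w) {
      a <- records[records$group == groups[1] & records$week == w, metric]
      b <- records[records$group == groups[2] & records$week == w, metric]
      a <- a[is.finite(a)]; b <- b[is.finite(b)]
      if (length(a) < 2L || length(b) < 2L) return(NULL)
      tt <- t.test(a, b, var.equal = !welch)
      data.frame(week = w,
                 contrast = paste(groups[1], "vs", groups[2]),
                 statistic = unname(tt$statistic), df = unname(tt$parameter),
                 pValue = tt$p.value)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
      stop("no week with at least two animals per group")
    rownames(out) <- NULL
    return(out)
  }
  # within-group repeated measures
  if (is.null(group)) stop("supply the group to analyze")
  d <- records[records$group == group, c("animalId", "week", metric)]
  names(d)[3] <- "value"
  d <- d[is.finite(d$value), , drop = FALSE]
  if (is.null(weeks)) weeks <- sort(unique(d$week))
  d <- d[d$week %in% weeks, , drop = FALSE]
  counts <- table(d$animalId)
  complete <- names(counts)[counts == length(weeks)]
  if (length(complete) < length(unique(d$animalId)))
    warning("unbalanced design: ",
            length(unique(d$animalId)) - length(complete),
            " animal(s) with missing weeks dropped listwise")
  d <- d[d$animalId %in% complete, , drop = FALSE]
  if (length(complete) < 2L || length(weeks) < 2L)
    stop("repeated-measures ANOVA needs >= 2 complete animals and >= 2 weeks")
  d$week <- factor(d$week)
  d$animalId <- factor(d$animalId)
  fit <- aov(value ~ week + Error(animalId), data = d)
  tab <- summary(fit)[["Error: Within"]][[1]]
  anovaRow <- data.frame(effect = "week",
                         df1 = tab["week", "Df"],
                         df2 = tab["Residuals", "Df"],
                         F = tab["week", "F value"],
                         pValue = tab["week", "Pr(>F)"])
  pairs <- utils::combn(levels(d$week), 2, simplify = FALSE)
  ph <- lapply(pairs, function(pr) {
    a <- d$value[d$week == pr[1]][order(d$animalId[d$week == pr[1]])]
    b <- d$value[d$week == pr[2]][order(d$animalId[d$week == pr[2]])]
    p <- t.test(a, b, paired = TRUE)$p.value
    data.frame(weekA = pr[1], weekB = pr[2], pRaw = p,
               pBonferroni = bonferroniAdjust(p, length(pairs)))
  })
  posthoc <- do.call(rbind, ph)
  rownames(posthoc) <- NULL
  list(anova = anovaRow, posthoc = posthoc)
}

#' Integer percentage of animals
#'
#' `round(100 x count / total)` with half-up rounding, the convention used
#' when reporting "x out of n animals (p%)".
#'
#' @param count number of animals with the feature (0 <= count <= total).
#' @param total total number of animals (> 0).
#' @return Integer percentage.
#' @examples
#' percentOfAnimals(5, 7)   # 71
#' percentOfAnimals(11, 17) # 65
#' @export
percentOfAnimals <- function(count, total) {
  if (any(total <= 0)) stop("total must be positive")
  if (any(count < 0) || any(count > total))
    stop("count must lie in [0, total]")
  .roundHalfUp(100 * count / total)
}
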