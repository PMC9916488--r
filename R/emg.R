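#' Band-pass and notch filtering of the EUS-EMG channel
#'
#' Zero-phase (forward-backward Butterworth) band-pass filtering between 10
#' and 10,000 Hz, with the upper edge clipped below Nyquist when the sampling
#' rate cannot support it, followed by a mains notch filter (50 Hz default).
#' Output length equals input length.
#'
#' @param recording a [UDIRecording-class] with an EMG channel, or a bare
#'   numeric EMG series (then `samplingRate` is required).
#' @param bandHz band-pass edges in Hz (default `c(10, 10000)`).
#' @param notchHz mains frequency to suppress; 0 disables (default 50).
#' @param notchHalfWidthHz half-width of the notch stop band (default 2 Hz).
#' @param samplingRate required for bare numeric input.
#' @return Filtered numeric series with attribute `"bandHz"` giving the
#'   effective band after any Nyquist clipping.
#' @examples
#' fs <- 5000
#' x <- rnorm(fs)
#' y <- preprocessEmg(x, samplingRate = fs)
#' attr(y, "bandHz")  # upper edge clipped below 2500
#' @export
preprocessEmg <- function(recording, bandHz = c(10, 10000), notchHz = 50,
                          notchHalfWidthHz = 2, samplingRate = NULL) {
  if (is(recording, "UDIRecording")) {
    if (!hasEmg(recording)) stop("recording has no EMG channel")
    x <- recording@emg
    fs <- recording@samplingRate
  } else {
    x <- as.numeric(recording)
    if (is.null(samplingRate))
      stop("samplingRate required for a bare numeric series")
    fs <- samplingRate
  }
  nyq <- fs / 2
  band <- bandHz
  if (band[2] >= nyq) {
    band[2] <- 0.9 * nyq
    warning("band upper edge at or above Nyquist (", nyq,
            " Hz); clipped to ", band[2], " Hz")
  }
  if (band[1] <= 0 || band[1] >= band[2])
    stop("invalid band after clipping")
  bf <- signal::butter(4, band / nyq, type = "pass")
  y <- signal::filtfilt(bf, x)
  if (notchHz > 0) {
    edges <- c(notchHz - notchHalfWidthHz, notchHz + notchHalfWidthHz) / nyq
    if (edges[1] > 0 && edges[2] < 1) {
      nf <- signal::butter(2, edges, type = "stop")
      y <- signal::filtfilt(nf, y)
    }
  }
  attr(y, "bandHz") <- band
  y
}

#' Before/during/after-voiding EMG section energies
#'
#' Partitions the threshold-to-peak interval of one contraction into
#' `nParts` (default 5) equal parts: the middle part is "during voiding",
#' the parts before it "before voiding" and the parts after it "after
#' voiding". The energy of a section is the sum over IMFs and in-section
#' samples of the squared instantaneous amplitude, restricted to samples
#' whose instantaneous frequency lies in `bandHz` (0-500 Hz default),
#' divided by the section duration in seconds. Percentages are computed over
#' the three duration-normalized energies and sum to 100; a contraction with
#' zero total in-band energy is flagged and excluded from summaries.
#'
#' @param spectrum a [HilbertSpectrum-class] covering the contraction.
#' @param tThreshS,tPmaxS threshold and peak times (s) bounding the
#'   partition; `tThreshS < tPmaxS`.
#' @param nParts odd number of parts (default 5).
#' @param bandHz analysis frequency band in Hz (default `c(0, 500)`).
#' @return A [SectionEnergies-class].
#' @export
sectionEnergies <- function(spectrum, tThreshS, tPmaxS, nParts = 5,
                            bandHz = c(0, 500)) {
  stopifnot(is(spectrum, "HilbertSpectrum"))
  if (!tThreshS < tPmaxS) stop("tThreshS must precede tPmaxS")
  if (nParts %% 2L != 1L || nParts < 3L)
    stop("nParts must be an odd number >= 3")
  edges <- seq(tThreshS, tPmaxS, length.out = nParts + 1L)
  tt <- spectrum@time
  halfSample <- 0.5 / spectrum@samplingRate
  if (tt[1] > tThreshS + halfSample || tt[length(tt)] < tPmaxS - halfSample)
    stop("spectrum does not cover the threshold-to-peak partition")
  amp <- spectrum@instAmplitude
  freq <- spectrum@instFrequency
  inBand <- freq >= bandHz[1] & freq <= bandHz[2]
  eSample <- rowSums((amp * inBand)^2)
  sect <- findInterval(tt, edges, rightmost.closed = TRUE)
  mid <- (nParts + 1L) %/% 2L
  partWidth <- (tPmaxS - tThreshS) / nParts
  sumIn <- function(parts) sum(eSample[sect %in% parts])
  eBefore <- sumIn(seq_len(mid - 1L)) / ((mid - 1L) * partWidth)
  eDuring <- sumIn(mid) / partWidth
  eAfter <- sumIn(seq(mid + 1L, nParts)) / ((nParts - mid) * partWidth)
  tot <- eBefore + eDuring + eAfter
  flagged <- !is.finite(tot) || tot <= 0
  new("SectionEnergies",
      eBefore = eBefore, eDuring = eDuring, eAfter = eAfter,
      pctBefore = if (flagged) NA_real_ else 100 * eBefore / tot,
      pctDuring = if (flagged) NA_real_ else 100 * eDuring / tot,
      pctAfter = if (flagged) NA_real_ else 100 * eAfter / tot,
      sectionBounds = edges, flagged = flagged)
}

#' Classify a contraction as v-shaped
#'
#' A contraction shows v-shape sphincter activity when the during-voiding
#' section has strictly the lowest duration-normalized energy of the three
#' sections (coordinated sphincter relaxation during voiding). Ties are
#' conservatively classified non-v-shape, as are flagged contractions.
#'
#' @param section a [SectionEnergies-class].
#' @return logical(1).
#' @examples
#' # percentages (40, 20, 40) -> v-shape; (30, 40, 30) -> not
#' @export
classifyVshape <- function(section) {
  stopifnot(is(section, "SectionEnergies"))
  if (section@flagged) return(FALSE)
  section@eDuring < section@eBefore && section@eDuring < section@eAfter
}

.roundHalfUp <- function(x) floor(x + 0.5)

#' Percentage of v-shaped contractions for one animal
#'
#' `100 x (number of v-shaped) / (number of analyzable contractions)`,
#' rounded to the nearest integer for reporting. Only contractions starting
#' within the analysis window (default the first 600 s = 10 min) count;
#' animals with fewer than `minContractions` analyzable contractions are
#' excluded from this analysis.
#'
#' @param contractions list of [SectionEnergies-class] objects.
#' @param minContractions minimum analyzable contractions (default 5).
#' @param windowS analysis window length in seconds (default 600).
#' @return A list: `percentage` (integer %, `NA` when excluded), `nVshape`,
#'   `nAnalyzable`, `excluded`.
#' @examples
#' # 5 v-shaped out of 7 analyzable -> 71%
#' @export
vshapePercentage <- function(contractions, minContractions = 5,
                             windowS = 600) {
  stopifnot(all(vapply(contractions, is, logical(1), "SectionEnergies")))
  inWin <- vapply(contractions, function(s)
    !s@flagged && s@sectionBounds[1] <= windowS, logical(1))
  analyzable <- contractions[inWin]
  nA <- length(analyzable)
  if (nA < minContractions)
    return(list(percentage = NA_real_, nVshape = NA_integer_,
                nAnalyzable = nA, excluded = TRUE))
  nV <- sum(vapply(analyzable, classifyVshape, logical(1)))
  list(percentage = .roundHalfUp(100 * nV / nA), nVshape = nV,
       nAnalyzable = nA, excluded = FALSE)
}

#' Mean activity pattern across contractions of one animal
#'
#' Arithmetic mean of the before/during/after percentages across the
#' animal's analyzable contractions; the animal shows mean v-shaped activity
#' when the mean during-voiding percentage is strictly the lowest.
#'
#' @param contractions list of [SectionEnergies-class] objects (at least one
#'   unflagged).
#' @return A list: `pctMean` (named numeric triple summing to 100),
#'   `meanVshape` (logical).
#' @export
meanActivityPattern <- function(contractions) {
  stopifnot(all(vapply(contractions, is, logical(1), "SectionEnergies")))
  ok <- Filter(function(s) !s@flagged, contractions)
  if (!length(ok)) stop("no valid contraction to average")
  m <- rowMeans(vapply(ok, sectionPercentages, numeric(3)))
  list(pctMean = m,
       meanVshape = m["during"] < m["before"] && m["during"] < m["after"])
}

#' Section energies for every contraction of a recording
#'
#' Convenience pipeline: optionally preprocesses the EMG channel
#' ([preprocessEmg()]), then for each contraction event (rows with
#' `tThreshS` / `tPmaxS`, e.g. from [detectCycles()] or
#' [normalizeNoCycle()]`$events`) computes the Hilbert-Huang spectrum of the
#' threshold-to-peak EMG segment and its [sectionEnergies()].
#'
#' @param recording a [UDIRecording-class] with an EMG channel.
#' @param events data.frame with columns `tThreshS`, `tPmaxS` and optionally
#'   `flagged`.
#' @param preprocess apply [preprocessEmg()] first (default TRUE).
#' @param bandHz analysis band passed to [sectionEnergies()].
#' @param nParts parts of the partition (default 5).
#' @param ... further arguments to [preprocessEmg()].
#' @return A list of [SectionEnergies-class], one per usable event; events
#'   that are flagged or too short are skipped.
#' @export
analyzeEmgContractions <- function(recording, events, preprocess = TRUE,
                                   bandHz = c(0, 500), nParts = 5, ...) {
  stopifnot(is(recording, "UDIRecording"))
  if (!hasEmg(recording)) stop("recording has no EMG channel")
  fs <- recording@samplingRate
  emg <- if (preprocess) preprocessEmg(recording, ...) else recording@emg
  out <- list()
  for (k in seq_len(nrow(events))) {
    if (!is.null(events$flagged) && isTRUE(events$flagged[k])) next
    t0 <- events$tThreshS[k]; t1 <- events$tPmaxS[k]
    if (is.na(t0) || is.na(t1) || t0 >= t1) next
    i0 <- max(1L, as.integer(round(t0 * fs)) + 1L)
    i1 <- min(length(emg), as.integer(round(t1 * fs)) + 1L)
    if (i1 - i0 + 1L < 16L) next
    hs <- hilbertHuang(emg[i0:i1], fs, startTimeS = (i0 - 1L) / fs)
    out[[length(out) + 1L]] <- sectionEnergies(hs, t0, t1, nParts = nParts,
                                               bandHz = bandHz)
  }
  out
}
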