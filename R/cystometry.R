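#' Smooth the pressure channel by a centered moving average
#'
#' The derivative used by the threshold-pressure rule is taken on a smoothed
#' trace: a centered moving average over 0.1 s, i.e. 50 samples at 500 Hz and
#' 500 samples at 5000 Hz. Windows shrink at the trace edges so the output
#' has the input length.
#'
#' @param recording a [UDIRecording-class], or a numeric pressure series (in
#'   which case `samplingRate` must be given).
#' @param windowS window length in seconds (default 0.1 s).
#' @param samplingRate required when `recording` is a bare numeric vector.
#' @return Numeric series of the input length with attribute
#'   `"windowSamples"` (the realized window length in samples).
#' @examples
#' sm <- smoothPressure(rep(10, 1000), samplingRate = 500)
#' attr(sm, "windowSamples")  # 50
#' @export
smoothPressure <- function(recording, windowS = 0.1, samplingRate = NULL) {
  if (is(recording, "UDIRecording")) {
    x <- recording@pressure
    fs <- recording@samplingRate
  } else {
    x <- as.numeric(recording)
    if (is.null(samplingRate))
      stop("samplingRate required when smoothing a bare numeric series")
    fs <- samplingRate
  }
  win <- as.integer(round(windowS * fs))
  if (win < 1L) stop("window shorter than one sample")
  if (win > length(x)) stop("smoothing window longer than the trace")
  out <- .movingAverage(x, win)
  attr(out, "windowSamples") <- win
  out
}

#' Threshold pressure by the 65%-of-maximal-derivative rule
#'
#' Within a lookback window (default 20 s) before the cycle's pressure peak,
#' the first discrete difference of the smoothed pressure is scanned; the
#' threshold time is the earliest sample whose difference reaches `fraction`
#' (default 65%) of the window's maximal difference, and the threshold
#' pressure is the raw pressure at that time. Differences are left-assigned
#' (the difference between samples i and i+1 belongs to sample i), so a
#' constant-slope ramp thresholds at the start of the lookback window. The
#' rule is invariant to rescaling the pressure channel.
#'
#' @param smoothed smoothed pressure series (see [smoothPressure()]).
#' @param raw raw pressure series (threshold pressure is read here);
#'   defaults to `smoothed`.
#' @param samplingRate sampling rate in Hz.
#' @param tPmax time (s) of the cycle's pressure maximum.
#' @param lookbackS lookback window length in seconds (default 20).
#' @param fraction fraction of the maximal derivative (default 0.65).
#' @return A list with `tThresh` (s), `pThresh` (cmH2O) and `flagged`
#'   (`TRUE` when the window is entirely non-increasing so no threshold
#'   exists; `tThresh`/`pThresh` are then `NA`).
#' @examples
#' fs <- 100
#' x <- c(seq(0, 10, length.out = 1001))  # linear ramp
#' computePthresh(x, samplingRate = fs, tPmax = 10)$tThresh  # 0
#' @export
computePthresh <- function(smoothed, raw = smoothed, samplingRate, tPmax,
                           lookbackS = 20, fraction = 0.65) {
  i1 <- as.integer(round(tPmax * samplingRate)) + 1L
  i1 <- min(max(i1, 1L), length(smoothed))
  i0 <- max(1L, i1 - as.integer(round(lookbackS * samplingRate)))
  if (i1 - i0 < 1L) stop("fewer than 2 samples in the lookback window")
  d <- diff(smoothed[i0:i1])
  D <- max(d)
  if (D <= 0)
    return(list(tThresh = NA_real_, pThresh = NA_real_, flagged = TRUE))
  j <- which(d >= fraction * D)[1L]
  idx <- i0 + j - 1L
  list(tThresh = (idx - 1L) / samplingRate, pThresh = raw[idx],
       flagged = FALSE)
}

#' Infused volume from cycle start to threshold
#'
#' Filling volume is the volume infused into the bladder from the beginning
#' of the cycle until the threshold pressure is reached:
#' `infusionRate / 60 * (tThresh - startTime)` uL.
#'
#' @param tThresh threshold time (s).
#' @param startTime cycle start time (s).
#' @param infusionRate infusion rate in uL/min.
#' @return Filling volume in uL.
#' @examples
#' computeFillingVolume(120, 0, 10)  # 20 uL
#' @export
computeFillingVolume <- function(tThresh, startTime, infusionRate) {
  if (any(tThresh < startTime, na.rm = TRUE))
    stop("threshold time precedes cycle start")
  infusionRate / 60 * (tThresh - startTime)
}

#' Detect micturition cycles on a pressure trace
#'
#' Peaks of the smoothed pressure with at least `minProminence` prominence
#' and `minIntervalS` separation become candidate voiding contractions. A
#' candidate becomes a micturition cycle only when it rises from and returns
#' to near baseline: the cycle start is the pressure minimum between the
#' previous cycle's end and the peak, the start minimum must lie within
#' `baselineTol` x prominence of the recording-wide minimum, and the cycle
#' end is the first return of the smoothed pressure to within the same
#' tolerance of the start minimum. Recordings whose contractions never
#' return to baseline (the SCI phenotype's sustained high-pressure
#' oscillations) therefore yield an empty result; use [normalizeNoCycle()]
#' for those.
#'
#' For each cycle the peak pressure `pmax` is the highest raw pressure in
#' the cycle, the threshold is computed by [computePthresh()], and the
#' filling volume by [computeFillingVolume()]. When a volume channel is
#' present, the recorded voided volume is the channel increment across the
#' cycle.
#'
#' @param recording a [UDIRecording-class].
#' @param minProminence minimal peak prominence, cmH2O (default 5).
#' @param minIntervalS minimal peak separation, s (default 10).
#' @param windowS smoothing window for [smoothPressure()] (default 0.1 s).
#' @param baselineTol baseline-return tolerance as a fraction of the peak
#'   prominence (default 0.1).
#' @param lookbackS,fraction threshold-rule settings, see [computePthresh()].
#' @return A data.frame with one row per cycle: `cycle`, `startTimeS`,
#'   `endTimeS`, `tPmaxS`, `pmaxCmH2O`, `tThreshS`, `pthreshCmH2O`,
#'   `vFillingUl`, `voidedVolumeUl` (NA without a volume channel) and
#'   `flagged`. Zero rows when no cycle is found (a valid result).
#' @examples
#' sim <- simulateRecording(simParams("sham", durationS = 900, seed = 1))
#' detectCycles(sim$recording)
#' @export
detectCycles <- function(recording, minProminence = 5, minIntervalS = 10,
                         windowS = 0.1, baselineTol = 0.1,
                         lookbackS = 20, fraction = 0.65) {
  stopifnot(is(recording, "UDIRecording"))
  fs <- recording@samplingRate
  raw <- recording@pressure
  sm <- smoothPressure(recording, windowS = windowS)
  peaks <- .findPeaks(sm, fs, minProminence, minIntervalS)
  empty <- data.frame(cycle = integer(0), startTimeS = numeric(0),
                      endTimeS = numeric(0), tPmaxS = numeric(0),
                      pmaxCmH2O = numeric(0), tThreshS = numeric(0),
                      pthreshCmH2O = numeric(0), vFillingUl = numeric(0),
                      voidedVolumeUl = numeric(0), flagged = logical(0))
  if (!nrow(peaks)) return(empty)
  globalMin <- min(sm)
  rows <- list()
  prevEnd <- 1L
  for (k in seq_len(nrow(peaks))) {
    pk <- peaks$index[k]
    tol <- baselineTol * peaks$prominence[k]
    if (pk <= prevEnd) next
    startIdx <- prevEnd - 1L + which.min(sm[prevEnd:pk])
    startMin <- sm[startIdx]
    # must rise from near the recording baseline
    if (startMin - globalMin > tol) next
    # and return to it before the next peak (or the trace end)
    searchEnd <- if (k < nrow(peaks)) peaks$index[k + 1L] else length(sm)
    seg <- sm[(pk + 1L):searchEnd]
    ret <- which(seg <= startMin + tol)
    if (!length(ret)) next
    endIdx <- pk + ret[1L]
    # peak value/time on the raw trace within the cycle
    pmax <- max(raw[startIdx:endIdx])
    tPmax <- (pk - 1L) / fs
    th <- computePthresh(sm, raw, fs, tPmax, lookbackS, fraction)
    vFill <- if (th$flagged) NA_real_ else
      computeFillingVolume(th$tThresh, (startIdx - 1L) / fs,
                           recording@infusionRate)
    vVoid <- if (length(recording@volume))
      recording@volume[endIdx] - recording@volume[startIdx] else NA_real_
    rows[[length(rows) + 1L]] <- data.frame(
      cycle = length(rows) + 1L,
      startTimeS = (startIdx - 1L) / fs,
      endTimeS = (endIdx - 1L) / fs,
      tPmaxS = tPmax, pmaxCmH2O = pmax,
      tThreshS = th$tThresh, pthreshCmH2O = th$pThresh,
      vFillingUl = vFill, voidedVolumeUl = vVoid,
      flagged = th$flagged)
    prevEnd <- endIdx
  }
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

#' Normalize a no-cycle recording and extract contraction events
#'
#' For recordings without micturition cycles (SCI phenotype) the pressure is
#' normalized to the lowest value of the entire recording and the peak
#' pressure is the highest normalized pressure observed. Contraction events
#' are the oscillation peaks found with the same prominence-based peak
#' finder as [detectCycles()] but without the baseline-return requirement;
#' each event carries a threshold time from the 65%-derivative rule.
#'
#' @inheritParams detectCycles
#' @return A list with `pressure` (the min-subtracted series), `pmaxCmH2O`
#'   (maximum of the normalized series) and `events`, a data.frame with one
#'   row per contraction (`tPmaxS`, `pmaxCmH2O` on the normalized scale,
#'   `tThreshS`, `pthreshCmH2O`, `flagged`).
#' @examples
#' sim <- simulateRecording(simParams("SCI", durationS = 300, riseTimeS = 60,
#'                                    seed = 1))
#' res <- normalizeNoCycle(sim$recording)
#' res$pmaxCmH2O
#' @export
normalizeNoCycle <- function(recording, minProminence = 5, minIntervalS = 10,
                             windowS = 0.1, lookbackS = 20, fraction = 0.65) {
  stopifnot(is(recording, "UDIRecording"))
  fs <- recording@samplingRate
  norm <- recording@pressure - min(recording@pressure)
  sm <- smoothPressure(norm, windowS = windowS, samplingRate = fs)
  peaks <- .findPeaks(sm, fs, minProminence, minIntervalS)
  events <- data.frame(tPmaxS = numeric(0), pmaxCmH2O = numeric(0),
                       tThreshS = numeric(0), pthreshCmH2O = numeric(0),
                       flagged = logical(0))
  if (nrow(peaks)) {
    evRows <- lapply(seq_len(nrow(peaks)), function(k) {
      tPmax <- peaks$time[k]
      th <- computePthresh(sm, norm, fs, tPmax, lookbackS, fraction)
      data.frame(tPmaxS = tPmax, pmaxCmH2O = norm[peaks$index[k]],
                 tThreshS = th$tThresh, pthreshCmH2O = th$pThresh,
                 flagged = th$flagged)
    })
    events <- do.call(rbind, evRows)
  }
  list(pressure = norm, pmaxCmH2O = max(norm), events = events)
}

#' Per-recording summary over the first analyzed cycles
#'
#' Means of peak pressure, threshold pressure and filling volume over the
#' first `nCycles` complete (unflagged) cycles; three cycles per animal per
#' week is the convention this mirrors. When fewer cycles are available the
#' mean is taken over those present and the result is flagged.
#'
#' @param cycles cycle table from [detectCycles()].
#' @param nCycles number of cycles to average (default 3).
#' @return A one-row data.frame: `nUsed`, `pmaxMean`, `pthreshMean`,
#'   `vFillingMean`, `fewerThanRequested`.
#' @examples
#' cyc <- data.frame(pmaxCmH2O = c(20, 22, 24), pthreshCmH2O = c(10, 11, 12),
#'                   vFillingUl = c(40, 50, 60), flagged = FALSE)
#' summarizeRecording(cyc)$pmaxMean  # 22
#' @export
summarizeRecording <- function(cycles, nCycles = 3) {
  ok <- cycles[!cycles$flagged, , drop = FALSE]
  if (!nrow(ok)) stop("no complete cycles to summarize")
  few <- nrow(ok) < nCycles
  if (few)
    warning("fewer than ", nCycles, " complete cycles available (",
            nrow(ok), ")")
  use <- head(ok, nCycles)
  data.frame(
    nUsed = nrow(use),
    pmaxMean = mean(use$pmaxCmH2O),
    pthreshMean = mean(use$pthreshCmH2O),
    vFillingMean = mean(use$vFillingUl),
    fewerThanRequested = few)
}
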