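#' Simulator parameters with phenotype presets
#'
#' Builds a validated [SimParams-class]. Acquisition presets mirror the two
#' study arms this package models: `"pboo-500hz"` (pressure sampled at
#' 500 Hz, infusion 10 uL/min, no EMG channel) and `"sci-5000hz"` (5000 Hz,
#' 20 uL/min, EMG recorded). Phenotypes set the pressure morphology: sham and
#' pBOO produce distinct filling/voiding cycles (pBOO with a higher voiding
#' pressure), SCI produces a ramp to a sustained high-pressure plateau with
#' superimposed oscillations and no voids.
#'
#' Defaults not fixed by the acquisition description are phenomenological
#' choices documented in the methods vignette: 300 s intercycle interval,
#' 5 s contraction width, 35 cmH2O SCI plateau with 5 cmH2O / 0.05 Hz
#' oscillations reached over 120 s, 30% void-trap probability.
#'
#' @param phenotype "sham", "pBOO" or "SCI".
#' @param preset acquisition preset, "pboo-500hz" or "sci-5000hz"; `NULL`
#'   picks "sci-5000hz" for SCI and "pboo-500hz" otherwise.
#' @param durationS recording length (s). Defaults: 3 cycles for sham/pBOO,
#'   1500 s (25 min) for SCI.
#' @param emgPattern EMG modulation; `NULL` picks "vshape" for sham,
#'   "dyssynergic" for SCI and "none" for pBOO.
#' @param seed master seed (integer).
#' @param ... any [SimParams-class] slot name to override.
#' @return A [SimParams-class] object.
#' @examples
#' p <- simParams("sham", seed = 1)
#' p
#' @export
simParams <- function(phenotype = c("sham", "pBOO", "SCI"), preset = NULL,
                      durationS = NULL, emgPattern = NULL, seed = 1L, ...) {
  phenotype <- match.arg(phenotype)
  if (is.null(preset))
    preset <- if (phenotype == "SCI") "sci-5000hz" else "pboo-500hz"
  preset <- match.arg(preset, c("pboo-500hz", "sci-5000hz"))
  acq <- if (preset == "pboo-500hz") {
    list(samplingRate = 500, infusionRate = 10)
  } else {
    list(samplingRate = 5000, infusionRate = 20)
  }
  if (is.null(emgPattern))
    emgPattern <- switch(phenotype, sham = "vshape", pBOO = "none",
                         SCI = "dyssynergic")
  defaults <- list(
    samplingRate = acq$samplingRate,
    infusionRate = acq$infusionRate,
    durationS = if (phenotype == "SCI") 1500 else 900,
    baselinePressure = 8,
    complianceSlope = 0.01,
    contractionAmplitude = if (phenotype == "pBOO") 22 else 12,
    contractionWidthS = 5,
    intercycleIntervalS = 300,
    phenotype = phenotype,
    emgPattern = emgPattern,
    emgCarrierBand = c(50, min(450, 0.4 * acq$samplingRate)),
    emgAmplitude = 0.2,
    vshapeSuppressionFraction = 0.2,
    powerlineHz = 0,
    powerlineAmplitude = 0,
    noiseSd = 0.1,
    emgNoiseSd = 0.005,
    voidTrapProbability = 0.3,
    plateauPressure = 35,
    oscillationFreq = 0.05,
    oscillationAmplitude = 5,
    riseTimeS = 120,
    seed = as.integer(seed)
  )
  if (!is.null(durationS)) defaults$durationS <- durationS
  dots <- list(...)
  bad <- setdiff(names(dots), slotNames("SimParams"))
  if (length(bad))
    stop("unknown SimParams fields: ", paste(bad, collapse = ", "))
  defaults[names(dots)] <- dots
  defaults$seed <- as.integer(defaults$seed)
  do.call(new, c(list(Class = "SimParams"), defaults))
}

## Noiseless pressure template for sham/pBOO phenotypes.
##
## Cycle i (i = 1..K, K = floor(duration / T), T = intercycleIntervalS,
## W = contractionWidthS, b = baselinePressure, s = complianceSlope,
## A = contractionAmplitude) on [c_i, c_i + T), c_i = (i-1) T, with peak at
## tPeak_i = c_i + T - W:
##   ramp:  b + s (t - c_i)                        for t in [c_i, tPeak]
##          b + s (T - W) (1 - (t - tPeak)/(W/2))  for t in (tPeak, tPeak+W/2]
##          b                                      afterwards
##   pulse: A/2 (1 + cos(2 pi (t - tPeak)/W))      for |t - tPeak| <= W/2
## Any tail beyond the last full cycle stays at baseline b.
.shamTemplate <- function(tt, p) {
  T <- p@intercycleIntervalS; W <- p@contractionWidthS
  if (p@durationS < T)
    stop("durationS shorter than one intercycle interval: no full cycle fits")
  if (W >= T)
    stop("contractionWidthS must be smaller than intercycleIntervalS")
  K <- floor(p@durationS / T)
  pr <- rep(p@baselinePressure, length(tt))
  peaks <- numeric(K)
  for (i in seq_len(K)) {
    ci <- (i - 1) * T
    tPeak <- ci + T - W
    peaks[i] <- tPeak
    inCycle <- tt >= ci & tt < ci + T
    u <- tt - ci
    ramp <- ifelse(u <= T - W, p@complianceSlope * u,
             ifelse(u <= T - W / 2,
               p@complianceSlope * (T - W) * (1 - (u - (T - W)) / (W / 2)),
               0))
    v <- tt - tPeak
    pulse <- ifelse(abs(v) <= W / 2,
                    p@contractionAmplitude / 2 * (1 + cos(2 * pi * v / W)), 0)
    pr[inCycle] <- p@baselinePressure + ramp[inCycle] + pulse[inCycle]
  }
  list(pressure = pr, peakTimes = peaks)
}

## Noiseless pressure template for the SCI phenotype: linear ramp from
## baseline to the plateau over riseTimeS, then plateau + sinusoidal
## oscillation starting at phase 0 (so the trace is continuous).
.sciTemplate <- function(tt, p) {
  pr <- ifelse(tt < p@riseTimeS,
    p@baselinePressure +
      (p@plateauPressure - p@baselinePressure) * tt / p@riseTimeS,
    p@plateauPressure +
      p@oscillationAmplitude *
        sin(2 * pi * p@oscillationFreq * (tt - p@riseTimeS)))
  # oscillation crests: t = riseTime + (k + 1/4) / f
  f <- p@oscillationFreq
  k <- 0
  peaks <- numeric(0)
  repeat {
    tk <- p@riseTimeS + (k + 0.25) / f
    if (tk > tt[length(tt)]) break
    peaks <- c(peaks, tk)
    k <- k + 1
  }
  list(pressure = pr, peakTimes = peaks)
}

## Ground-truth threshold times: the 65%-of-maximal-derivative rule applied
## to the *noiseless* sampled template (first difference, left-assigned),
## within lookbackS before each peak.
.templateThreshTimes <- function(pr, tt, fs, peakTimes,
                                 lookbackS = 20, fraction = 0.65) {
  vapply(peakTimes, function(tp) {
    i1 <- min(length(tt), round(tp * fs) + 1L)
    i0 <- max(1L, i1 - as.integer(round(lookbackS * fs)))
    d <- diff(pr[i0:i1])
    j <- which(d >= fraction * max(d))[1L]
    tt[i0 + j - 1L]
  }, numeric(1))
}

#' Simulate a urodynamic recording with ground truth
#'
#' Generates a synthetic UDI recording for one animal. Sham/pBOO phenotypes
#' produce micturition cycles: a slow compliance ramp plus a raised-cosine
#' voiding pulse per cycle, with the pressure returning to baseline and a
#' void emitted at each pulse peak. The SCI phenotype ramps to a sustained
#' high-pressure plateau with sinusoidal oscillations (non-voiding
#' contractions) and never returns to baseline; no voids are emitted. The
#' EMG channel is band-limited Gaussian noise whose envelope is suppressed
#' during the voiding section (`"vshape"`), scales with instantaneous
#' pressure (`"dyssynergic"`), or stays constant (`"flat"`). Each void is
#' omitted from the recorded volume trace with probability
#' `voidTrapProbability` (voids trapped in the animal's fur). Identical
#' parameters, including the seed, give bit-identical output.
#'
#' Ground-truth threshold times are computed by applying the
#' 65%-of-maximal-derivative rule to the noiseless sampled template.
#'
#' @param params a [SimParams-class] from [simParams()].
#' @return A list with elements `recording` ([UDIRecording-class]) and
#'   `truth` ([GroundTruth-class]).
#' @examples
#' sim <- simulateRecording(simParams("sham", durationS = 900, seed = 7))
#' sim$recording
#' sim$truth
#' @export
simulateRecording <- function(params) {
  validObject(params)
  p <- params
  fs <- p@samplingRate
  n <- as.integer(round(p@durationS * fs))
  tt <- (seq_len(n) - 1) / fs
  set.seed(p@seed)

  if (p@phenotype == "SCI") {
    if (p@durationS <= p@riseTimeS + 0.25 / p@oscillationFreq)
      stop("durationS too short for the SCI plateau to develop a contraction")
    tpl <- .sciTemplate(tt, p)
  } else {
    tpl <- .shamTemplate(tt, p)
  }
  peakTimes <- tpl$peakTimes
  threshTimes <- .templateThreshTimes(tpl$pressure, tt, fs, peakTimes)

  pressureTrace <- tpl$pressure +
    if (p@noiseSd > 0) rnorm(n, 0, p@noiseSd) else 0

  # ---- EMG channel -------------------------------------------------------
  emg <- NULL
  if (p@emgPattern != "none") {
    carrier <- rnorm(n)
    band <- p@emgCarrierBand / (fs / 2)
    bf <- signal::butter(4, band, type = "pass")
    carrier <- signal::filtfilt(bf, carrier)
    carrier <- carrier / sqrt(mean(carrier^2))
    env <- rep(1, n)
    if (p@emgPattern == "vshape") {
      for (i in seq_along(peakTimes)) {
        span <- peakTimes[i] - threshTimes[i]
        lo <- threshTimes[i] + 2 / 5 * span
        hi <- threshTimes[i] + 3 / 5 * span
        env[tt >= lo & tt < hi] <- p@vshapeSuppressionFraction
      }
    } else if (p@emgPattern == "dyssynergic") {
      rng <- range(tpl$pressure)
      env <- 0.3 + 0.7 * (tpl$pressure - rng[1]) / max(rng[2] - rng[1], 1e-12)
    }
    emg <- p@emgAmplitude * env * carrier
    if (p@powerlineHz > 0 && p@powerlineAmplitude > 0)
      emg <- emg + p@powerlineAmplitude * sin(2 * pi * p@powerlineHz * tt)
    if (p@emgNoiseSd > 0) emg <- emg + rnorm(n, 0, p@emgNoiseSd)
  }

  # ---- voids and volume channel -----------------------------------------
  if (p@phenotype == "SCI") {
    voidTimes <- numeric(0)
    trapped <- logical(0)
    recordedVolumes <- numeric(0)
    volume <- rep(0, n)
  } else {
    voidTimes <- peakTimes
    prevVoid <- c(0, head(voidTimes, -1))
    volumes <- p@infusionRate / 60 * (voidTimes - prevVoid)
    trapped <- runif(length(voidTimes)) < p@voidTrapProbability
    recordedVolumes <- volumes[!trapped]
    volume <- rep(0, n)
    cum <- 0
    for (i in seq_along(voidTimes)) {
      if (!trapped[i]) {
        cum <- cum + volumes[i]
        volume[tt >= voidTimes[i]] <- cum
      }
    }
  }

  rec <- UDIRecording(
    time = tt, pressure = pressureTrace, emg = emg, volume = volume,
    samplingRate = fs, volumeRate = 5, infusionRate = p@infusionRate,
    group = p@phenotype)
  truth <- new("GroundTruth",
    voidTimes = voidTimes,
    pmaxTimes = peakTimes,
    threshTimes = threshTimes,
    emgPattern = rep(p@emgPattern, length(peakTimes)),
    trappedVoidFlags = trapped,
    recordedVoidVolumes = recordedVolumes,
    pressureRange = range(tpl$pressure))
  list(recording = rec, truth = truth)
}
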