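#' UDIRecording: a synchronized urodynamic recording
#'
#' Container for one urodynamic investigation (UDI): intravesical pressure
#' (cmH2O), optional external urethral sphincter EMG (V) and optional
#' cumulative voided volume (uL) on a shared, uniformly sampled time base.
#'
#' @slot time numeric, sample times in seconds from recording start
#'   (monotone non-decreasing, uniform at `samplingRate`).
#' @slot pressure numeric, intravesical pressure P_ves in cmH2O; same length
#'   as `time`.
#' @slot emg numeric, EUS-EMG in volts; either length 0 (channel absent) or
#'   the length of `time`.
#' @slot volume numeric, cumulative voided volume in uL as recorded by the
#'   scale; length 0 or the length of `time`.
#' @slot samplingRate numeric(1), sampling rate in Hz.
#' @slot volumeRate numeric(1), native acquisition rate of the scale channel
#'   in Hz (metadata only; the stored series is on the common time base).
#'   `NA` when the channel is absent.
#' @slot infusionRate numeric(1), saline infusion rate in uL/min.
#' @slot animalId character(1) metadata label.
#' @slot group character(1) metadata label (e.g. "sham", "pBOO", "SCI").
#' @slot week numeric(1) study week (0 = baseline); `NA` when unknown.
#'
#' @seealso [UDIRecording()] for the constructor, [readRecording()],
#'   [simulateRecording()].
#' @export
setClass("UDIRecording",
  slots = c(
    time = "numeric",
    pressure = "numeric",
    emg = "numeric",
    volume = "numeric",
    samplingRate = "numeric",
    volumeRate = "numeric",
    infusionRate = "numeric",
    animalId = "character",
    group = "character",
    week = "numeric"
  ),
  prototype = list(
    emg = numeric(0), volume = numeric(0),
    volumeRate = NA_real_, infusionRate = 10,
    animalId = NA_character_, group = NA_character_, week = NA_real_
  )
)

setValidity("UDIRecording", function(object) {
  msg <- character(0)
  n <- length(object@time)
  if (n < 2L)
    msg <- c(msg, "recording must contain at least 2 samples")
  if (length(object@pressure) != n)
    msg <- c(msg, "pressure series length must equal time series length")
  if (length(object@emg) != 0L && length(object@emg) != n)
    msg <- c(msg, "emg series must be empty or match the time series length")
  if (length(object@volume) != 0L && length(object@volume) != n)
    msg <- c(msg, "volume series must be empty or match the time series length")
  if (length(object@samplingRate) != 1L || !is.finite(object@samplingRate) ||
      object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be a single positive number")
  if (length(object@infusionRate) != 1L || !is.finite(object@infusionRate) ||
      object@infusionRate <= 0)
    msg <- c(msg, "infusionRate must be a single positive number")
  if (n >= 2L) {
    dt <- diff(object@time)
    if (any(dt < 0))
      msg <- c(msg, "time must be monotone non-decreasing")
    # sampling interval must match the declared rate to 1 part in 1e6
    if (abs(median(dt) * object@samplingRate - 1) > 1e-6)
      msg <- c(msg, "sampling interval inconsistent with samplingRate (> 1 ppm)")
  }
  if (length(msg)) msg else TRUE
})

#' GroundTruth: simulator annotations for recovery testing
#'
#' Side-car object emitted by [simulateRecording()] describing the planted
#' events of a synthetic recording: true void times, contraction peak and
#' threshold times, the planted EMG modulation pattern per contraction, and
#' which voids were "trapped" (visible but not recorded by the scale).
#'
#' @slot voidTimes numeric, true void times in seconds (empty for SCI).
#' @slot pmaxTimes numeric, true contraction-peak times in seconds.
#' @slot threshTimes numeric, true threshold times (derivative rule applied
#'   to the noiseless template), one per contraction.
#' @slot emgPattern character, planted EMG pattern label per contraction
#'   ("vshape", "dyssynergic", "flat" or "none").
#' @slot trappedVoidFlags logical, one per true void; `TRUE` when the void
#'   was omitted from the recorded volume trace.
#' @slot recordedVoidVolumes numeric, volumes (uL) of the voids that reached
#'   the scale (length = number of untrapped voids).
#' @slot pressureRange numeric(2), min and max of the noiseless pressure
#'   template (used to validate no-cycle normalization).
#' @export
setClass("GroundTruth",
  slots = c(
    voidTimes = "numeric",
    pmaxTimes = "numeric",
    threshTimes = "numeric",
    emgPattern = "character",
    trappedVoidFlags = "logical",
    recordedVoidVolumes = "numeric",
    pressureRange = "numeric"
  )
)

setValidity("GroundTruth", function(object) {
  msg <- character(0)
  k <- length(object@pmaxTimes)
  if (length(object@threshTimes) != k)
    msg <- c(msg, "threshTimes and pmaxTimes must have equal length")
  if (length(object@emgPattern) != k)
    msg <- c(msg, "emgPattern and pmaxTimes must have equal length")
  if (k > 0L && any(object@threshTimes >= object@pmaxTimes))
    msg <- c(msg, "every threshold time must precede its paired peak time")
  if (length(object@trappedVoidFlags) != length(object@voidTimes))
    msg <- c(msg, "trappedVoidFlags must have one entry per true void")
  if (length(object@recordedVoidVolumes) != sum(!object@trappedVoidFlags))
    msg <- c(msg, "recordedVoidVolumes must match the number of untrapped voids")
  if (length(msg)) msg else TRUE
})

#' HilbertSpectrum: empirical mode decomposition + analytic signal
#'
#' Result of [hilbertHuang()]: intrinsic mode functions (IMFs) of the input
#' signal together with their instantaneous amplitude and frequency obtained
#' from the analytic signal of each IMF.
#'
#' @slot imfs numeric matrix (samples x IMFs).
#' @slot residual numeric, the non-oscillatory remainder; IMFs + residual
#'   reconstruct the input to machine precision.
#' @slot instAmplitude numeric matrix, |analytic signal| per IMF.
#' @slot instFrequency numeric matrix, instantaneous frequency in Hz per IMF
#'   (derivative of the unwrapped phase).
#' @slot time numeric, shared time base in seconds.
#' @slot samplingRate numeric(1), Hz.
#' @export
setClass("HilbertSpectrum",
  slots = c(
    imfs = "matrix",
    residual = "numeric",
    instAmplitude = "matrix",
    instFrequency = "matrix",
    time = "numeric",
    samplingRate = "numeric"
  )
)

setValidity("HilbertSpectrum", function(object) {
  msg <- character(0)
  n <- length(object@time)
  if (nrow(object@imfs) != n || length(object@residual) != n)
    msg <- c(msg, "IMFs and residual must match the time base length")
  if (!identical(dim(object@imfs), dim(object@instAmplitude)) ||
      !identical(dim(object@imfs), dim(object@instFrequency)))
    msg <- c(msg, "amplitude/frequency matrices must match the IMF matrix")
  if (length(msg)) msg else TRUE
})

#' SectionEnergies: before/during/after-voiding EMG energy of one contraction
#'
#' The threshold-to-peak interval of a contraction is split into five equal
#' parts; parts 1-2 are "before voiding", part 3 "during voiding", parts 4-5
#' "after voiding". Energies are the in-band (0-500 Hz by default) squared
#' instantaneous amplitudes summed over the section and divided by the
#' section duration; percentages are taken over the three normalized
#' energies and sum to 100.
#'
#' @slot eBefore,eDuring,eAfter numeric(1), duration-normalized energies
#'   (arbitrary units per second), all >= 0.
#' @slot pctBefore,pctDuring,pctAfter numeric(1), percentages summing to 100
#'   (NA when `flagged`).
#' @slot sectionBounds numeric(6), edges of the five-part partition in
#'   seconds.
#' @slot flagged logical(1), `TRUE` when total energy is zero and percentages
#'   are undefined; flagged contractions are excluded from summaries.
#' @export
setClass("SectionEnergies",
  slots = c(
    eBefore = "numeric", eDuring = "numeric", eAfter = "numeric",
    pctBefore = "numeric", pctDuring = "numeric", pctAfter = "numeric",
    sectionBounds = "numeric",
    flagged = "logical"
  )
)

setValidity("SectionEnergies", function(object) {
  msg <- character(0)
  e <- c(object@eBefore, object@eDuring, object@eAfter)
  if (any(!is.finite(e)) || any(e < 0))
    msg <- c(msg, "energies must be finite and non-negative")
  if (length(object@sectionBounds) != 6L)
    msg <- c(msg, "sectionBounds must contain the 6 edges of the 5 parts")
  if (!object@flagged) {
    s <- object@pctBefore + object@pctDuring + object@pctAfter
    if (!is.finite(s) || abs(s - 100) > 1e-6)
      msg <- c(msg, "percentages must sum to 100 within 1e-6")
  }
  if (length(msg)) msg else TRUE
})

#' SharedGeneSet: two-condition DEG intersection partitioned by sign
#'
#' Result of [intersectDegs()]: genes differentially expressed in both
#' conditions, partitioned into sign-concordant (same direction of log2 fold
#' change) and discordant sets, plus the condition-unique genes.
#'
#' @slot shared character, genes present in both DEG tables.
#' @slot concordant character, shared genes with sign(log2FC_A) =
#'   sign(log2FC_B).
#' @slot discordant character, shared genes with opposite signs.
#' @slot uniqueA,uniqueB character, genes in only one table.
#' @export
setClass("SharedGeneSet",
  slots = c(
    shared = "character",
    concordant = "character",
    discordant = "character",
    uniqueA = "character",
    uniqueB = "character"
  )
)

setValidity("SharedGeneSet", function(object) {
  msg <- character(0)
  if (length(object@concordant) + length(object@discordant) !=
      length(object@shared))
    msg <- c(msg, "|concordant| + |discordant| must equal |shared|")
  if (!all(object@concordant %in% object@shared) ||
      !all(object@discordant %in% object@shared))
    msg <- c(msg, "concordant/discordant must be subsets of shared")
  if (length(intersect(object@shared, object@uniqueA)) ||
      length(intersect(object@shared, object@uniqueB)) ||
      length(intersect(object@uniqueA, object@uniqueB)))
    msg <- c(msg, "shared, uniqueA and uniqueB must be pairwise disjoint")
  if (length(msg)) msg else TRUE
})

#' SimParams: configuration of the UDI/EMG simulator
#'
#' All knobs of [simulateRecording()]. Use [simParams()] which applies
#' phenotype- and preset-specific defaults and validates the combination.
#'
#' @slot samplingRate numeric(1), Hz (500 pBOO-style, 5000 SCI-style).
#' @slot infusionRate numeric(1), uL/min (10 pBOO-style, 20 SCI-style).
#' @slot durationS numeric(1), recording length in seconds.
#' @slot baselinePressure numeric(1), resting P_ves in cmH2O.
#' @slot complianceSlope numeric(1), filling-phase pressure rise in cmH2O/s.
#' @slot contractionAmplitude numeric(1), voiding-contraction pulse height in
#'   cmH2O (sham/pBOO phenotypes).
#' @slot contractionWidthS numeric(1), full width of the raised-cosine
#'   voiding pulse in seconds.
#' @slot intercycleIntervalS numeric(1), micturition cycle period in seconds.
#' @slot phenotype character(1): "sham", "pBOO" or "SCI".
#' @slot emgPattern character(1): "vshape", "dyssynergic", "flat" or "none"
#'   (no EMG channel).
#' @slot emgCarrierBand numeric(2), band (Hz) of the band-limited noise
#'   carrier; upper bound must stay below Nyquist.
#' @slot emgAmplitude numeric(1), RMS of the unmodulated EMG carrier (V).
#' @slot vshapeSuppressionFraction numeric(1) in \[0,1\]: multiplicative
#'   envelope factor applied during the voiding section (smaller = stronger
#'   suppression).
#' @slot powerlineHz numeric(1), mains frequency added to the EMG (0
#'   disables).
#' @slot powerlineAmplitude numeric(1), mains sinusoid amplitude (V).
#' @slot noiseSd numeric(1), additive Gaussian noise SD on pressure (cmH2O).
#' @slot emgNoiseSd numeric(1), additive Gaussian noise SD on EMG (V).
#' @slot voidTrapProbability numeric(1) in \[0,1\], probability that a void
#'   is trapped (not recorded by the scale).
#' @slot plateauPressure numeric(1), SCI plateau level in cmH2O.
#' @slot oscillationFreq numeric(1), SCI high-pressure oscillation frequency
#'   in Hz.
#' @slot oscillationAmplitude numeric(1), SCI oscillation amplitude in cmH2O.
#' @slot riseTimeS numeric(1), SCI ramp duration from baseline to plateau.
#' @slot seed integer(1), master seed; all stochastic draws derive from it.
#' @export
setClass("SimParams",
  slots = c(
    samplingRate = "numeric",
    infusionRate = "numeric",
    durationS = "numeric",
    baselinePressure = "numeric",
    complianceSlope = "numeric",
    contractionAmplitude = "numeric",
    contractionWidthS = "numeric",
    intercycleIntervalS = "numeric",
    phenotype = "character",
    emgPattern = "character",
    emgCarrierBand = "numeric",
    emgAmplitude = "numeric",
    vshapeSuppressionFraction = "numeric",
    powerlineHz = "numeric",
    powerlineAmplitude = "numeric",
    noiseSd = "numeric",
    emgNoiseSd = "numeric",
    voidTrapProbability = "numeric",
    plateauPressure = "numeric",
    oscillationFreq = "numeric",
    oscillationAmplitude = "numeric",
    riseTimeS = "numeric",
    seed = "integer"
  )
)

setValidity("SimParams", function(object) {
  msg <- character(0)
  pos1 <- function(x) length(x) == 1L && is.finite(x) && x > 0
  if (!pos1(object@samplingRate)) msg <- c(msg, "samplingRate must be positive")
  if (!pos1(object@infusionRate)) msg <- c(msg, "infusionRate must be positive")
  if (!pos1(object@durationS)) msg <- c(msg, "durationS must be positive")
  if (!pos1(object@contractionAmplitude))
    msg <- c(msg, "contractionAmplitude must be positive")
  if (!pos1(object@contractionWidthS))
    msg <- c(msg, "contractionWidthS must be positive")
  if (!pos1(object@intercycleIntervalS))
    msg <- c(msg, "intercycleIntervalS must be positive")
  if (object@complianceSlope < 0) msg <- c(msg, "complianceSlope must be >= 0")
  if (!object@phenotype %in% c("sham", "pBOO", "SCI"))
    msg <- c(msg, "phenotype must be one of sham, pBOO, SCI")
  if (!object@emgPattern %in% c("vshape", "dyssynergic", "flat", "none"))
    msg <- c(msg, "emgPattern must be one of vshape, dyssynergic, flat, none")
  if (length(object@emgCarrierBand) != 2L ||
      object@emgCarrierBand[1] <= 0 ||
      object@emgCarrierBand[2] <= object@emgCarrierBand[1])
    msg <- c(msg, "emgCarrierBand must be an increasing positive pair")
  else if (object@emgPattern != "none" &&
           object@emgCarrierBand[2] >= object@samplingRate / 2)
    msg <- c(msg, "emgCarrierBand upper bound must be below Nyquist")
  if (object@vshapeSuppressionFraction < 0 ||
      object@vshapeSuppressionFraction > 1)
    msg <- c(msg, "vshapeSuppressionFraction must lie in [0, 1]")
  if (object@voidTrapProbability < 0 || object@voidTrapProbability > 1)
    msg <- c(msg, "voidTrapProbability must lie in [0, 1]")
  if (object@powerlineHz < 0 || object@powerlineAmplitude < 0)
    msg <- c(msg, "powerline settings must be non-negative")
  if (object@noiseSd < 0 || object@emgNoiseSd < 0)
    msg <- c(msg, "noise SDs must be non-negative")
  # whole number of samples
  ns <- object@durationS * object@samplingRate
  if (abs(ns - round(ns)) > 1e-6)
    msg <- c(msg, "durationS x samplingRate must be a whole number of samples")
  if (length(msg)) msg else TRUE
})
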