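#' Construct a UDIRecording
#'
#' @param time sample times in seconds (uniform grid).
#' @param pressure intravesical pressure, cmH2O.
#' @param emg optional EUS-EMG series (V); `NULL` or `numeric(0)` when the
#'   channel is absent.
#' @param volume optional cumulative voided-volume series (uL).
#' @param samplingRate sampling rate in Hz; inferred from `time` when `NULL`.
#' @param volumeRate native scale-channel rate in Hz (metadata; 5 Hz in the
#'   acquisition setup this models).
#' @param infusionRate saline infusion rate, uL/min.
#' @param animalId,group,week metadata labels.
#' @return A validated [UDIRecording-class] object.
#' @examples
#' t <- seq(0, 1, by = 1 / 500)
#' rec <- UDIRecording(t, pressure = rep(10, length(t)))
#' samplingRate(rec)
#' @export
UDIRecording <- function(time, pressure, emg = NULL, volume = NULL,
                         samplingRate = NULL, volumeRate = NA_real_,
                         infusionRate = 10, animalId = NA_character_,
                         group = NA_character_, week = NA_real_) {
  if (is.null(samplingRate)) {
    if (length(time) < 2L)
      stop("cannot infer samplingRate from fewer than 2 samples")
    samplingRate <- (length(time) - 1) / (time[length(time)] - time[1])
  }
  new("UDIRecording",
    time = as.numeric(time), pressure = as.numeric(pressure),
    emg = if (is.null(emg)) numeric(0) else as.numeric(emg),
    volume = if (is.null(volume)) numeric(0) else as.numeric(volume),
    samplingRate = as.numeric(samplingRate),
    volumeRate = as.numeric(volumeRate),
    infusionRate = as.numeric(infusionRate),
    animalId = as.character(animalId), group = as.character(group),
    week = as.numeric(week))
}

#' Accessors for UDIRecording
#'
#' @param x a [UDIRecording-class].
#' @return `pressure`, `emgSignal`, `voidedVolume`, `sampleTimes` return the
#'   corresponding numeric series (`emgSignal`/`voidedVolume` are `NULL` when
#'   the channel is absent); `samplingRate` and `infusionRate` return single
#'   numbers; `hasEmg`/`hasVolume` return logicals.
#' @name UDIRecording-accessors
NULL

#' @rdname UDIRecording-accessors
#' @export
setMethod("pressure", "UDIRecording", function(x) x@pressure)

#' @rdname UDIRecording-accessors
#' @export
setMethod("emgSignal", "UDIRecording",
  function(x) if (length(x@emg)) x@emg else NULL)

#' @rdname UDIRecording-accessors
#' @export
setMethod("voidedVolume", "UDIRecording",
  function(x) if (length(x@volume)) x@volume else NULL)

#' @rdname UDIRecording-accessors
#' @export
setMethod("sampleTimes", "UDIRecording", function(x) x@time)

#' @rdname UDIRecording-accessors
#' @export
setMethod("samplingRate", "UDIRecording", function(x) x@samplingRate)

#' @rdname UDIRecording-accessors
#' @export
setMethod("infusionRate", "UDIRecording", function(x) x@infusionRate)

#' @rdname UDIRecording-accessors
#' @export
setMethod("hasEmg", "UDIRecording", function(x) length(x@emg) > 0L)

#' @rdname UDIRecording-accessors
#' @export
setMethod("hasVolume", "UDIRecording", function(x) length(x@volume) > 0L)

setMethod("show", "UDIRecording", function(object) {
  cat("UDIRecording:", length(object@time), "samples @",
      object@samplingRate, "Hz (",
      sprintf("%.1f", length(object@time) / object@samplingRate), "s )\n")
  cat("  channels: pressure",
      if (length(object@emg)) "+ EMG" else "",
      if (length(object@volume)) "+ volume" else "", "\n")
  cat("  infusion:", object@infusionRate, "uL/min;",
      "animal:", object@animalId, "group:", object@group,
      "week:", object@week, "\n")
  cat("  P_ves range:", sprintf("%.2f - %.2f cmH2O",
      min(object@pressure), max(object@pressure)), "\n")
})

#' Accessors for HilbertSpectrum
#'
#' @param x a [HilbertSpectrum-class].
#' @return `imfs` the samples-by-IMF matrix; `instAmplitude` and
#'   `instFrequency` the matching amplitude (signal units) and frequency (Hz)
#'   matrices.
#' @name HilbertSpectrum-accessors
NULL

#' @rdname HilbertSpectrum-accessors
#' @export
setMethod("imfs", "HilbertSpectrum", function(x) x@imfs)

#' @rdname HilbertSpectrum-accessors
#' @export
setMethod("instAmplitude", "HilbertSpectrum", function(x) x@instAmplitude)

#' @rdname HilbertSpectrum-accessors
#' @export
setMethod("instFrequency", "HilbertSpectrum", function(x) x@instFrequency)

setMethod("show", "HilbertSpectrum", function(object) {
  cat("HilbertSpectrum:", ncol(object@imfs), "IMFs x",
      nrow(object@imfs), "samples @", object@samplingRate, "Hz\n")
  if (ncol(object@imfs)) {
    med <- apply(object@instFrequency, 2, median, na.rm = TRUE)
    cat("  median instantaneous frequency per IMF (Hz):",
        paste(sprintf("%.1f", med), collapse = ", "), "\n")
  }
})

#' Accessors for SectionEnergies
#'
#' @param x a [SectionEnergies-class].
#' @return `sectionPercentages` the named (before/during/after) percentage
#'   triple; `sectionEnergyValues` the named duration-normalized energies.
#' @name SectionEnergies-accessors
NULL

#' @rdname SectionEnergies-accessors
#' @export
setMethod("sectionPercentages", "SectionEnergies", function(x)
  c(before = x@pctBefore, during = x@pctDuring, after = x@pctAfter))

#' @rdname SectionEnergies-accessors
#' @export
setMethod("sectionEnergyValues", "SectionEnergies", function(x)
  c(before = x@eBefore, during = x@eDuring, after = x@eAfter))

setMethod("show", "SectionEnergies", function(object) {
  if (object@flagged) {
    cat("SectionEnergies: flagged (zero total energy)\n")
  } else {
    cat(sprintf(
      "SectionEnergies: before %.1f%% | during %.1f%% | after %.1f%%%s\n",
      object@pctBefore, object@pctDuring, object@pctAfter,
      if (classifyVshape(object)) "  [v-shape]" else ""))
  }
})

#' Accessors for SharedGeneSet
#'
#' @param x a [SharedGeneSet-class].
#' @param which `"A"` or `"B"`, which condition's unique genes to return.
#' @return Character vectors of gene identifiers.
#' @name SharedGeneSet-accessors
NULL

#' @rdname SharedGeneSet-accessors
#' @export
setMethod("sharedGenes", "SharedGeneSet", function(x) x@shared)

#' @rdname SharedGeneSet-accessors
#' @export
setMethod("concordantGenes", "SharedGeneSet", function(x) x@concordant)

#' @rdname SharedGeneSet-accessors
#' @export
setMethod("discordantGenes", "SharedGeneSet", function(x) x@discordant)

#' @rdname SharedGeneSet-accessors
#' @export
setMethod("uniqueGenes", "SharedGeneSet", function(x, which = c("A", "B")) {
  which <- match.arg(which)
  if (which == "A") x@uniqueA else x@uniqueB
})

setMethod("show", "SharedGeneSet", function(object) {
  cat("SharedGeneSet:", length(object@shared), "shared genes (",
      length(object@concordant), "concordant,",
      length(object@discordant), "discordant );",
      length(object@uniqueA), "unique to A,",
      length(object@uniqueB), "unique to B\n")
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", length(object@pmaxTimes), "contractions,",
      length(object@voidTimes), "true voids (",
      sum(object@trappedVoidFlags), "trapped )\n")
})

setMethod("show", "SimParams", function(object) {
  cat("SimParams:", object@phenotype, "phenotype,",
      object@durationS, "s @", object@samplingRate, "Hz,",
      "infusion", object@infusionRate, "uL/min, EMG pattern",
      object@emgPattern, ", seed", object@seed, "\n")
})
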