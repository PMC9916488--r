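#' @rdname UDIRecording-accessors
#' @export
setGeneric("pressure", function(x) standardGeneric("pressure"))

#' @rdname UDIRecording-accessors
#' @export
setGeneric("emgSignal", function(x) standardGeneric("emgSignal"))

#' @rdname UDIRecording-accessors
#' @export
setGeneric("voidedVolume", function(x) standardGeneric("voidedVolume"))

#' @rdname UDIRecording-accessors
#' @export
setGeneric("sampleTimes", function(x) standardGeneric("sampleTimes"))

#' @rdname UDIRecording-accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname UDIRecording-accessors
#' @export
setGeneric("infusionRate", function(x) standardGeneric("infusionRate"))

#' @rdname UDIRecording-accessors
#' @export
setGeneric("hasEmg", function(x) standardGeneric("hasEmg"))

#' @rdname UDIRecording-accessors
#' @export
setGeneric("hasVolume", function(x) standardGeneric("hasVolume"))

#' @rdname HilbertSpectrum-accessors
#' @export
setGeneric("imfs", function(x) standardGeneric("imfs"))

#' @rdname HilbertSpectrum-accessors
#' @export
setGeneric("instAmplitude", function(x) standardGeneric("instAmplitude"))

#' @rdname HilbertSpectrum-accessors
#' @export
setGeneric("instFrequency", function(x) standardGeneric("instFrequency"))

#' @rdname SectionEnergies-accessors
#' @export
setGeneric("sectionPercentages", function(x) standardGeneric("sectionPercentages"))

#' @rdname SectionEnergies-accessors
#' @export
setGeneric("sectionEnergyValues", function(x) standardGeneric("sectionEnergyValues"))

#' @rdname SharedGeneSet-accessors
#' @export
setGeneric("sharedGenes", function(x) standardGeneric("sharedGenes"))

#' @rdname SharedGeneSet-accessors
#' @export
setGeneric("concordantGenes", function(x) standardGeneric("concordantGenes"))

#' @rdname SharedGeneSet-accessors
#' @export
setGeneric("discordantGenes", function(x) standardGeneric("discordantGenes"))

#' @rdname SharedGeneSet-accessors
#' @export
setGeneric("uniqueGenes", function(x, which = c("A", "B"))
  standardGeneric("uniqueGenes"))
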