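#' @include nirsize-package.R
NULL

#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @export
setGeneric("diameters", function(x) standardGeneric("diameters"))

#' @export
setGeneric("ssc", function(x) standardGeneric("ssc"))

#' @export
setGeneric("groupLabels", function(x) standardGeneric("groupLabels"))

#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @export
setGeneric("nWavelengths", function(x) standardGeneric("nWavelengths"))

#' @export
setGeneric("spectrumValues", function(x) standardGeneric("spectrumValues"))

#' @export
setGeneric("extinction", function(x) standardGeneric("extinction"))

#' @export
setGeneric("referenceDiameter", function(x) standardGeneric("referenceDiameter"))

#' @export
setGeneric("referenceSpectrum", function(x) standardGeneric("referenceSpectrum"))

#' @export
setGeneric("calibrationIndices", function(x) standardGeneric("calibrationIndices"))

#' @export
setGeneric("predictionIndices", function(x) standardGeneric("predictionIndices"))

#' @export
setGeneric("nLatent", function(x) standardGeneric("nLatent"))
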