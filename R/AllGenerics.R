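#' @title Generics for OdontoID classes
#' @description Accessor and operation generics used across the package.
#' @name OdontoID-generics
#' @keywords internal
NULL

#' @export
setGeneric("pixelData", function(x) standardGeneric("pixelData"))

#' @export
setGeneric("bitDepth", function(x) standardGeneric("bitDepth"))

#' @export
setGeneric("spacingMM", function(x) standardGeneric("spacingMM"))

#' @export
setGeneric("individualId", function(x) standardGeneric("individualId"))

#' @export
setGeneric("ageYears", function(x) standardGeneric("ageYears"))

#' @export
setGeneric("processingLog", function(x) standardGeneric("processingLog"))

#' @export
setGeneric("nKeypoints", function(x) standardGeneric("nKeypoints"))

#' @export
setGeneric("descriptorLength", function(x) standardGeneric("descriptorLength"))

#' @export
setGeneric("keypoints", function(x) standardGeneric("keypoints"))

#' @export
setGeneric("descriptors", function(x) standardGeneric("descriptors"))

#' @export
setGeneric("imageShape", function(x) standardGeneric("imageShape"))

#' @export
setGeneric("dbSize", function(db) standardGeneric("dbSize"))

#' @export
setGeneric("forwardPoints", function(x) standardGeneric("forwardPoints"))

#' @export
setGeneric("reversePoints", function(x) standardGeneric("reversePoints"))

#' @export
setGeneric("averagePoints", function(x) standardGeneric("averagePoints"))

#' @export
setGeneric("rankedCandidates", function(x) standardGeneric("rankedCandidates"))

#' @export
setGeneric("rowsEvaluated", function(x) standardGeneric("rowsEvaluated"))

#' @export
setGeneric("fractionEvaluated",
           function(x) standardGeneric("fractionEvaluated"))

#' @export
setGeneric("estimatedAge", function(x) standardGeneric("estimatedAge"))

#' @export
setGeneric("stopReason", function(x) standardGeneric("stopReason"))

#' @export
setGeneric("layerManifest", function(model) standardGeneric("layerManifest"))

#' @export
setGeneric("parameterCount", function(model) standardGeneric("parameterCount"))
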