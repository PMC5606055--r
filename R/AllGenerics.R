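# Accessor generics. Slot access from user code is discouraged; these are the
# supported surface.

#' @export
setGeneric("nRecords", function(x) standardGeneric("nRecords"))

#' @export
setGeneric("featureNames", function(x) standardGeneric("featureNames"))

#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @export
setGeneric("outcome", function(x) standardGeneric("outcome"))

#' @export
setGeneric("featureInfo", function(x) standardGeneric("featureInfo"))

#' @export
setGeneric("isScaled", function(x) standardGeneric("isScaled"))

#' @export
setGeneric("scalingParams", function(x) standardGeneric("scalingParams"))

#' @export
setGeneric("connectionMask", function(x) standardGeneric("connectionMask"))

#' @export
setGeneric("inputWeights", function(x) standardGeneric("inputWeights"))

#' @export
setGeneric("outputWeights", function(x) standardGeneric("outputWeights"))

#' @export
setGeneric("sensitivities", function(x) standardGeneric("sensitivities"))

#' @export
setGeneric("featureRanks", function(x) standardGeneric("featureRanks"))

#' @export
setGeneric("removedFeatures", function(x) standardGeneric("removedFeatures"))

#' @export
setGeneric("stageAccuracies", function(x) standardGeneric("stageAccuracies"))

#' @export
setGeneric("baselineAccuracy", function(x) standardGeneric("baselineAccuracy"))

#' @export
setGeneric("changeCells", function(x) standardGeneric("changeCells"))

#' @export
setGeneric("columnAverages", function(x) standardGeneric("columnAverages"))

#' @export
setGeneric("correlatedPairs", function(x) standardGeneric("correlatedPairs"))

#' @export
setGeneric("featureGroups", function(x) standardGeneric("featureGroups"))

#' @export
setGeneric("confusionCounts", function(x) standardGeneric("confusionCounts"))

#' @export
setGeneric("selectedFeatures", function(x) standardGeneric("selectedFeatures"))

#' @export
setGeneric("modelMetrics", function(x) standardGeneric("modelMetrics"))
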