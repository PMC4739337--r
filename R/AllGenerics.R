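#' @rdname VimDataset-accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname VimDataset-accessors
#' @export
setGeneric("nFeatures", function(x) standardGeneric("nFeatures"))
#' @rdname VimDataset-accessors
#' @export
setGeneric("nClasses", function(x) standardGeneric("nClasses"))
#' @rdname VimDataset-accessors
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))
#' @rdname VimDataset-accessors
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))
#' @rdname VimDataset-accessors
#' @export
setGeneric("datasetName", function(x) standardGeneric("datasetName"))
#' @rdname VimDataset-accessors
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname oobAccuracy
#' @export
setGeneric("oobAccuracy", function(model, data, ...)
  standardGeneric("oobAccuracy"))
#' @rdname oobSamples
#' @export
setGeneric("oobSamples", function(model) standardGeneric("oobSamples"))
#' @rdname mdaImportance
#' @export
setGeneric("mdaImportance", function(model, data, seed, ...)
  standardGeneric("mdaImportance"))
#' @rdname mdgImportance
#' @export
setGeneric("mdgImportance", function(model, ...)
  standardGeneric("mdgImportance"))
#' @rdname rankFeatures
#' @export
setGeneric("rankFeatures", function(scores, ...)
  standardGeneric("rankFeatures"))

#' @rdname importanceScores-accessors
#' @export
setGeneric("importanceMethod", function(x) standardGeneric("importanceMethod"))
#' @rdname importanceScores-accessors
#' @export
setGeneric("scoreValues", function(x) standardGeneric("scoreValues"))
#' @rdname ranking-accessors
#' @export
setGeneric("rankedFeatures", function(x) standardGeneric("rankedFeatures"))
#' @rdname ranking-accessors
#' @export
setGeneric("featurePositions", function(x) standardGeneric("featurePositions"))

#' @rdname stability-accessors
#' @export
setGeneric("pairwiseValues", function(x, ...) standardGeneric("pairwiseValues"))
#' @rdname stability-accessors
#' @export
setGeneric("stabilityMean", function(x, ...) standardGeneric("stabilityMean"))
#' @rdname stability-accessors
#' @export
setGeneric("stabilityVariance", function(x, ...)
  standardGeneric("stabilityVariance"))
#' @rdname stability-accessors
#' @export
setGeneric("nRuns", function(x) standardGeneric("nRuns"))

#' @rdname computeIndicators
#' @export
setGeneric("computeIndicators", function(data, model, ...)
  standardGeneric("computeIndicators"))
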