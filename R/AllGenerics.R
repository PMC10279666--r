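#' @rdname learningRate
#' @export
setGeneric("learningRate", function(config, epoch) standardGeneric("learningRate"))

#' @rdname snapshotEpochs
#' @export
setGeneric("snapshotEpochs", function(config) standardGeneric("snapshotEpochs"))

#' @rdname scheduleTable
#' @export
setGeneric("scheduleTable", function(config, file = NULL) standardGeneric("scheduleTable"))

#' @rdname SnapshotSet-accessors
#' @export
setGeneric("checkpoints", function(x) standardGeneric("checkpoints"))

#' @rdname SnapshotSet-accessors
#' @export
setGeneric("valAccuracy", function(x) standardGeneric("valAccuracy"))

#' @rdname SnapshotSet-accessors
#' @export
setGeneric("trainingLog", function(x) standardGeneric("trainingLog"))

#' @rdname FeatureMatrix-accessors
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @rdname FeatureMatrix-accessors
#' @export
setGeneric("sampleLabels", function(x) standardGeneric("sampleLabels"))

#' @rdname FeatureMatrix-accessors
#' @export
setGeneric("splitTag", function(x) standardGeneric("splitTag"))

#' @rdname FeatureMatrix-accessors
#' @export
setGeneric("snapshotBlocks", function(x) standardGeneric("snapshotBlocks"))

#' @rdname FeatureMatrix-accessors
#' @export
setGeneric("featureDim", function(x) standardGeneric("featureDim"))

#' @rdname FSResult-accessors
#' @export
setGeneric("selectionMask", function(x) standardGeneric("selectionMask"))

#' @rdname FSResult-accessors
#' @export
setGeneric("bestFitness", function(x) standardGeneric("bestFitness"))

#' @rdname FSResult-accessors
#' @export
setGeneric("gbestHistory", function(x) standardGeneric("gbestHistory"))

#' @rdname EvalReport-accessors
#' @export
setGeneric("accuracyOf", function(x) standardGeneric("accuracyOf"))

#' @rdname EvalReport-accessors
#' @export
setGeneric("macroMetrics", function(x) standardGeneric("macroMetrics"))

#' @rdname EvalReport-accessors
#' @export
setGeneric("perClassMetrics", function(x) standardGeneric("perClassMetrics"))

#' @rdname EvalReport-accessors
#' @export
setGeneric("confusionCounts", function(x) standardGeneric("confusionCounts"))
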