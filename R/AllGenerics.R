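# Accessor generics. Slots are never accessed with @ by user code.

#' @rdname LabeledScene-class
#' @param object,x a CentroidSeg S4 object.
#' @export
setGeneric("sceneImage", function(x) standardGeneric("sceneImage"))
#' @rdname LabeledScene-class
#' @export
setGeneric("instanceMap", function(x) standardGeneric("instanceMap"))
#' @rdname LabeledScene-class
#' @export
setGeneric("partMap", function(x) standardGeneric("partMap"))
#' @rdname LabeledScene-class
#' @export
setGeneric("instrumentTypes", function(x) standardGeneric("instrumentTypes"))
#' @rdname LabeledScene-class
#' @export
setGeneric("clasperVisible", function(x) standardGeneric("clasperVisible"))
#' @rdname LabeledScene-class
#' @export
setGeneric("frameId", function(x) standardGeneric("frameId"))

#' @rdname TargetBundle-class
#' @param x a CentroidSeg S4 object.
#' @export
setGeneric("partTarget", function(x) standardGeneric("partTarget"))
#' @rdname TargetBundle-class
#' @export
setGeneric("offsetTarget", function(x) standardGeneric("offsetTarget"))
#' @rdname TargetBundle-class
#' @export
setGeneric("heatmapTarget", function(x) standardGeneric("heatmapTarget"))
#' @rdname TargetBundle-class
#' @export
setGeneric("centroidList", function(x) standardGeneric("centroidList"))
#' @rdname TargetBundle-class
#' @export
setGeneric("foregroundMask", function(x) standardGeneric("foregroundMask"))

#' @rdname PredictionBundle-class
#' @param x a CentroidSeg S4 object.
#' @export
setGeneric("partLogits", function(x) standardGeneric("partLogits"))
#' @rdname PredictionBundle-class
#' @export
setGeneric("partProbs", function(x) standardGeneric("partProbs"))
#' @rdname PredictionBundle-class
#' @export
setGeneric("offsetField", function(x) standardGeneric("offsetField"))
#' @rdname PredictionBundle-class
#' @export
setGeneric("heatmap", function(x) standardGeneric("heatmap"))
#' @rdname PredictionBundle-class
#' @export
setGeneric("fSeg", function(x) standardGeneric("fSeg"))

#' @rdname InstanceResult-class
#' @param x a CentroidSeg S4 object.
#' @export
setGeneric("centroids", function(x) standardGeneric("centroids"))
#' @rdname InstanceResult-class
#' @export
setGeneric("classProbs", function(x) standardGeneric("classProbs"))
#' @rdname InstanceResult-class
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))
#' @rdname InstanceResult-class
#' @export
setGeneric("detectionScores", function(x) standardGeneric("detectionScores"))

#' @rdname EvalReport-class
#' @param x a CentroidSeg S4 object.
#' @export
setGeneric("typesMIoU", function(x) standardGeneric("typesMIoU"))
#' @rdname EvalReport-class
#' @export
setGeneric("partsMIoU", function(x) standardGeneric("partsMIoU"))
#' @rdname EvalReport-class
#' @export
setGeneric("maskMAPScore", function(x) standardGeneric("maskMAPScore"))
#' @rdname EvalReport-class
#' @export
setGeneric("perFrameMIoU", function(x) standardGeneric("perFrameMIoU"))
#' @rdname EvalReport-class
#' @export
setGeneric("perClassAP", function(x) standardGeneric("perClassAP"))

#' @rdname LabeledScene-class
#' @export
setMethod("sceneImage", "LabeledScene", function(x) x@image)
#' @rdname LabeledScene-class
#' @export
setMethod("instanceMap", "LabeledScene", function(x) x@instanceMap)
#' @rdname InstanceResult-class
#' @export
setMethod("instanceMap", "InstanceResult", function(x) x@instanceMap)
#' @rdname LabeledScene-class
#' @export
setMethod("partMap", "LabeledScene", function(x) x@partMap)
#' @rdname LabeledScene-class
#' @export
setMethod("instrumentTypes", "LabeledScene", function(x) x@types)
#' @rdname LabeledScene-class
#' @export
setMethod("clasperVisible", "LabeledScene", function(x) x@clasperVisible)
#' @rdname LabeledScene-class
#' @export
setMethod("frameId", "LabeledScene", function(x) x@frameId)

#' @rdname TargetBundle-class
#' @export
setMethod("partTarget", "TargetBundle", function(x) x@partTarget)
#' @rdname TargetBundle-class
#' @export
setMethod("offsetTarget", "TargetBundle", function(x) x@offsetTarget)
#' @rdname TargetBundle-class
#' @export
setMethod("heatmapTarget", "TargetBundle", function(x) x@heatmapTarget)
#' @rdname TargetBundle-class
#' @export
setMethod("centroidList", "TargetBundle", function(x) x@centroidList)
#' @rdname TargetBundle-class
#' @export
setMethod("foregroundMask", "TargetBundle", function(x) x@foregroundMask)

#' @rdname PredictionBundle-class
#' @export
setMethod("partLogits", "PredictionBundle", function(x) x@partLogits)
#' @rdname PredictionBundle-class
#' @export
setMethod("partProbs", "PredictionBundle", function(x) x@partProbs)
#' @rdname PredictionBundle-class
#' @export
setMethod("offsetField", "PredictionBundle", function(x) x@offsets)
#' @rdname PredictionBundle-class
#' @export
setMethod("heatmap", "PredictionBundle", function(x) x@heatmap)
#' @rdname PredictionBundle-class
#' @export
setMethod("fSeg", "PredictionBundle", function(x) x@fSeg)

#' @rdname InstanceResult-class
#' @export
setMethod("centroids", "InstanceResult", function(x) x@centroids)
#' @rdname InstanceResult-class
#' @export
setMethod("classProbs", "InstanceResult", function(x) x@classProbs)
#' @rdname InstanceResult-class
#' @export
setMethod("classLabels", "InstanceResult", function(x) x@classLabel)
#' @rdname InstanceResult-class
#' @export
setMethod("detectionScores", "InstanceResult", function(x) x@detectionScore)

#' @rdname EvalReport-class
#' @export
setMethod("typesMIoU", "EvalReport", function(x) x@typesMIoU)
#' @rdname EvalReport-class
#' @export
setMethod("partsMIoU", "EvalReport", function(x) x@partsMIoU)
#' @rdname EvalReport-class
#' @export
setMethod("maskMAPScore", "EvalReport", function(x) x@mAP5095)
#' @rdname EvalReport-class
#' @export
setMethod("perFrameMIoU", "EvalReport", function(x) x@perFrameMIoU)
#' @rdname EvalReport-class
#' @export
setMethod("perClassAP", "EvalReport", function(x) x@perClassAP)
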