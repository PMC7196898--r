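# Accessor generics: slots are never reached into from user code.

#' @rdname ImageStack-class
#' @param x an object.
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))
#' @rdname ImageStack-class
#' @export
setMethod("voxels", "ImageStack", function(x) x@voxels)

#' @rdname ImageStack-class
#' @export
setGeneric("pixelSizeXY", function(x) standardGeneric("pixelSizeXY"))
#' @rdname ImageStack-class
#' @export
setMethod("pixelSizeXY", "ImageStack", function(x) x@pixelSizeXY)

#' @rdname ImageStack-class
#' @export
setGeneric("zStep", function(x) standardGeneric("zStep"))
#' @rdname ImageStack-class
#' @export
setMethod("zStep", "ImageStack", function(x) x@zStep)

#' @rdname SpotSet-class
#' @param x an object.
#' @export
setGeneric("spotTable", function(x) standardGeneric("spotTable"))
#' @rdname SpotSet-class
#' @export
setMethod("spotTable", "SpotSet", function(x) x@spots)

#' @rdname SpotSet-class
#' @export
setGeneric("nSpots", function(x) standardGeneric("nSpots"))
#' @rdname SpotSet-class
#' @export
setMethod("nSpots", "SpotSet", function(x) x@nSpots)

#' @rdname ROISet-class
#' @param x an object.
#' @export
setGeneric("rois", function(x) standardGeneric("rois"))
#' @rdname ROISet-class
#' @export
setMethod("rois", "ROISet", function(x) x@rois)

#' @rdname DecayHistogram-class
#' @param x an object.
#' @export
setGeneric("binCenters", function(x) standardGeneric("binCenters"))
#' @rdname DecayHistogram-class
#' @export
setMethod("binCenters", "DecayHistogram", function(x) x@binCenters)

#' @rdname DecayHistogram-class
#' @export
setGeneric("photonCounts", function(x) standardGeneric("photonCounts"))
#' @rdname DecayHistogram-class
#' @export
setMethod("photonCounts", "DecayHistogram", function(x) x@counts)

#' @rdname DecayHistogram-class
#' @export
setGeneric("repetitionPeriod", function(x) standardGeneric("repetitionPeriod"))
#' @rdname DecayHistogram-class
#' @export
setMethod("repetitionPeriod", "DecayHistogram", function(x) x@repetitionPeriod)

#' @rdname LifetimeFit-class
#' @param x an object.
#' @export
setGeneric("lifetimes", function(x) standardGeneric("lifetimes"))
#' @rdname LifetimeFit-class
#' @export
setMethod("lifetimes", "LifetimeFit", function(x) x@lifetimes)

#' @rdname LifetimeFit-class
#' @export
setGeneric("amplitudes", function(x) standardGeneric("amplitudes"))
#' @rdname LifetimeFit-class
#' @export
setMethod("amplitudes", "LifetimeFit", function(x) x@amplitudes)

#' @rdname LifetimeFit-class
#' @export
setGeneric("tauAv", function(x) standardGeneric("tauAv"))
#' @rdname LifetimeFit-class
#' @export
setMethod("tauAv", "LifetimeFit", function(x) x@tauAv)

#' @rdname LifetimeFit-class
#' @export
setGeneric("fitDeviance", function(x) standardGeneric("fitDeviance"))
#' @rdname LifetimeFit-class
#' @export
setMethod("fitDeviance", "LifetimeFit", function(x) x@fitDeviance)

#' @rdname PolarizedPair-class
#' @param x an object.
#' @export
setGeneric("iPar", function(x) standardGeneric("iPar"))
#' @rdname PolarizedPair-class
#' @export
setMethod("iPar", "PolarizedPair", function(x) x@iPar)

#' @rdname PolarizedPair-class
#' @export
setGeneric("iPerp", function(x) standardGeneric("iPerp"))
#' @rdname PolarizedPair-class
#' @export
setMethod("iPerp", "PolarizedPair", function(x) x@iPerp)

#' @rdname PolarizedPair-class
#' @export
setGeneric("nFramesMerged", function(x) standardGeneric("nFramesMerged"))
#' @rdname PolarizedPair-class
#' @export
setMethod("nFramesMerged", "PolarizedPair", function(x) x@nFramesMerged)

#' @rdname FrapTrace-class
#' @param x an object.
#' @export
setGeneric("frapTime", function(x) standardGeneric("frapTime"))
#' @rdname FrapTrace-class
#' @export
setMethod("frapTime", "FrapTrace", function(x) x@time)

#' @rdname FrapTrace-class
#' @export
setGeneric("bleachFrameIndex", function(x) standardGeneric("bleachFrameIndex"))
#' @rdname FrapTrace-class
#' @export
setMethod("bleachFrameIndex", "FrapTrace", function(x) x@bleachFrameIndex)
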