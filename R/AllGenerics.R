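#' @name apneaScatter-generics
#' @title Accessor generics
#'
#' @description Accessor generics for the classes in this package. Slot access
#' from user code should always go through these rather than `@`.
#'
#' @param x,object An object of one of the package's classes.
#' @param ... Further arguments for methods.
NULL

#' @rdname apneaScatter-generics
#' @export
setGeneric("recordId", function(x) standardGeneric("recordId"))

#' @rdname apneaScatter-generics
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname apneaScatter-generics
#' @export
setGeneric("ecgSamples", function(x) standardGeneric("ecgSamples"))

#' @rdname apneaScatter-generics
#' @export
setGeneric("minuteLabels", function(x) standardGeneric("minuteLabels"))

#' @rdname apneaScatter-generics
#' @export
setGeneric("segmentMatrix", function(x) standardGeneric("segmentMatrix"))

#' @rdname apneaScatter-generics
#' @export
setGeneric("segmentWeightValues", function(x) standardGeneric("segmentWeightValues"))

#' @rdname apneaScatter-generics
#' @export
setGeneric("similarityMatrix", function(x) standardGeneric("similarityMatrix"))

#' @rdname apneaScatter-generics
#' @export
setGeneric("droppedSegments", function(x) standardGeneric("droppedSegments"))

#' @rdname apneaScatter-generics
#' @export
setGeneric("scatteringPaths", function(x) standardGeneric("scatteringPaths"))

#' @rdname apneaScatter-generics
#' @export
setGeneric("coefficientArray", function(x) standardGeneric("coefficientArray"))

#' @rdname apneaScatter-generics
#' @export
setGeneric("nWindows", function(x) standardGeneric("nWindows"))

#' @rdname apneaScatter-generics
#' @export
setGeneric("scatteringEnergy", function(x, ...) standardGeneric("scatteringEnergy"))

#' @rdname apneaScatter-generics
#' @export
setGeneric("metricSummary", function(x) standardGeneric("metricSummary"))

#' @rdname apneaScatter-generics
#' @export
setGeneric("perRepeatMetrics", function(x) standardGeneric("perRepeatMetrics"))
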