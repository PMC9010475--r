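#' @rdname parcellationGraph
#' @export
setGeneric("regionIds", function(x) standardGeneric("regionIds"))

#' @rdname parcellationGraph
#' @export
setGeneric("hemispheres", function(x) standardGeneric("hemispheres"))

#' @rdname parcellationGraph
#' @export
setGeneric("edgeMatrix", function(x) standardGeneric("edgeMatrix"))

#' @rdname parcellationGraph
#' @export
setGeneric("nRegions", function(x) standardGeneric("nRegions"))

#' @rdname computeSPC
#' @export
setGeneric("computeSPC", function(tp1, tp2, ...) standardGeneric("computeSPC"))

#' @rdname computeRawDiff
#' @export
setGeneric("computeRawDiff",
           function(tp1, tp2, ...) standardGeneric("computeRawDiff"))

#' @rdname changeMatrix-accessors
#' @export
setGeneric("changeValues", function(x) standardGeneric("changeValues"))

#' @rdname changeMatrix-accessors
#' @export
setGeneric("changeMetric", function(x) standardGeneric("changeMetric"))

#' @rdname clusterResult-accessors
#' @export
setGeneric("clusterRegions", function(x) standardGeneric("clusterRegions"))

#' @rdname clusterResult-accessors
#' @export
setGeneric("clusterSizes", function(x) standardGeneric("clusterSizes"))

#' @rdname clusterResult-accessors
#' @export
setGeneric("correctedP", function(x) standardGeneric("correctedP"))

#' @rdname clusterResult-accessors
#' @export
setGeneric("nullMaxSizes", function(x) standardGeneric("nullMaxSizes"))
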