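#' Accessor generics
#'
#' Small accessor family for the package's S4 containers; slots are never
#' reached into directly by user code.
#'
#' @param x an object of one of the package's S4 classes.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))
#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))
#' @rdname accessors
#' @export
setGeneric("channelRoles", function(x) standardGeneric("channelRoles"))
#' @rdname accessors
#' @export
setGeneric("bitDepth", function(x) standardGeneric("bitDepth"))
#' @rdname accessors
#' @export
setGeneric("tracePoints", function(x) standardGeneric("tracePoints"))
#' @rdname accessors
#' @export
setGeneric("timepointIndex", function(x) standardGeneric("timepointIndex"))
#' @rdname accessors
#' @export
setGeneric("maskVoxels", function(x) standardGeneric("maskVoxels"))
#' @rdname accessors
#' @export
setGeneric("thresholdUsed", function(x) standardGeneric("thresholdUsed"))
#' @rdname accessors
#' @export
setGeneric("ratioValues", function(x) standardGeneric("ratioValues"))
#' @rdname accessors
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))
#' @rdname accessors
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))
#' @rdname accessors
#' @export
setGeneric("profilePositions", function(x) standardGeneric("profilePositions"))
#' @rdname accessors
#' @export
setGeneric("binMeans", function(x) standardGeneric("binMeans"))
#' @rdname accessors
#' @export
setGeneric("binRanges", function(x) standardGeneric("binRanges"))
#' @rdname accessors
#' @export
setGeneric("validCounts", function(x) standardGeneric("validCounts"))
#' @rdname accessors
#' @export
setGeneric("condition", function(x) standardGeneric("condition"))
#' @rdname accessors
#' @export
setGeneric("trueTraces", function(x) standardGeneric("trueTraces"))

#' Extract one channel's z-stack at one timepoint
#'
#' @param x a \linkS4class{TimelapseStack}.
#' @param timepoint 1-based timepoint index.
#' @param channel "green" or "red" (resolved through the channel roles).
#' @return 3-D (Z,Y,X) numeric array.
#' @export
setGeneric("channelStack",
           function(x, timepoint, channel) standardGeneric("channelStack"))
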