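#' @rdname accessors
setMethod("frames", "TimelapseStack", function(x) x@frames)
#' @rdname accessors
setMethod("pixelSize", "TimelapseStack", function(x) x@pixelSizeUm)
#' @rdname accessors
setMethod("frameInterval", "TimelapseStack", function(x) x@frameIntervalMin)
#' @rdname accessors
setMethod("channelRoles", "TimelapseStack", function(x) x@channelRoles)
#' @rdname accessors
setMethod("bitDepth", "TimelapseStack", function(x) x@bitDepth)

#' @rdname channelStack
#' @aliases channelStack,TimelapseStack-method
setMethod("channelStack", "TimelapseStack", function(x, timepoint, channel) {
  stopifnot(timepoint >= 1L, timepoint <= dim(x@frames)[1L])
  ch <- x@channelRoles[[match.arg(channel, c("green", "red"))]]
  arr <- x@frames[timepoint, ch, , , , drop = FALSE]
  dim(arr) <- dim(x@frames)[3:5]
  arr
})

#' @rdname accessors
setMethod("tracePoints", "TracePath", function(x) x@points)
#' @rdname accessors
setMethod("timepointIndex", "TracePath", function(x) x@timepointIndex)
#' @rdname accessors
setMethod("maskVoxels", "MaskVolume", function(x) x@voxels)
#' @rdname accessors
setMethod("thresholdUsed", "MaskVolume", function(x) x@thresholdUsed)
#' @rdname accessors
setMethod("ratioValues", "RatioMap", function(x) x@values)
#' @rdname accessors
setMethod("validMask", "RatioMap", function(x) x@valid)
#' @rdname accessors
setMethod("timepointIndex", "RatioMap", function(x) x@timepointIndex)
#' @rdname accessors
setMethod("profileValues", "IntensityProfile", function(x) x@values)
#' @rdname accessors
setMethod("profilePositions", "IntensityProfile", function(x) x@positionsPx)
#' @rdname accessors
setMethod("timepointIndex", "IntensityProfile", function(x) x@timepointIndex)
#' @rdname accessors
setMethod("binMeans", "BinnedProfile", function(x) x@binMeans)
#' @rdname accessors
setMethod("binRanges", "BinnedProfile", function(x) x@binRanges)
#' @rdname accessors
setMethod("validCounts", "BinnedProfile", function(x) x@validCounts)
#' @rdname accessors
setMethod("timepointIndex", "BinnedProfile", function(x) x@timepointIndex)
#' @rdname accessors
setMethod("condition", "GroundTruth", function(x) x@condition)
#' @rdname accessors
setMethod("trueTraces", "GroundTruth", function(x) x@trueTraces)

setMethod("show", "TimelapseStack", function(object) {
  d <- dim(object@frames)
  cat(sprintf("TimelapseStack: %d timepoints x %d channels x %d z x %d x %d px\n",
              d[1], d[2], d[3], d[4], d[5]))
  cat(sprintf("  pixel size %.4f um, interval %g min, %d-bit\n",
              object@pixelSizeUm, object@frameIntervalMin, object@bitDepth))
  cat(sprintf("  channels: green=%d red=%d\n",
              object@channelRoles[["green"]], object@channelRoles[["red"]]))
})

setMethod("show", "TracePath", function(object) {
  cat(sprintf("TracePath: %d points, timepoint %d%s\n",
              nrow(object@points), object@timepointIndex,
              if (object@orientedRetrograde) " (retrograde, tip first)" else ""))
})

setMethod("show", "RatioMap", function(object) {
  cat(sprintf("RatioMap: %d x %d px, timepoint %d, %.1f%% valid (min red %g)\n",
              nrow(object@values), ncol(object@values), object@timepointIndex,
              100 * mean(object@valid), object@minRedUsed))
})

setMethod("show", "MaskVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("MaskVolume: %d x %d x %d, %s threshold %g, %.1f%% foreground\n",
              d[1], d[2], d[3], object@method, object@thresholdUsed,
              100 * mean(object@voxels)))
})

setMethod("show", "BinnedProfile", function(object) {
  cat(sprintf("BinnedProfile: %d bins, timepoint %d\n",
              length(object@binMeans), object@timepointIndex))
  print(round(object@binMeans, 4))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %s, %d timepoints, domain %.1f -> %.1f um\n",
              object@condition, length(object@green),
              max(object@sGridsUm[[1]]),
              max(object@sGridsUm[[length(object@sGridsUm)]])))
})
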