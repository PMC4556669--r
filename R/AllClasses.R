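#' @import methods
NULL

#' TimelapseStack: a calibrated 5-D photoconversion timelapse
#'
#' Container for a two-channel confocal timelapse, stored in canonical
#' \code{(T, C, Z, Y, X)} order.  The green channel holds unconverted Kaede
#' (newly synthesized protein after photoconversion), the red channel the
#' photoconverted pool.
#'
#' @slot frames 5-D numeric array indexed (time, channel, z, y, x); raw
#'   detector counts, non-negative, within the bit-depth range.
#' @slot pixelSizeUm microns per pixel (scalar > 0).
#' @slot frameIntervalMin minutes between consecutive timepoints (> 0).
#' @slot channelRoles named integer vector mapping \code{"green"} and
#'   \code{"red"} to channel indices.
#' @slot bitDepth integer, 8 or 16.
#'
#' @aliases TimelapseStack-class
#' @exportClass TimelapseStack
setClass("TimelapseStack",
  representation(
    frames = "array",
    pixelSizeUm = "numeric",
    frameIntervalMin = "numeric",
    channelRoles = "integer",
    bitDepth = "integer"
  )
)

setValidity("TimelapseStack", function(object) {
  msg <- character()
  d <- dim(object@frames)
  if (length(d) != 5L)
    msg <- c(msg, "frames must be a 5-D (T,C,Z,Y,X) array")
  else {
    if (any(d < 1L)) msg <- c(msg, "all dimensions must be >= 1")
    roles <- object@channelRoles
    if (!setequal(names(roles), c("green", "red")) ||
        length(unique(roles)) != 2L)
      msg <- c(msg, "channelRoles must map 'green' and 'red' to two distinct channels")
    else if (any(roles < 1L | roles > d[2L]))
      msg <- c(msg, "channelRoles out of channel range")
  }
  if (length(object@pixelSizeUm) != 1L || object@pixelSizeUm <= 0)
    msg <- c(msg, "pixelSizeUm must be a positive scalar")
  if (length(object@frameIntervalMin) != 1L || object@frameIntervalMin <= 0)
    msg <- c(msg, "frameIntervalMin must be a positive scalar")
  if (!object@bitDepth %in% c(8L, 16L))
    msg <- c(msg, "bitDepth must be 8 or 16")
  if (length(object@frames) &&
      (min(object@frames) < 0 || max(object@frames) > 2^object@bitDepth - 1))
    msg <- c(msg, "intensities outside bit-depth range")
  if (length(msg)) msg else TRUE
})

#' Construct a TimelapseStack
#'
#' @param frames 5-D array in (T,C,Z,Y,X) order.
#' @param pixelSizeUm microns per pixel; default 32/150 (the assay's trace
#'   calibration, 150 px = 32 um).
#' @param frameIntervalMin minutes between z-stacks; default 10.
#' @param channelRoles named integer vector with elements "green" and "red".
#' @param bitDepth 8 or 16.
#' @return A \linkS4class{TimelapseStack}.
#' @examples
#' a <- array(0, c(2, 2, 1, 4, 4))
#' TimelapseStack(a)
#' @export
TimelapseStack <- function(frames,
                           pixelSizeUm = 32 / 150,
                           frameIntervalMin = 10,
                           channelRoles = c(green = 1L, red = 2L),
                           bitDepth = 16L) {
  new("TimelapseStack", frames = frames, pixelSizeUm = pixelSizeUm,
      frameIntervalMin = frameIntervalMin,
      channelRoles = vapply(channelRoles, as.integer, integer(1)),
      bitDepth = as.integer(bitDepth))
}

#' TracePath: an ordered retrograde neurite trace
#'
#' Coordinates are 0-based (y, x) with origin at the image top-left;
#' sub-pixel values are allowed.  When \code{orientedRetrograde} is TRUE the
#' first point is the growth-cone tip and the trace runs back toward the
#' soma.
#'
#' @slot points numeric matrix with columns \code{y}, \code{x}.
#' @slot timepointIndex 1-based timepoint this trace belongs to.
#' @slot orientedRetrograde logical flag; TRUE when point 1 is the tip.
#' @aliases TracePath-class
#' @exportClass TracePath
setClass("TracePath",
  representation(points = "matrix", timepointIndex = "integer",
                 orientedRetrograde = "logical")
)

setValidity("TracePath", function(object) {
  p <- object@points
  if (!is.numeric(p) || ncol(p) != 2L)
    return("points must be a numeric n x 2 (y, x) matrix")
  if (nrow(p) < 2L) return("a trace needs at least 2 points")
  d <- sqrt(rowSums((p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  if (any(d == 0)) return("consecutive trace points must be distinct")
  TRUE
})

#' Construct a TracePath
#' @param points numeric n x 2 matrix (or data.frame) of (y, x) coordinates,
#'   0-based, tip first.
#' @param timepointIndex 1-based timepoint index.
#' @param orientedRetrograde TRUE when the first point is the growth-cone tip.
#' @return A \linkS4class{TracePath}.
#' @export
TracePath <- function(points, timepointIndex = 1L, orientedRetrograde = TRUE) {
  points <- as.matrix(points)
  colnames(points) <- c("y", "x")
  new("TracePath", points = points, timepointIndex = as.integer(timepointIndex),
      orientedRetrograde = orientedRetrograde)
}

#' MaskVolume: a binary z-stack mask
#'
#' @slot voxels logical 3-D array (Z,Y,X), TRUE = foreground.
#' @slot thresholdUsed intensity threshold that produced the mask.
#' @slot method character, name of the auto-threshold or "manual".
#' @aliases MaskVolume-class
#' @exportClass MaskVolume
setClass("MaskVolume",
  representation(voxels = "array", thresholdUsed = "numeric",
                 method = "character")
)

setValidity("MaskVolume", function(object) {
  if (!is.logical(object@voxels) || length(dim(object@voxels)) != 3L)
    return("voxels must be a logical 3-D array")
  TRUE
})

#' RatioMap: a green/red ratio SUM projection
#'
#' Per-timepoint 2-D image of green/red ratios with an explicit validity
#' mask: the ratio is defined only where the red SUM projection reaches the
#' denominator floor, so no pixel is ever a division by (near-)zero.
#'
#' @slot values numeric matrix of ratios (dimensionless); undefined pixels
#'   hold NA.
#' @slot valid logical matrix, TRUE where the ratio is defined.
#' @slot timepointIndex 1-based timepoint index.
#' @slot minRedUsed denominator floor applied to the red SUM projection.
#' @aliases RatioMap-class
#' @exportClass RatioMap
setClass("RatioMap",
  representation(values = "matrix", valid = "matrix",
                 timepointIndex = "integer", minRedUsed = "numeric")
)

setValidity("RatioMap", function(object) {
  if (!identical(dim(object@values), dim(object@valid)))
    return("values and valid must have identical shape")
  if (any(!is.finite(object@values[object@valid])))
    return("values must be finite wherever valid")
  TRUE
})

#' IntensityProfile: ratio values along the resampled trace
#'
#' @slot positionsPx arc-length positions 1..N from the tip (pixel units).
#' @slot values ratio at each position; NA where the ratio map is invalid.
#' @slot timepointIndex 1-based timepoint index.
#' @slot nPixels N, the number of sampled positions (150 at defaults).
#' @aliases IntensityProfile-class
#' @exportClass IntensityProfile
setClass("IntensityProfile",
  representation(positionsPx = "numeric", values = "numeric",
                 timepointIndex = "integer", nPixels = "integer")
)

setValidity("IntensityProfile", function(object) {
  if (length(object@positionsPx) != length(object@values))
    return("positions and values must have equal length")
  if (length(object@positionsPx) > 1L &&
      any(abs(diff(object@positionsPx) - 1) > 1e-9))
    return("positions must increase with unit spacing")
  TRUE
})

#' BinnedProfile: 10-pixel bin means of a trace profile
#'
#' The unit of all downstream statistics: consecutive 10-pixel stretches of
#' the 150-pixel profile are averaged into 15 bin means, reported with
#' 1-based pixel ranges (1-10, 11-20, ..., 141-150) as in the assay's
#' convention.
#'
#' @slot binMeans numeric bin averages; NA where a bin has no valid pixel.
#' @slot binRanges integer matrix with columns \code{start}, \code{end}
#'   (1-based pixel indices, inclusive).
#' @slot validCounts number of valid pixels entering each mean.
#' @slot timepointIndex 1-based timepoint index.
#' @aliases BinnedProfile-class
#' @exportClass BinnedProfile
setClass("BinnedProfile",
  representation(binMeans = "numeric", binRanges = "matrix",
                 validCounts = "integer", timepointIndex = "integer")
)

setValidity("BinnedProfile", function(object) {
  n <- length(object@binMeans)
  if (nrow(object@binRanges) != n || length(object@validCounts) != n)
    return("binMeans, binRanges and validCounts must agree in length")
  TRUE
})

#' SimulationConfig: parameters of the synthetic photoconversion timelapse
#'
#' Groups geometry, kinetics and imaging parameters for the ground-truthed
#' simulator.  All rates are per minute, lengths in microns unless noted.
#'
#' @slot pathControlPointsPx numeric matrix of (y, x) control points (pixels,
#'   0-based) tracing the axon from soma end to beyond the final tip
#'   position.
#' @slot axonLengthUm initial arc length of the simulated axon domain.
#' @slot axonRadiusUm tube radius used when painting the axon.
#' @slot gcRadiusUm growth-cone disk radius at the tip.
#' @slot tipSpeedUmMin tip advance speed; the domain is extended each frame.
#' @slot tipRegionUm length of the terminal region receiving local synthesis.
#' @slot diffusionUm2Min diffusion coefficient D.
#' @slot transportUmMin anterograde transport speed v (applied to green).
#' @slot somaInflux green influx J at the soma boundary (conc * um / min).
#' @slot kLocal local synthesis rate in the tip region (conc / min).
#' @slot bleachRate red bleaching rate (1 / min); 0 = photostable.
#' @slot residualGreen fraction of green remaining after photoconversion.
#' @slot redInit initial (post-conversion) red concentration.
#' @slot dsUm kinetics grid spacing.
#' @slot psfSigmaUm Gaussian PSF sigma.
#' @slot background per-slice background offset (counts).
#' @slot gain photon counts per concentration unit (summed over z).
#' @slot readNoiseSd Gaussian read noise SD (counts); 0 disables.
#' @slot shotNoise logical; Poisson shot noise on/off.
#' @slot zSlices number of z slices.
#' @slot imageShapePx integer (height, width) of the rendered frame.
#' @slot pixelSizeUm microns per pixel.
#' @slot nTimepoints number of post-conversion stacks.
#' @slot frameIntervalMin minutes between stacks.
#' @slot bitDepth 8 or 16.
#' @slot rngSeed seed for the rendering noise.
#' @aliases SimulationConfig-class
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(
    pathControlPointsPx = "matrix",
    axonLengthUm = "numeric", axonRadiusUm = "numeric",
    gcRadiusUm = "numeric", tipSpeedUmMin = "numeric", tipRegionUm = "numeric",
    diffusionUm2Min = "numeric", transportUmMin = "numeric",
    somaInflux = "numeric", kLocal = "numeric", bleachRate = "numeric",
    residualGreen = "numeric", redInit = "numeric", dsUm = "numeric",
    psfSigmaUm = "numeric", background = "numeric", gain = "numeric",
    readNoiseSd = "numeric", shotNoise = "logical", zSlices = "integer",
    imageShapePx = "integer", pixelSizeUm = "numeric",
    nTimepoints = "integer", frameIntervalMin = "numeric",
    bitDepth = "integer", rngSeed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  rates <- c(object@diffusionUm2Min, object@transportUmMin, object@somaInflux,
             object@kLocal, object@bleachRate, object@tipSpeedUmMin)
  if (any(rates < 0)) msg <- c(msg, "all rates must be >= 0")
  if (object@residualGreen < 0 || object@residualGreen > 1)
    msg <- c(msg, "residualGreen must lie in [0, 1]")
  if (object@dsUm <= 0) msg <- c(msg, "dsUm must be > 0")
  if (object@axonLengthUm < object@tipRegionUm)
    msg <- c(msg, "axon shorter than tip region")
  if (!object@bitDepth %in% c(8L, 16L)) msg <- c(msg, "bitDepth must be 8 or 16")
  if (length(msg)) msg else TRUE
})

#' GroundTruth: simulated concentration fields with true traces
#'
#' The acceptance surface for recovery tests: green and red concentration
#' profiles on the 1-D arc-length grid per timepoint (the domain grows as
#' the tip advances, so grids differ in length across time), plus the true
#' tip-anchored retrograde trace for every timepoint.
#'
#' @slot green list of per-timepoint concentration vectors G(s, t).
#' @slot red list of per-timepoint concentration vectors R(s, t).
#' @slot sGridsUm list of arc-length cell-center grids (um from the soma).
#' @slot trueTraces list of \linkS4class{TracePath}, one per timepoint.
#' @slot condition "+UTR" or "-UTR".
#' @slot config the \linkS4class{SimulationConfig} that produced the truth.
#' @aliases GroundTruth-class
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(green = "list", red = "list", sGridsUm = "list",
                 trueTraces = "list", condition = "character",
                 config = "SimulationConfig")
)

setValidity("GroundTruth", function(object) {
  nT <- length(object@green)
  if (length(object@red) != nT || length(object@sGridsUm) != nT)
    return("green, red and sGridsUm must have one entry per timepoint")
  if (any(vapply(object@green, function(g) any(g < -1e-12), logical(1))) ||
      any(vapply(object@red, function(r) any(r < -1e-12), logical(1))))
    return("concentrations must be non-negative")
  TRUE
})
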