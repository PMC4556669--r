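#' Resample a trace to unit pixel spacing
#'
#' Arc-length parameterizes the retrograde polyline and returns points at
#' exact \code{stepPx} spacing starting at the growth-cone tip (the tip is
#' preserved as point 1), truncated to \code{nPixels} points.  The result is
#' independent of the vertex density of the input polyline.
#'
#' @param trace a \linkS4class{TracePath}, tip first.
#' @param stepPx spacing between resampled points (pixels); default 1.
#' @param nPixels number of points to keep; default 150 (= 32 um at the
#'   default calibration).
#' @return A \linkS4class{TracePath} of exactly \code{nPixels} points.
#' @export
resampleTrace <- function(trace, stepPx = 1.0, nPixels = 150L) {
  pts <- tracePoints(trace)
  total <- .arcLength(pts)[nrow(pts)]
  need <- (nPixels - 1L) * stepPx
  if (total < need - 1e-9)
    .stopf("trace too short: %.2f px available, %.2f px required",
           total, need)
  at <- seq(0, by = stepPx, length.out = nPixels)
  TracePath(.pointAtArc(pts, at), timepointIndex = timepointIndex(trace),
            orientedRetrograde = trace@orientedRetrograde)
}

#' Sample a ratio map along a resampled trace
#'
#' \code{nearest} (default) replicates literal pixel lookup: each trace
#' point reads the pixel whose center is closest, as the original
#' macro-based measurement did.  \code{bilinear} interpolates the four
#' neighboring pixels for sub-pixel traces; at integer coordinates the two
#' agree.  Invalid ratio pixels propagate as NA profile entries.
#'
#' @param ratio a \linkS4class{RatioMap}.
#' @param trace a resampled \linkS4class{TracePath} within image bounds.
#' @param interpolation "nearest" or "bilinear".
#' @return An \linkS4class{IntensityProfile}; positions are 1..N from the
#'   tip.
#' @export
sampleProfile <- function(ratio, trace,
                          interpolation = c("nearest", "bilinear")) {
  interpolation <- match.arg(interpolation)
  pts <- tracePoints(trace)
  vals <- ratioValues(ratio)
  ny <- nrow(vals); nx <- ncol(vals)
  # 0-based coordinates -> 1-based matrix indices
  yi <- pts[, 1L] + 1; xi <- pts[, 2L] + 1
  if (any(round(yi) < 1 | round(yi) > ny | round(xi) < 1 | round(xi) > nx))
    .stopf("trace point out of image bounds (%d x %d)", ny, nx)
  v <- if (interpolation == "nearest") {
    vals[cbind(round(yi), round(xi))]
  } else {
    y0 <- pmin(pmax(floor(yi), 1), ny); y1 <- pmin(y0 + 1, ny)
    x0 <- pmin(pmax(floor(xi), 1), nx); x1 <- pmin(x0 + 1, nx)
    fy <- yi - y0; fx <- xi - x0
    (1 - fy) * (1 - fx) * vals[cbind(y0, x0)] +
      (1 - fy) * fx     * vals[cbind(y0, x1)] +
      fy       * (1 - fx) * vals[cbind(y1, x0)] +
      fy       * fx     * vals[cbind(y1, x1)]
  }
  new("IntensityProfile", positionsPx = seq_along(v), values = as.numeric(v),
      timepointIndex = timepointIndex(trace), nPixels = length(v))
}

#' Average a profile into consecutive pixel bins
#'
#' Averages each \code{width} consecutive pixels (1-10, 11-20, ...) into one
#' bin mean; a 150-pixel profile at the default width yields the assay's 15
#' values.  NA (invalid) pixels are excluded from their bin's mean; a bin
#' with no valid pixel is reported as NA with a zero valid count.  A
#' trailing remainder shorter than \code{width} is dropped with a warning.
#'
#' @param profile an \linkS4class{IntensityProfile}.
#' @param width bin width in pixels (default 10).
#' @return A \linkS4class{BinnedProfile}.
#' @export
binProfile <- function(profile, width = 10L) {
  if (width < 1L) .stopf("bin width must be >= 1")
  v <- profileValues(profile)
  n <- length(v)
  nBins <- n %/% width
  if (n %% width != 0L)
    .warnf("profile length %d not divisible by %d; dropping trailing %d pixels",
           n, width, n %% width)
  idx <- rep(seq_len(nBins), each = width)
  v <- v[seq_len(nBins * width)]
  means <- vapply(split(v, idx), function(b) {
    if (all(is.na(b))) NA_real_ else mean(b, na.rm = TRUE)
  }, numeric(1))
  counts <- vapply(split(v, idx), function(b) sum(!is.na(b)), integer(1))
  ranges <- cbind(start = (seq_len(nBins) - 1L) * width + 1L,
                  end = seq_len(nBins) * width)
  new("BinnedProfile", binMeans = unname(means), binRanges = ranges,
      validCounts = unname(counts), timepointIndex = timepointIndex(profile))
}

#' Bin-center positions of a binned profile
#'
#' Centers of the 1-based pixel ranges: 5.5, 15.5, ..., 145.5 at defaults.
#' These are the position axis of the spatial-gradient regression.
#'
#' @param binned a \linkS4class{BinnedProfile}.
#' @param unit "px" or "um".
#' @param pixelSizeUm calibration, required for \code{unit = "um"}.
#' @return numeric vector of bin centers.
#' @export
binCenters <- function(binned, unit = c("px", "um"), pixelSizeUm = 32 / 150) {
  unit <- match.arg(unit)
  ctr <- rowMeans(binRanges(binned))
  if (unit == "um") ctr * pixelSizeUm else ctr
}
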