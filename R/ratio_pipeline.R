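#' Binarize the red z-stack
#'
#' Thresholds one timepoint's red channel into a binary mask; foreground is
#' every voxel at or above the threshold.  Auto-thresholds operate on the
#' discrete intensity histogram (exact integer levels when the data carry at
#' most 4096 distinct values, 256 equal-width bins otherwise, mirroring the
#' 8-bit histogram convention of common image software).
#'
#' @param redZstack 3-D (Z,Y,X) numeric array.
#' @param method "otsu" (default), "isodata" or "manual".
#' @param manualThreshold threshold for \code{method = "manual"}.
#' @return A \linkS4class{MaskVolume}.
#' @export
binarizeRed <- function(redZstack, method = c("otsu", "isodata", "manual"),
                        manualThreshold = NULL) {
  method <- match.arg(method)
  if (length(redZstack) == 0L) .stopf("empty stack")
  if (length(dim(redZstack)) != 3L) .stopf("redZstack must be 3-D (Z,Y,X)")
  flat <- diff(range(redZstack)) == 0
  thr <- switch(method,
    manual = {
      if (is.null(manualThreshold))
        .stopf("manual method requires manualThreshold")
      manualThreshold
    },
    otsu = otsuThreshold(as.vector(redZstack)),
    isodata = isodataThreshold(as.vector(redZstack)))
  # a contrast-free stack has no foreground under any auto-threshold
  vox <- if (flat && method != "manual") array(FALSE, dim(redZstack))
         else redZstack >= thr
  dim(vox) <- dim(redZstack)
  new("MaskVolume", voxels = vox, thresholdUsed = as.numeric(thr),
      method = method)
}

# discrete histogram used by both auto-thresholds: returns level values and
# counts; for heavily quantized data the levels are the exact unique values
.intensityLevels <- function(x) {
  ux <- sort(unique(x))
  if (length(ux) <= 4096L) {
    list(levels = ux, counts = tabulate(match(x, ux), length(ux)))
  } else {
    br <- seq(min(x), max(x), length.out = 257L)
    cnt <- tabulate(findInterval(x, br, rightmost.closed = TRUE), 256L)
    list(levels = (br[-257L] + br[-1L]) / 2, counts = cnt)
  }
}

#' Otsu's threshold
#'
#' Maximizes the between-class variance over all histogram cut points; the
#' returned threshold is the midpoint between the last background level and
#' the first foreground level, so \code{x >= threshold} selects the
#' foreground class.  Ties take the lowest maximizing cut.
#'
#' @param x numeric vector (or array) of intensities.
#' @return scalar threshold.
#' @export
otsuThreshold <- function(x) {
  h <- .intensityLevels(as.vector(x))
  lv <- h$levels; cnt <- h$counts
  if (length(lv) == 1L) return(lv)
  w <- cnt / sum(cnt)
  mu <- cumsum(w * lv)
  om <- cumsum(w)
  muT <- mu[length(mu)]
  # cut after level k: classes {<=k}, {>k}
  k <- seq_len(length(lv) - 1L)
  sb <- (muT * om[k] - mu[k])^2 / (om[k] * (1 - om[k]))
  sb[!is.finite(sb)] <- -Inf
  best <- which.max(sb)
  (lv[best] + lv[best + 1L]) / 2
}

#' Isodata (intermeans) threshold
#'
#' Iterates threshold = mean of the two class means until stable; the ImageJ
#' default auto-threshold follows the same scheme.
#'
#' @param x numeric vector (or array) of intensities.
#' @param maxIter iteration cap.
#' @return scalar threshold.
#' @export
isodataThreshold <- function(x, maxIter = 100L) {
  x <- as.vector(x)
  if (length(unique(x)) == 1L) return(x[1L])
  thr <- mean(range(x))
  for (i in seq_len(maxIter)) {
    lo <- x[x < thr]; hi <- x[x >= thr]
    if (!length(lo) || !length(hi)) break
    newThr <- (mean(lo) + mean(hi)) / 2
    if (abs(newThr - thr) < 1e-9) { thr <- newThr; break }
    thr <- newThr
  }
  thr
}

#' Edit the green stack with the red mask
#'
#' \code{restrict} (default) keeps green only inside the red-positive axon
#' (voxels outside the mask are zeroed), which is the measurement-preserving
#' reading of "mask subtraction": downstream ratios remain finite along the
#' axon.  \code{literal_subtract} reproduces 8/16-bit image-calculator
#' arithmetic exactly: the mask at full bit-depth intensity is subtracted
#' from green and clamped at zero.
#'
#' @param greenZstack 3-D (Z,Y,X) numeric array.
#' @param mask \linkS4class{MaskVolume} of identical shape.
#' @param mode "restrict" or "literal_subtract".
#' @param maxIntensity mask foreground intensity for literal subtraction
#'   (default 255, the 8-bit mask convention).
#' @return edited 3-D array.
#' @export
editGreen <- function(greenZstack, mask,
                      mode = c("restrict", "literal_subtract"),
                      maxIntensity = 255) {
  mode <- match.arg(mode)
  vox <- maskVoxels(mask)
  if (!identical(dim(greenZstack), dim(vox)))
    .stopf("shape mismatch: green %s vs mask %s",
           paste(dim(greenZstack), collapse = "x"),
           paste(dim(vox), collapse = "x"))
  if (mode == "restrict") {
    out <- greenZstack * vox
  } else {
    out <- pmax(greenZstack - vox * maxIntensity, 0)
    dim(out) <- dim(greenZstack)
  }
  out
}

#' SUM projection of a z-stack
#'
#' Per-pixel sum over z, computed in doubles so 16-bit inputs cannot clip
#' (the ImageJ SUM projection promotes to 32-bit the same way).
#'
#' @param zstack 3-D (Z,Y,X) numeric array.
#' @return 2-D (Y,X) matrix.
#' @export
sumProject <- function(zstack) {
  if (length(dim(zstack)) != 3L) .stopf("zstack must be 3-D (Z,Y,X)")
  colSums(zstack, dims = 1L)
}

#' Green/red ratio SUM projection
#'
#' Divides the green SUM projection by the red SUM projection wherever the
#' red denominator reaches \code{minRed}; elsewhere the ratio is undefined
#' and flagged invalid (never a division by zero).
#'
#' @param greenSum,redSum 2-D matrices of equal shape.
#' @param minRed denominator floor (> 0); default 1 count.
#' @param timepointIndex recorded in the result.
#' @return A \linkS4class{RatioMap}.
#' @export
computeRatio <- function(greenSum, redSum, minRed = 1, timepointIndex = 1L) {
  if (!identical(dim(greenSum), dim(redSum)))
    .stopf("shape mismatch between green and red projections")
  if (minRed <= 0) .stopf("minRed must be > 0")
  valid <- redSum >= minRed
  vals <- matrix(NA_real_, nrow(greenSum), ncol(greenSum))
  vals[valid] <- greenSum[valid] / redSum[valid]
  new("RatioMap", values = vals, valid = valid,
      timepointIndex = as.integer(timepointIndex), minRedUsed = minRed)
}

#' One timepoint's full ratio pipeline
#'
#' Convenience wrapper chaining \code{\link{binarizeRed}},
#' \code{\link{editGreen}}, \code{\link{sumProject}} and
#' \code{\link{computeRatio}} for one timepoint of a
#' \linkS4class{TimelapseStack}.
#'
#' @param stack a \linkS4class{TimelapseStack}.
#' @param timepoint 1-based timepoint.
#' @param method auto-threshold method for the red mask.
#' @param mode green-edit mode.
#' @param minRed denominator floor.
#' @param manualThreshold optional manual threshold.
#' @return A \linkS4class{RatioMap}.
#' @export
ratioAtTimepoint <- function(stack, timepoint, method = "otsu",
                             mode = "restrict", minRed = 1,
                             manualThreshold = NULL) {
  red <- channelStack(stack, timepoint, "red")
  green <- channelStack(stack, timepoint, "green")
  mask <- binarizeRed(red, method = method, manualThreshold = manualThreshold)
  green <- editGreen(green, mask, mode = mode,
                     maxIntensity = 2^bitDepth(stack) - 1)
  computeRatio(sumProject(green), sumProject(red), minRed = minRed,
               timepointIndex = timepoint)
}

#' Write a ratio map (values + validity) as 32-bit float TIFFs
#'
#' @param ratio a \linkS4class{RatioMap}.
#' @param path output TIFF for the values; the validity mask goes to
#'   \code{<stem>_valid.tif}.
#' @param scale values are divided by \code{scale} before writing (the TIFF
#'   float writer expects [0,1]); default the max finite value.
#' @return \code{path}, invisibly.
#' @export
writeRatioMap <- function(ratio, path, scale = NULL) {
  v <- ratioValues(ratio)
  if (is.null(scale)) scale <- max(v[validMask(ratio)], 1e-12)
  v[!validMask(ratio)] <- 0
  tiff::writeTIFF(pmin(v / scale, 1), path, bits.per.sample = 32L,
                  compression = "none", reduce = FALSE)
  tiff::writeTIFF(validMask(ratio) * 1, sub("(\\.[^.]+)$", "_valid\\1", path),
                  bits.per.sample = 8L, compression = "none", reduce = FALSE)
  invisible(path)
}
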