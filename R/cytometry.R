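#' Detect bright spots in a 3-D volume (multiscale LoG)
#'
#' Scale-normalized Laplacian-of-Gaussian blob detection: the volume is
#' smoothed with separable 3-D Gaussians over a ladder of scales spanning
#' the configured blob-radius range (radius = sigma * sqrt(3) for a 3-D
#' blob), the negated scale-normalized Laplacian response is computed, and
#' bright-blob maxima above a threshold given as a fraction of the maximum
#' response are kept after non-maximum suppression at the minimum
#' separation.  Deterministic; intensity rescaling of the volume leaves the
#' detection set unchanged because the threshold is relative.
#'
#' @param volume 3-D (Z,Y,X) numeric array.
#' @param scaleRangeUm blob radius range searched, default \code{c(2, 6)}
#'   (cell-nucleus scale).
#' @param voxelSizeUm isotropic voxel size (default 1).
#' @param responseThreshold fraction of the maximum LoG response required
#'   (default 0.3); must be > 0.
#' @param minSeparationUm minimum center-to-center distance between reported
#'   spots; default the lower scale bound.
#' @param nScales number of scales in the ladder.
#' @return list of class \code{SpotDetection}: \code{centroids} (n x 3
#'   matrix of (z,y,x) voxel coordinates, 1-based), \code{scales} (detected
#'   blob radius per spot, um) and \code{intensities} (peak response).
#' @export
detectSpots <- function(volume, scaleRangeUm = c(2, 6), voxelSizeUm = 1,
                        responseThreshold = 0.3, minSeparationUm = NULL,
                        nScales = 4L) {
  if (length(volume) == 0L || length(dim(volume)) != 3L)
    .stopf("volume must be a non-empty 3-D array")
  if (responseThreshold <= 0) .stopf("responseThreshold must be > 0")
  if (any(scaleRangeUm <= 0)) .stopf("scale range must be positive")
  if (is.null(minSeparationUm)) minSeparationUm <- min(scaleRangeUm)
  d <- dim(volume)
  radii <- seq(min(scaleRangeUm), max(scaleRangeUm), length.out = nScales)
  sigmasVox <- radii / sqrt(3) / voxelSizeUm
  resp <- vector("list", length(sigmasVox))
  for (k in seq_along(sigmasVox)) {
    sm <- .gaussSmooth3d(volume, sigmasVox[k])
    lap <- .secondDiff3d(sm, 1L) + .secondDiff3d(sm, 2L) + .secondDiff3d(sm, 3L)
    resp[[k]] <- -sigmasVox[k]^2 * lap  # bright blobs -> positive response
  }
  maxResp <- max(vapply(resp, max, numeric(1)))
  # a contrast-free volume produces only numerical-noise responses; the
  # floor is relative to the intensity range so rescaling cannot change it
  if (maxResp <= max(1e-12, 1e-8 * diff(range(volume))))
    return(structure(list(centroids = matrix(numeric(0), 0L, 3L,
                                             dimnames = list(NULL, c("z", "y", "x"))),
                          scales = numeric(0), intensities = numeric(0)),
                     class = "SpotDetection"))
  thr <- responseThreshold * maxResp
  cand <- NULL
  for (k in seq_along(resp)) {
    r <- resp[[k]]
    # 6-neighborhood local maxima along each axis (strictly >= neighbors)
    isMax <- r >= thr
    for (ax in 1:3) {
      n <- d[ax]
      up <- pmin(seq_len(n) + 1L, n); dn <- pmax(seq_len(n) - 1L, 1L)
      sel <- function(ord) switch(ax, r[ord, , , drop = FALSE],
                                  r[, ord, , drop = FALSE],
                                  r[, , ord, drop = FALSE])
      isMax <- isMax & (r >= array(sel(up), d)) & (r >= array(sel(dn), d))
    }
    w <- which(isMax, arr.ind = TRUE)
    if (nrow(w)) {
      cand <- rbind(cand, cbind(w, response = r[w], radius = radii[k]))
    }
  }
  if (is.null(cand) || nrow(cand) == 0L)
    return(structure(list(centroids = matrix(numeric(0), 0L, 3L,
                                             dimnames = list(NULL, c("z", "y", "x"))),
                          scales = numeric(0), intensities = numeric(0)),
                     class = "SpotDetection"))
  cand <- cand[order(-cand[, "response"]), , drop = FALSE]
  sepVox <- minSeparationUm / voxelSizeUm
  kept <- matrix(numeric(0), 0L, 3L)
  keptRows <- integer(0)
  for (i in seq_len(nrow(cand))) {
    p <- cand[i, 1:3]
    if (nrow(kept) == 0L ||
        all(sqrt(rowSums((kept - matrix(p, nrow(kept), 3L, byrow = TRUE))^2)) >=
            sepVox)) {
      kept <- rbind(kept, p)
      keptRows <- c(keptRows, i)
    }
  }
  centroids <- unname(cand[keptRows, 1:3, drop = FALSE])
  colnames(centroids) <- c("z", "y", "x")
  structure(list(centroids = centroids,
                 scales = unname(cand[keptRows, "radius"]),
                 intensities = unname(cand[keptRows, "response"])),
            class = "SpotDetection")
}

#' @export
print.SpotDetection <- function(x, ...) {
  cat(sprintf("SpotDetection: %d spots\n", nrow(x$centroids)))
  if (nrow(x$centroids))
    print(utils::head(cbind(x$centroids, radius_um = x$scales), 10L))
  invisible(x)
}

#' Exclude spots inside a region and count the remainder
#'
#' Removes detections whose centroid falls inside the exclusion geometry
#' (the counting convention "retina only, not lens or extraocular tissue").
#' Bookkeeping is exact: \code{n_counted = n_total - n_excluded}.
#'
#' @param spots a \code{SpotDetection}.
#' @param exclusion either a logical 3-D array (TRUE = excluded) matching
#'   the source volume, or a list \code{list(center = c(z,y,x), radius)}
#'   describing a spherical ROI in voxel units, or NULL for no exclusion.
#' @return list of class \code{CountResult}: n_total, n_excluded, n_counted,
#'   exclusion description, and the retained centroids.
#' @export
applyExclusion <- function(spots, exclusion = NULL) {
  cen <- spots$centroids
  nTotal <- nrow(cen)
  if (is.null(exclusion)) {
    inside <- rep(FALSE, nTotal)
    descr <- "none"
  } else if (is.array(exclusion)) {
    idx <- matrix(pmax(1L, round(cen)), ncol = 3L)
    for (j in 1:3) idx[, j] <- pmin(idx[, j], dim(exclusion)[j])
    inside <- if (nTotal) exclusion[idx] else logical(0)
    descr <- "binary volume"
  } else {
    dd <- sweep(cen, 2L, exclusion$center)
    inside <- sqrt(rowSums(dd^2)) <= exclusion$radius
    descr <- sprintf("sphere r=%g at (%s)", exclusion$radius,
                     paste(exclusion$center, collapse = ","))
  }
  structure(list(n_total = nTotal, n_excluded = sum(inside),
                 n_counted = nTotal - sum(inside), exclusion = descr,
                 centroids = cen[!inside, , drop = FALSE]),
            class = "CountResult")
}

#' @export
print.CountResult <- function(x, ...) {
  cat(sprintf("CountResult: %d counted (%d detected - %d excluded; exclusion: %s)\n",
              x$n_counted, x$n_total, x$n_excluded, x$exclusion))
  invisible(x)
}

#' Axon-to-soma labeling ratio
#'
#' Percentage of labeled axons per labeled cell body for one or more
#' retinotectal projections, with the group mean +/- SEM across
#' tectum-eye pairs.
#'
#' @param nAxons,nSomata integer vectors (parallel, one entry per
#'   projection); every \code{nSomata} must be >= 1.
#' @param pairIds optional projection identifiers.
#' @return list: \code{perProjection} data.frame (pair_id, n_axons,
#'   n_somata, percent) and \code{summary} (mean, sem, n).
#' @examples
#' axonSomaRatio(6, 16)$perProjection$percent  # 37.5
#' @export
axonSomaRatio <- function(nAxons, nSomata, pairIds = NULL) {
  if (length(nAxons) != length(nSomata))
    .stopf("nAxons and nSomata must be parallel vectors")
  if (any(nSomata < 1)) .stopf("every projection needs n_somata >= 1")
  if (is.null(pairIds)) pairIds <- sprintf("pair%02d", seq_along(nAxons))
  pct <- 100 * nAxons / nSomata
  list(perProjection = data.frame(pair_id = pairIds, n_axons = nAxons,
                                  n_somata = nSomata, percent = pct),
       summary = c(mean = mean(pct),
                   sem = if (length(pct) > 1)
                     stats::sd(pct) / sqrt(length(pct)) else NA_real_,
                   n = length(pct)))
}
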