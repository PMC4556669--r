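#' Build a simulation configuration
#'
#' Constructor for \linkS4class{SimulationConfig} with the study's
#' acquisition defaults (10 z-stacks at 10-minute intervals, 32/150 um
#' pixels, two channels, 5 z-slices) and kinetic defaults chosen to
#' reproduce the qualitative in vivo picture: in +UTR axons the growth-cone
#' green/red ratio climbs well above its starting level within 90 minutes,
#' while -UTR axons stay near-flat because soma-derived green protein
#' cannot reach the measured window in that time.  In vivo kinetic rates
#' are unknown; these defaults are illustrative, not measured (see the
#' methods vignette).
#'
#' @param ... named slot overrides, e.g. \code{kLocal = 0} for a -UTR axon.
#' @return A \linkS4class{SimulationConfig}.
#' @examples
#' cfg <- simulationConfig(kLocal = 0, rngSeed = 7L)
#' @export
simulationConfig <- function(...) {
  defaults <- list(
    pathControlPointsPx = cbind(y = c(40, 30, 36, 30),
                                x = c(8, 100, 220, 376)),
    axonLengthUm = 60, axonRadiusUm = 0.5, gcRadiusUm = 1.5,
    tipSpeedUmMin = 0.1, tipRegionUm = 2,
    diffusionUm2Min = 1, transportUmMin = 0.1, somaInflux = 0.05,
    kLocal = 0.015, bleachRate = 0, residualGreen = 0.1, redInit = 1,
    dsUm = 0.25, psfSigmaUm = 0.3, background = 1, gain = 300,
    readNoiseSd = 1, shotNoise = TRUE, zSlices = 5L,
    imageShapePx = c(64L, 384L), pixelSizeUm = 32 / 150,
    nTimepoints = 10L, frameIntervalMin = 10, bitDepth = 16L, rngSeed = 1L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad)) .stopf("unknown config fields: %s", paste(bad, collapse = ", "))
  defaults[names(over)] <- over
  ints <- c("zSlices", "nTimepoints", "bitDepth", "rngSeed")
  for (f in ints) defaults[[f]] <- as.integer(defaults[[f]])
  defaults$imageShapePx <- as.integer(defaults$imageShapePx)
  do.call(new, c(list("SimulationConfig"), defaults))
}

#' Simulate post-photoconversion Kaede kinetics along the axon
#'
#' Solves the 1-D reaction-diffusion-transport system on the axon's
#' arc-length domain (s = 0 at the soma boundary, s = L(t) at the advancing
#' tip) with a conservative finite-volume scheme:
#' the newly supplied green pool obeys
#' dG/dt = D d2G/ds2 - v dG/ds + k_local * 1[tip region], with influx
#' J_soma at the soma boundary and zero flux at the tip; the residual
#' (pre-conversion) green left by incomplete photoconversion and the red
#' pool are old protein already distributed along the axon, so both evolve
#' by diffusion only (red additionally bleaches); active anterograde
#' transport applies to the newly supplied pool alone.  Reported G is the
#' residual plus new pool.  The initial condition is the post-conversion
#' state G = residualGreen * R0, R = R0.  Explicit substeps are sized so that
#' D dt / ds^2 <= 0.5 (and the advective CFL holds); the domain is extended
#' by the tip advance after each frame, new cells inheriting the tip
#' concentrations.  The dynamics are deterministic (no noise enters here).
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param condition condition label; default "+UTR" when \code{kLocal > 0},
#'   otherwise "-UTR".
#' @return A \linkS4class{GroundTruth}.
#' @export
simulateKinetics <- function(config,
                             condition = if (config@kLocal > 0) "+UTR" else "-UTR") {
  validObject(config)
  ds <- config@dsUm
  D <- config@diffusionUm2Min; v <- config@transportUmMin
  J <- config@somaInflux; kloc <- config@kLocal
  interval <- config@frameIntervalMin
  N <- max(4L, round(config@axonLengthUm / ds))
  Gres <- rep(config@residualGreen * config@redInit, N)  # old, unconverted
  Gnew <- rep(0, N)                                      # supplied/synthesized
  R <- rep(config@redInit, N)
  dtDiff <- if (D > 0) 0.45 * ds^2 / D else Inf
  dtAdv <- if (v > 0) 0.8 * ds / v else Inf
  nsub <- max(1L, ceiling(interval / min(dtDiff, dtAdv, interval)))
  if (nsub > 2e5)
    .stopf("stability violation: frame would need %d substeps; coarsen dsUm", nsub)
  dt <- interval / nsub
  if (D * dt / ds^2 > 0.5 + 1e-12)
    .stopf("stability violation: D*dt/ds^2 = %.3f > 0.5", D * dt / ds^2)

  nT <- config@nTimepoints
  green <- red <- sGrids <- traces <- vector("list", nT)
  record <- function(t) {
    green[[t]] <<- Gres + Gnew; red[[t]] <<- R
    sGrids[[t]] <<- (seq_along(R) - 0.5) * ds
    traces[[t]] <<- .truePath(config, length(R) * ds, t)
  }
  record(1L)
  growRem <- 0
  diffuseFlux <- function(u) {
    f <- -D * (u[-1L] - u[-length(u)]) / ds
    (c(0, f) - c(f, 0)) / ds
  }
  for (t in seq_len(nT - 1L)) {
    n <- length(R)
    tipInd <- ((seq_len(n) - 0.5) * ds) > (n * ds - config@tipRegionUm)
    for (s in seq_len(nsub)) {
      gl <- Gnew[-n]; gr <- Gnew[-1L]
      fluxG <- v * gl - D * (gr - gl) / ds
      Gnew <- Gnew + dt * ((c(J, fluxG) - c(fluxG, 0)) / ds + kloc * tipInd)
      Gres <- Gres + dt * diffuseFlux(Gres)
      R <- R + dt * (diffuseFlux(R) - config@bleachRate * R)
    }
    growRem <- growRem + config@tipSpeedUmMin * interval
    nNew <- floor(growRem / ds)
    if (nNew >= 1L) {
      growRem <- growRem - nNew * ds
      # new cells take the linearly extrapolated tip-boundary value (the
      # cell-center value alone under-fills the tip, first order in ds)
      tipVal <- function(u) {
        m <- length(u)
        max(0, u[m] + 0.5 * (u[m] - u[m - 1L]))
      }
      Gnew <- c(Gnew, rep(tipVal(Gnew), nNew))
      Gres <- c(Gres, rep(tipVal(Gres), nNew))
      R <- c(R, rep(tipVal(R), nNew))
    }
    record(t + 1L)
  }
  new("GroundTruth", green = green, red = red, sGridsUm = sGrids,
      trueTraces = traces, condition = condition, config = config)
}

# true retrograde trace for domain length LUm at one timepoint:
# dense 0-based (y,x) points from the tip back to the soma end of the path
.truePath <- function(config, LUm, timepoint) {
  tipPx <- LUm / config@pixelSizeUm
  ctrl <- config@pathControlPointsPx
  if (tipPx > .arcLength(ctrl)[nrow(ctrl)])
    .stopf("axon path leaving the field of view: tip at %.1f px exceeds path length %.1f px",
           tipPx, .arcLength(ctrl)[nrow(ctrl)])
  at <- seq(tipPx, 0, by = -0.5)
  TracePath(.pointAtArc(ctrl, at), timepointIndex = timepoint,
            orientedRetrograde = TRUE)
}

# rasterization geometry for one timepoint: which image pixel takes which
# arc-length sample (nearest-sample tube of the axon radius + tip disk)
.paintGeometry <- function(config, tipPx) {
  ctrl <- config@pathControlPointsPx
  ny <- config@imageShapePx[1L]; nx <- config@imageShapePx[2L]
  px <- config@pixelSizeUm
  sPx <- seq(0, tipPx, by = 0.5)
  pts <- .pointAtArc(ctrl, sPx)
  rTube <- config@axonRadiusUm / px
  r <- ceiling(rTube)
  off <- expand.grid(dy = -r:r, dx = -r:r)
  nS <- length(sPx); nO <- nrow(off)
  pyc <- rep(round(pts[, 1L]), times = nO) + rep(off$dy, each = nS)
  pxc <- rep(round(pts[, 2L]), times = nO) + rep(off$dx, each = nS)
  yj <- rep(pts[, 1L], times = nO); xj <- rep(pts[, 2L], times = nO)
  jIdx <- rep(seq_len(nS), times = nO)
  dist <- sqrt((pyc - yj)^2 + (pxc - xj)^2)
  keep <- dist <= rTube + 0.5
  pyc <- pyc[keep]; pxc <- pxc[keep]; dist <- dist[keep]; jIdx <- jIdx[keep]
  if (any(pyc < 0 | pyc >= ny | pxc < 0 | pxc >= nx))
    .stopf("axon path leaving the field of view during rendering")
  li <- pyc + 1L + pxc * ny
  ord <- order(dist)
  li <- li[ord]; jIdx <- jIdx[ord]
  first <- !duplicated(li)
  # growth-cone disk around the tip
  tip <- pts[nrow(pts), ]
  rGc <- config@gcRadiusUm / px
  rg <- ceiling(rGc)
  offg <- expand.grid(dy = -rg:rg, dx = -rg:rg)
  gy <- round(tip[1L]) + offg$dy; gx <- round(tip[2L]) + offg$dx
  gkeep <- sqrt((gy - tip[1L])^2 + (gx - tip[2L])^2) <= rGc
  gy <- gy[gkeep]; gx <- gx[gkeep]
  if (any(gy < 0 | gy >= ny | gx < 0 | gx >= nx))
    .stopf("axon path leaving the field of view: growth-cone disk clipped")
  list(sUm = sPx * px, li = li[first], jIdx = jIdx[first],
       gcLi = gy + 1L + gx * ny, ny = ny, nx = nx)
}

#' Render a simulated timelapse into a noisy image stack
#'
#' Paints the ground-truth concentration fields onto the curved 2-D axon
#' (a tube of the axon radius plus a disk of the growth-cone radius at the
#' advancing tip), distributes intensity across z slices with a Gaussian
#' weight profile, convolves each slice with the Gaussian PSF, applies the
#' photon gain, adds Poisson shot noise, Gaussian read noise and the
#' background offset, and quantizes to the configured bit depth.  Fully
#' reproducible from \code{config@rngSeed}.
#'
#' @param truth a \linkS4class{GroundTruth} from
#'   \code{\link{simulateKinetics}}.
#' @param config the matching \linkS4class{SimulationConfig}.
#' @return list with elements \code{stack} (a
#'   \linkS4class{TimelapseStack}) and \code{traces} (the per-timepoint true
#'   \linkS4class{TracePath}s).
#' @export
renderFrames <- function(truth, config = truth@config) {
  nT <- length(truth@green)
  ny <- config@imageShapePx[1L]; nx <- config@imageShapePx[2L]
  nZ <- config@zSlices
  arr <- array(0, c(nT, 2L, nZ, ny, nx))
  maxv <- 2^config@bitDepth - 1
  sigmaPx <- config@psfSigmaUm / config@pixelSizeUm
  Ky <- .gaussOperator(ny, sigmaPx)
  Kxt <- t(.gaussOperator(nx, sigmaPx))
  wz <- stats::dnorm(seq_len(nZ), (nZ + 1) / 2, max(1, nZ / 4))
  wz <- wz / sum(wz)
  .withSeed(config@rngSeed, {
    for (t in seq_len(nT)) {
      sGrid <- truth@sGridsUm[[t]]
      LUm <- max(sGrid) + config@dsUm / 2
      geom <- .paintGeometry(config, LUm / config@pixelSizeUm)
      tipReg <- sGrid > LUm - config@tipRegionUm
      for (ch in 1:2) {
        conc <- if (ch == 1L) truth@green[[t]] else truth@red[[t]]
        cs <- stats::approx(sGrid, conc, xout = geom$sUm, rule = 2)$y
        img <- matrix(0, ny, nx)
        img[geom$li] <- cs[geom$jIdx]
        gcVal <- mean(conc[tipReg])
        img[geom$gcLi] <- pmax(img[geom$gcLi], gcVal)
        # PSF and z-weighting are both linear: blur once, scale per slice
        blurred <- Ky %*% img %*% Kxt
        for (z in seq_len(nZ)) {
          counts <- blurred * (wz[z] * config@gain) + config@background
          if (config@shotNoise)
            counts <- stats::rpois(length(counts), pmax(counts, 0))
          if (config@readNoiseSd > 0)
            counts <- counts + stats::rnorm(length(counts), 0, config@readNoiseSd)
          arr[t, ch, z, , ] <- pmin(pmax(round(counts), 0), maxv)
        }
      }
    }
  })
  stack <- TimelapseStack(arr, pixelSizeUm = config@pixelSizeUm,
                          frameIntervalMin = config@frameIntervalMin,
                          channelRoles = c(green = 1L, red = 2L),
                          bitDepth = config@bitDepth)
  list(stack = stack, traces = truth@trueTraces)
}

#' Generate a ground-truthed +UTR / -UTR cohort
#'
#' Simulates and renders \code{nPlus} axons with local synthesis on and
#' \code{nMinus} with it off (the study's 10 + 6 design at defaults),
#' deriving each axon's seed from the master seed.  Optionally writes TIFF
#' hyperstacks, trace CSVs, a design CSV and the ground truth to
#' \code{outDir}.
#'
#' @param nPlus,nMinus axon counts per condition (each >= 1).
#' @param config base \linkS4class{SimulationConfig}; \code{kLocal} is
#'   zeroed for -UTR axons.
#' @param seed master seed; axon i uses \code{seed + i}.
#' @param outDir optional output directory.
#' @return list with \code{axons} (per-axon list: axonId, condition, stack,
#'   traces, truth) and \code{design} (data.frame axon_id, condition, seed).
#' @export
generateCohort <- function(nPlus = 10L, nMinus = 6L,
                           config = simulationConfig(), seed = 1L,
                           outDir = NULL) {
  if (nPlus < 1L || nMinus < 1L) .stopf("counts must be >= 1")
  conds <- c(rep("+UTR", nPlus), rep("-UTR", nMinus))
  axons <- vector("list", length(conds))
  for (i in seq_along(conds)) {
    cfg <- config
    if (conds[i] == "-UTR") cfg@kLocal <- 0
    cfg@rngSeed <- as.integer(seed + i)
    truth <- simulateKinetics(cfg, condition = conds[i])
    rend <- renderFrames(truth, cfg)
    axons[[i]] <- list(axonId = sprintf("axon%02d", i), condition = conds[i],
                       stack = rend$stack, traces = rend$traces, truth = truth)
  }
  design <- data.frame(axon_id = vapply(axons, `[[`, "", "axonId"),
                       condition = conds, seed = seed + seq_along(conds))
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    for (a in axons) {
      writeHyperstack(a$stack, file.path(outDir, paste0(a$axonId, ".tif")))
      writeTrace(a$traces, file.path(outDir, paste0(a$axonId, "_traces.csv")))
      jsonlite::write_json(
        list(condition = a$condition, green = a$truth@green,
             red = a$truth@red, sGridsUm = a$truth@sGridsUm),
        file.path(outDir, paste0(a$axonId, "_truth.json")), digits = NA)
    }
    utils::write.csv(design, file.path(outDir, "design.csv"), row.names = FALSE)
  }
  list(axons = axons, design = design, seed = seed)
}

#' Generate a 3-D spot-count fixture volume
#'
#' Places \code{nSpots} Gaussian spots (sd = radius / 2) with pairwise
#' center separation of at least twice the spot radius on a noisy
#' background, returning the volume and the planted centroids: the
#' ground-truth fixture for the 3-D apoptotic-cell counting stage.
#'
#' @param nSpots number of spots (0 allowed).
#' @param shape integer (Z, Y, X) voxel dimensions.
#' @param spotRadiusUm spot radius.
#' @param voxelSizeUm isotropic voxel size.
#' @param intensity peak spot intensity above background.
#' @param background background level.
#' @param noiseSd Gaussian noise SD.
#' @param exclusionRoi optional list(center = c(z,y,x), radius) kept free of
#'   spots.
#' @param seed RNG seed.
#' @return list with \code{volume} (3-D array) and \code{centroids}
#'   (nSpots x 3 matrix of (z,y,x) voxel coordinates, 1-based).
#' @export
generateAoVolume <- function(nSpots = 15L, shape = c(40L, 64L, 64L),
                             spotRadiusUm = 2.5, voxelSizeUm = 1,
                             intensity = 150, background = 20, noiseSd = 8,
                             exclusionRoi = NULL, seed = 1L) {
  rVox <- spotRadiusUm / voxelSizeUm
  .withSeed(seed, {
    centroids <- matrix(numeric(0), 0L, 3L)
    tries <- 0L
    while (nrow(centroids) < nSpots) {
      cand <- vapply(shape, function(n) stats::runif(1, 1 + rVox, n - rVox),
                     numeric(1))
      ok <- TRUE
      if (nrow(centroids) > 0L)
        ok <- all(sqrt(rowSums((centroids -
                 matrix(cand, nrow(centroids), 3L, byrow = TRUE))^2)) >= 2 * rVox)
      if (ok && !is.null(exclusionRoi))
        ok <- sqrt(sum((cand - exclusionRoi$center)^2)) > exclusionRoi$radius
      if (ok) centroids <- rbind(centroids, cand)
      tries <- tries + 1L
      if (tries > 1e4) .stopf("could not place %d spots with separation %g",
                              nSpots, 2 * rVox)
    }
    vol <- array(0, shape)
    sd <- rVox / 2
    r3 <- ceiling(3 * sd)
    for (i in seq_len(nrow(centroids))) {
      c0 <- centroids[i, ]
      zr <- max(1, floor(c0[1] - r3)):min(shape[1], ceiling(c0[1] + r3))
      yr <- max(1, floor(c0[2] - r3)):min(shape[2], ceiling(c0[2] + r3))
      xr <- max(1, floor(c0[3] - r3)):min(shape[3], ceiling(c0[3] + r3))
      g <- expand.grid(z = zr, y = yr, x = xr)
      d2 <- (g$z - c0[1])^2 + (g$y - c0[2])^2 + (g$x - c0[3])^2
      vol[as.matrix(g)] <- vol[as.matrix(g)] + intensity * exp(-d2 / (2 * sd^2))
    }
    vol <- vol + background
    if (noiseSd > 0) vol <- vol + stats::rnorm(length(vol), 0, noiseSd)
    vol <- pmax(vol, 0)
    dim(vol) <- shape
    colnames(centroids) <- c("z", "y", "x")
    list(volume = vol, centroids = centroids)
  })
}
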