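# internal numeric helpers shared across modules

# cumulative arc length of a polyline given as an n x 2 matrix
.arcLength <- function(points) {
  seg <- sqrt(rowSums((points[-1L, , drop = FALSE] -
                       points[-nrow(points), , drop = FALSE])^2))
  c(0, cumsum(seg))
}

# point on a polyline at arc-length distances `at` (linear interpolation);
# `at` must lie within [0, total length]
.pointAtArc <- function(points, at) {
  s <- .arcLength(points)
  y <- stats::approx(s, points[, 1L], xout = at, rule = 2)$y
  x <- stats::approx(s, points[, 2L], xout = at, rule = 2)$y
  cbind(y = y, x = x)
}

# dense 1-D Gaussian smoothing operator (n x n, rows renormalized so that
# constants are preserved at the edges -- replicate-style boundary mass)
.gaussOperator <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  idx <- seq_len(n)
  K <- outer(idx, idx, function(i, j) exp(-(i - j)^2 / (2 * sigma^2)))
  K[abs(row(K) - col(K)) > ceiling(4 * sigma)] <- 0
  K / rowSums(K)
}

# separable Gaussian smoothing of a 2-D matrix (PSF model for rendering)
.gaussBlur2d <- function(img, sigma) {
  if (sigma <= 0) return(img)
  .gaussOperator(nrow(img), sigma) %*% img %*% t(.gaussOperator(ncol(img), sigma))
}

# separable Gaussian smoothing of a 3-D array, sigma per axis (voxels)
.gaussSmooth3d <- function(vol, sigma) {
  d <- dim(vol)
  if (length(sigma) == 1L) sigma <- rep(sigma, 3L)
  # axis 1
  m <- matrix(vol, d[1L], d[2L] * d[3L])
  m <- .gaussOperator(d[1L], sigma[1L]) %*% m
  vol <- array(m, d)
  # axis 2
  vol <- aperm(vol, c(2L, 1L, 3L))
  m <- matrix(vol, d[2L], d[1L] * d[3L])
  m <- .gaussOperator(d[2L], sigma[2L]) %*% m
  vol <- aperm(array(m, d[c(2L, 1L, 3L)]), c(2L, 1L, 3L))
  # axis 3
  vol <- aperm(vol, c(3L, 1L, 2L))
  m <- matrix(vol, d[3L], d[1L] * d[2L])
  m <- .gaussOperator(d[3L], sigma[3L]) %*% m
  aperm(array(m, d[c(3L, 1L, 2L)]), c(2L, 3L, 1L))
}

# second central difference along one axis of a 3-D array (replicated edges)
.secondDiff3d <- function(vol, axis) {
  d <- dim(vol)
  n <- d[axis]
  up <- pmin(seq_len(n) + 1L, n)
  dn <- pmax(seq_len(n) - 1L, 1L)
  idx <- function(ord) {
    switch(axis,
           vol[ord, , , drop = FALSE],
           vol[, ord, , drop = FALSE],
           vol[, , ord, drop = FALSE])
  }
  out <- idx(up) + idx(dn) - 2 * vol
  dim(out) <- d
  out
}

# run `expr` under a fixed RNG seed, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# md5 digest of an arbitrary R object (used for config provenance)
.objectHash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
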