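test_that("trace resampling gives exact unit arc-length spacing", {
  tr <- resampleTrace(horizontalTrace(200))
  pts <- tracePoints(tr)
  expect_equal(nrow(pts), 150L)
  expect_equal(pts[, "x"], 0:149, ignore_attr = TRUE)
  expect_true(all(pts[, "y"] == 10))
  # 45-degree diagonal, arc length 160
  diag <- TracePath(cbind(c(0, 160 / sqrt(2)), c(0, 160 / sqrt(2))))
  gaps <- diff(.arcOf(tracePoints(resampleTrace(diag))))
  expect_true(all(abs(gaps - 1) < 1e-9))
  expect_error(resampleTrace(horizontalTrace(100)), "trace too short")
  expect_error(resampleTrace(horizontalTrace(100)), "100")
})

test_that("resampling is independent of input vertex density", {
  # same underlying piecewise-linear curve, sparse vs dense vertices
  ctrl <- cbind(y = c(0, 12, 20, 60), x = c(0, 70, 140, 210))
  dense <- do.call(rbind, lapply(1:3, function(i) {
    f <- seq(0, 1, length.out = 60)[-60]
    cbind(ctrl[i, 1] + f * (ctrl[i + 1, 1] - ctrl[i, 1]),
          ctrl[i, 2] + f * (ctrl[i + 1, 2] - ctrl[i, 2]))
  }))
  dense <- rbind(dense, ctrl[4, ])
  a <- tracePoints(resampleTrace(TracePath(ctrl)))
  b <- tracePoints(resampleTrace(TracePath(dense)))
  expect_equal(a, b, tolerance = 1e-6)
})

test_that("profile sampling reads pixels along the trace", {
  const <- new("RatioMap", values = matrix(0.37, 64, 256),
               valid = matrix(TRUE, 64, 256), timepointIndex = 1L,
               minRedUsed = 1)
  prof <- sampleProfile(const, resampleTrace(horizontalTrace(200)))
  expect_equal(profileValues(prof), rep(0.37, 150))
  expect_equal(profilePositions(prof), 1:150)
  # ratio = 0-based column index, horizontal trace -> successive columns
  cols <- matrix(rep(0:255, each = 64), 64, 256)
  rm <- new("RatioMap", values = cols, valid = matrix(TRUE, 64, 256),
            timepointIndex = 1L, minRedUsed = 1)
  prof <- sampleProfile(rm, resampleTrace(horizontalTrace(200, x0 = 5)))
  expect_equal(profileValues(prof), 5:154)
  # bilinear equals nearest at integer coordinates
  set.seed(2)
  rnd <- new("RatioMap", values = matrix(runif(64 * 256), 64, 256),
             valid = matrix(TRUE, 64, 256), timepointIndex = 1L, minRedUsed = 1)
  tr <- resampleTrace(horizontalTrace(200, y0 = 20, x0 = 3))
  expect_equal(profileValues(sampleProfile(rnd, tr, "bilinear")),
               profileValues(sampleProfile(rnd, tr, "nearest")))
  far <- TracePath(cbind(c(10, 10), c(250, 400)))
  expect_error(sampleProfile(rnd, resampleTrace(far)), "out of image bounds")
})

test_that("binning yields 15 means with the documented ranges", {
  vals <- 1:150
  prof <- new("IntensityProfile", positionsPx = 1:150, values = as.numeric(vals),
              timepointIndex = 1L, nPixels = 150L)
  b <- binProfile(prof)
  expect_length(binMeans(b), 15L)
  expect_equal(binMeans(b), seq(5.5, 145.5, by = 10))
  expect_equal(binRanges(b)[1, ], c(start = 1L, end = 10L))
  expect_equal(binRanges(b)[15, ], c(start = 141L, end = 150L))
  expect_true(all(validCounts(b) == 10L))
})

test_that("invalid pixels are excluded from their bin mean", {
  vals <- as.numeric(1:150)
  vals[3:7] <- NA
  prof <- new("IntensityProfile", positionsPx = 1:150, values = vals,
              timepointIndex = 1L, nPixels = 150L)
  b <- binProfile(prof)
  expect_equal(validCounts(b)[1], 5L)
  expect_equal(binMeans(b)[1], mean(c(1, 2, 8, 9, 10)))
  expect_equal(binMeans(b)[-1], seq(15.5, 145.5, by = 10))
  # a fully invalid bin is missing with zero count
  vals[11:20] <- NA
  b2 <- binProfile(new("IntensityProfile", positionsPx = 1:150, values = vals,
                       timepointIndex = 1L, nPixels = 150L))
  expect_true(is.na(binMeans(b2)[2]))
  expect_identical(validCounts(b2)[2], 0L)
})

test_that("binning is linear, within-bin permutation invariant, and mean-preserving", {
  set.seed(5)
  v <- runif(150)
  mk <- function(x) new("IntensityProfile", positionsPx = seq_along(x),
                        values = x, timepointIndex = 1L,
                        nPixels = length(x))
  b <- binProfile(mk(v))
  expect_equal(binMeans(binProfile(mk(3 * v + 2))), 3 * binMeans(b) + 2)
  vperm <- as.vector(apply(matrix(v, 10), 2, sample))
  expect_equal(binMeans(binProfile(mk(vperm))), binMeans(b))
  expect_equal(mean(binMeans(b)), mean(v))
  expect_warning(binProfile(mk(runif(157))), "dropping trailing 7")
})
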