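test_that("homogeneous closed system stays homogeneous", {
  cfg <- smallSimConfig(kLocal = 0, somaInflux = 0, transportUmMin = 0,
                        tipSpeedUmMin = 0, bleachRate = 0)
  truth <- simulateKinetics(cfg)
  for (t in seq_along(truth@green)) {
    expect_equal(truth@green[[t]] / truth@red[[t]],
                 rep(0.1, length(truth@green[[t]])), tolerance = 1e-12)
    expect_equal(truth@red[[t]], rep(1, length(truth@red[[t]])),
                 tolerance = 1e-12)
  }
})

test_that("kinetics solver conserves mass with closed boundaries", {
  cfg <- smallSimConfig(kLocal = 0, somaInflux = 0, tipSpeedUmMin = 0,
                        bleachRate = 0, transportUmMin = 0.3,
                        residualGreen = 0.4)
  truth <- simulateKinetics(cfg)
  totG <- vapply(truth@green, sum, numeric(1)) * cfg@dsUm
  totR <- vapply(truth@red, sum, numeric(1)) * cfg@dsUm
  expect_true(all(abs(totG / totG[1] - 1) < 1e-3))
  expect_true(all(abs(totR / totR[1] - 1) < 1e-3))
})

test_that("source terms add exactly the booked mass (flux-form accounting)", {
  # local synthesis only: dM/dt = k_local * (tip region length)
  cfg <- smallSimConfig(kLocal = 0.02, somaInflux = 0, tipSpeedUmMin = 0,
                        bleachRate = 0)
  truth <- simulateKinetics(cfg)
  s <- truth@sGridsUm[[1]]
  tipLen <- sum(s > max(s) + cfg@dsUm / 2 - cfg@tipRegionUm) * cfg@dsUm
  totG <- vapply(truth@green, sum, numeric(1)) * cfg@dsUm
  tmin <- (seq_along(totG) - 1) * cfg@frameIntervalMin
  expect_equal(totG - totG[1], 0.02 * tipLen * tmin, tolerance = 1e-9)
  # soma influx only: dM/dt = J
  cfgJ <- smallSimConfig(kLocal = 0, somaInflux = 0.05, tipSpeedUmMin = 0)
  truthJ <- simulateKinetics(cfgJ)
  totJ <- vapply(truthJ@green, sum, numeric(1)) * cfgJ@dsUm
  expect_equal(totJ - totJ[1], 0.05 * tmin, tolerance = 1e-9)
})

test_that("red is monotone non-increasing in time at every position", {
  truth <- simulateKinetics(smallSimConfig(bleachRate = 0.01))
  nMin <- length(truth@red[[1]])
  for (t in 2:length(truth@red))
    expect_true(all(truth@red[[t]][1:nMin] <= truth@red[[t - 1]][1:nMin] + 1e-9))
})

test_that("local synthesis makes tip green strictly increase", {
  truth <- simulateKinetics(smallSimConfig(kLocal = 0.015))
  tipG <- vapply(seq_along(truth@green), function(t) {
    g <- truth@green[[t]]; s <- truth@sGridsUm[[t]]
    mean(g[s > max(s) - 2])
  }, numeric(1))
  expect_true(all(diff(tipG) > 0))
})

test_that("coarse and 4x refined grids agree within 2 percent", {
  coarse <- simulateKinetics(smallSimConfig())
  fine <- simulateKinetics(smallSimConfig(dsUm = 0.0625))
  for (t in c(5L, 10L)) {
    gC <- approx(coarse@sGridsUm[[t]], coarse@green[[t]],
                 xout = fine@sGridsUm[[t]], rule = 2)$y
    dev <- max(abs(gC - fine@green[[t]])) / max(fine@green[[t]])
    expect_lt(dev, 0.02)
  }
})

test_that("solver refuses an unattainable stability condition", {
  expect_error(simulateKinetics(smallSimConfig(dsUm = 0.005)),
               "stability violation")
})

test_that("noise-free rendering of a uniform field gives ratio 1 on the trace", {
  cfg <- smallSimConfig(residualGreen = 1, kLocal = 0, somaInflux = 0,
                        bleachRate = 0, shotNoise = FALSE, readNoiseSd = 0,
                        background = 0)
  rend <- renderFrames(simulateKinetics(cfg), cfg)
  q <- quantifyAxon(rend$stack, rend$traces)
  expect_true(all(abs(q$profiles$mean_ratio - 1) < 1e-6))
})

test_that("rendering is bit-identical for the same seed", {
  cfg <- smallSimConfig(rngSeed = 99L, nTimepoints = 3L)
  truth <- simulateKinetics(cfg)
  expect_identical(frames(renderFrames(truth, cfg)$stack),
                   frames(renderFrames(truth, cfg)$stack))
  cfg2 <- smallSimConfig(rngSeed = 100L, nTimepoints = 3L)
  expect_false(identical(frames(renderFrames(truth, cfg)$stack),
                         frames(renderFrames(simulateKinetics(cfg2), cfg2)$stack)))
})

test_that("rendering rejects an axon that outgrows the field of view", {
  cfg <- smallSimConfig(axonLengthUm = 70)
  expect_error(simulateKinetics(cfg), "field of view")
})

test_that("recovered gradient rate decreases monotonically with k_local", {
  rates <- vapply(c(0, 0.006, 0.015), function(k) {
    cfg <- smallSimConfig(kLocal = k, shotNoise = FALSE, readNoiseSd = 0,
                          nTimepoints = 6L)
    rend <- renderFrames(simulateKinetics(cfg), cfg)
    quantifyAxon(rend$stack, rend$traces)$rate$rate
  }, numeric(1))
  expect_true(all(diff(rates) < 0))
})

test_that("cohort generation follows the 10 + 6 design and is reproducible", {
  cfg <- smallSimConfig(nTimepoints = 3L)
  co <- generateCohort(2, 1, cfg, seed = 21)
  expect_length(co$axons, 3L)
  expect_equal(co$design$condition, c("+UTR", "+UTR", "-UTR"))
  expect_equal(sum(co$design$condition == "+UTR"), 2L)
  co2 <- generateCohort(2, 1, cfg, seed = 21)
  for (i in 1:3)
    expect_identical(frames(co$axons[[i]]$stack), frames(co2$axons[[i]]$stack))
  # -UTR axons carry no local synthesis in their truth
  expect_identical(co$axons[[3]]$truth@config@kLocal, 0)
  dir <- withr::local_tempdir()
  co3 <- generateCohort(1, 1, cfg, seed = 4, outDir = dir)
  expect_true(file.exists(file.path(dir, "design.csv")))
  expect_true(file.exists(file.path(dir, "axon01.tif")))
  expect_equal(frames(readHyperstack(file.path(dir, "axon02.tif"))),
               frames(co3$axons[[2]]$stack))
})

test_that("spot fixture volumes honor count, separation and determinism", {
  empty <- generateAoVolume(0, seed = 1)
  expect_equal(nrow(empty$centroids), 0L)
  expect_lt(max(empty$volume), 20 + 8 * 6)  # background + noise only
  v <- generateAoVolume(20, shape = c(48L, 80L, 80L), seed = 2)
  expect_equal(nrow(v$centroids), 20L)
  dists <- as.matrix(dist(v$centroids))
  diag(dists) <- Inf
  expect_true(all(dists >= 2 * 2.5))
  v2 <- generateAoVolume(20, shape = c(48L, 80L, 80L), seed = 2)
  expect_identical(v$volume, v2$volume)
  roi <- list(center = c(20, 40, 40), radius = 15)
  vex <- generateAoVolume(10, shape = c(40L, 80L, 80L), exclusionRoi = roi,
                          seed = 3)
  d <- sqrt(colSums((t(vex$centroids) - roi$center)^2))
  expect_true(all(d > roi$radius))
})
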