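mkBinned <- function(means, timepoint = 1L) {
  n <- length(means)
  new("BinnedProfile", binMeans = as.numeric(means),
      binRanges = cbind(start = (seq_len(n) - 1L) * 10L + 1L,
                        end = seq_len(n) * 10L),
      validCounts = rep(10L, n), timepointIndex = as.integer(timepoint))
}

test_that("spatial gradient recovers exact and random slopes", {
  flat <- fitSpatialGradient(mkBinned(rep(0.4, 15)))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r_squared, 0)
  ctr <- seq(5.5, 145.5, by = 10)
  lin <- fitSpatialGradient(mkBinned(2 - 0.01 * ctr))
  expect_equal(lin$slope, -0.01)
  expect_equal(lin$intercept, 2)
  set.seed(1)
  for (i in 1:20) {
    y <- rnorm(15)
    fit <- fitSpatialGradient(mkBinned(y))
    lmfit <- lm(y ~ ctr)  # independent reference fit
    expect_equal(fit$slope, unname(coef(lmfit)[2]), tolerance = 1e-10)
    expect_equal(fit$intercept, unname(coef(lmfit)[1]), tolerance = 1e-10)
    expect_lt(abs(fit$r_squared - summary(lmfit)$r.squared), 1e-10)
  }
  few <- mkBinned(c(1, 2, rep(NA, 13)))
  expect_error(fitSpatialGradient(few), ">= 3")
})

test_that("gradient positions can be reported in microns", {
  set.seed(2)
  y <- rnorm(15)
  px <- fitSpatialGradient(mkBinned(y))
  um <- fitSpatialGradient(mkBinned(y), unit = "um", pixelSizeUm = 32 / 150)
  expect_equal(um$slope, px$slope / (32 / 150), tolerance = 1e-10)
})

test_that("gradient rate is the OLS slope of gradient versus time", {
  grads <- function(slopes) data.frame(timepoint_min = seq(0, 90, by = 10),
                                       slope = slopes)
  expect_equal(fitGradientRate(grads(rep(-0.002, 10)))$rate, 0)
  expect_equal(fitGradientRate(grads(-0.001 * seq(0, 90, 10)))$rate, -0.001)
  set.seed(3)
  g <- grads(rnorm(10, 0, 1e-3))
  fit <- fitGradientRate(g, condition = "+UTR", axonId = "ax1")
  ref <- lm(slope ~ timepoint_min, g)
  expect_equal(fit$rate, unname(coef(ref)[2]), tolerance = 1e-10)
  expect_identical(fit$condition, "+UTR")
  dup <- rbind(g, g[1, ])
  expect_error(fitGradientRate(dup), "duplicate timepoints")
  expect_error(fitGradientRate(g[1:2, ]), ">= 3")
  noT0 <- fitGradientRate(g, includeT0 = FALSE)
  expect_equal(noT0$n_timepoints_used, 9)
})

test_that("regressions shift- and scale-covariantly transform", {
  set.seed(4)
  y <- rnorm(15)
  base <- fitSpatialGradient(mkBinned(y))
  shifted <- fitSpatialGradient(mkBinned(y + 5))
  expect_equal(shifted$slope, base$slope, tolerance = 1e-12)
  scaled <- fitSpatialGradient(mkBinned(2 * y))
  expect_equal(scaled$slope, 2 * base$slope, tolerance = 1e-12)
})

test_that("region summary extracts growth cone (bin 1) and proximal (bin 15)", {
  const <- regionSummary(lapply(1:3, function(t) mkBinned(rep(0.8, 15), t)))
  expect_true(all(const$growth_cone == 0.8) && all(const$proximal == 0.8))
  expect_equal(const$timepoint_min, c(0, 10, 20))
  ctr <- seq(5.5, 145.5, by = 10)
  lin <- regionSummary(list(mkBinned(2 - 0.01 * ctr)))
  expect_equal(lin$growth_cone, 1.945)
  expect_equal(lin$proximal, 0.545)
})

test_that("ANOVA + Tukey flags the separated group only", {
  same <- anovaTukey(rep(c(1, 2, 3), 3), rep(c("a", "b", "c"), each = 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  res <- anovaTukey(c(1, 2, 3, 1, 2, 3, 10, 11, 12),
                    rep(c("a", "b", "c"), each = 3))
  sig <- res$pairwise$significant
  names(sig) <- res$pairwise$pair
  expect_false(sig[["b-a"]])
  expect_true(sig[["c-a"]] && sig[["c-b"]])
  # agrees with the stats:: reference route
  ref <- TukeyHSD(aov(c(1, 2, 3, 1, 2, 3, 10, 11, 12) ~
                        factor(rep(c("a", "b", "c"), each = 3))))
  expect_equal(res$pairwise$p_adj, unname(ref[[1]][, "p adj"]), tolerance = 1e-10)
  expect_error(anovaTukey(1:4, c("a", "a", "b", "c")), "n >= 2")
})

test_that("Tukey-flagged pairs are a subset of unadjusted pairwise-t flags", {
  set.seed(6)
  for (i in 1:10) {
    vals <- c(rnorm(5), rnorm(5, 1), rnorm(5, 2), rnorm(6, 0.5))
    grp <- rep(c("a", "b", "c", "d"), c(5, 5, 5, 6))
    res <- anovaTukey(vals, grp)
    praw <- pairwise.t.test(vals, grp, p.adjust.method = "none",
                            pool.sd = TRUE)$p.value
    lookup <- function(i, j) {
      v <- c(if (i %in% rownames(praw) && j %in% colnames(praw)) praw[i, j],
             if (j %in% rownames(praw) && i %in% colnames(praw)) praw[j, i])
      min(v, na.rm = TRUE)
    }
    for (r in seq_len(nrow(res$pairwise))) {
      pr <- strsplit(res$pairwise$pair[r], "-")[[1]]
      if (res$pairwise$significant[r]) expect_lt(lookup(pr[1], pr[2]), 0.05)
    }
  }
})

test_that("mimicked four-group growth-cone layout flags +UTR growth cones", {
  set.seed(7)
  vals <- c(rnorm(10, 0.6, 0.08),  # +UTR growth cone, elevated
            rnorm(10, 0.12, 0.03), # +UTR proximal
            rnorm(6, 0.12, 0.03),  # -UTR growth cone
            rnorm(6, 0.12, 0.03))  # -UTR proximal
  grp <- rep(c("+UTR gc", "+UTR prox", "-UTR gc", "-UTR prox"), c(10, 10, 6, 6))
  res <- anovaTukey(vals, grp)
  expect_lt(res$p_value, 0.01)
  flag <- setNames(res$pairwise$significant, res$pairwise$pair)
  hit <- grepl("\\+UTR gc", names(flag))
  expect_true(all(flag[hit]))
  expect_false(any(flag[!hit]))
})

test_that("Mann-Whitney exact p matches the textbook examples", {
  r1 <- mannWhitneyExact(0, 1)
  expect_equal(r1$statistic, 0)
  expect_equal(r1$p_value, 1)
  r2 <- mannWhitneyExact(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r2$statistic, 0)
  expect_equal(r2$p_value, 0.1)  # 2 of C(6,3)=20 arrangements
  r3 <- mannWhitneyExact(1:6, 7:16)
  expect_equal(r3$p_value, 2 / 8008)
  expect_identical(r3$method, "exact enumeration")
  expect_error(mannWhitneyExact(numeric(0), 1), "non-empty")
})

test_that("exact Mann-Whitney agrees with wilcox.test across designs", {
  set.seed(8)
  for (na in 1:6) for (nb in na:(12 - na)) {
    s <- tieFreePair(na, nb)
    mine <- mannWhitneyExact(s$a, s$b)
    ref <- suppressWarnings(wilcox.test(s$a, s$b, exact = TRUE))
    expect_equal(mine$statistic, unname(ref$statistic))
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12,
                 label = sprintf("p at na=%d nb=%d", na, nb))
  }
  # ties fall back to the corrected normal approximation
  tied <- mannWhitneyExact(c(1, 2, 2, 3), c(2, 4, 5))
  expect_identical(tied$method, "normal approximation")
  expect_true(tied$p_value >= 0 && tied$p_value <= 1)
})
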