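#' Spatial gradient of the ratio along the axon at one timepoint
#'
#' Ordinary least squares of the 15 bin means against bin-center position
#' (pixels from the growth cone: 5.5, 15.5, ..., 145.5 at defaults).  A
#' negative slope means the green/red ratio is enriched at the growth cone.
#' Missing bins are dropped pairwise; at least 3 bins are required.
#'
#' @param binned a \linkS4class{BinnedProfile}.
#' @param timepointMin minutes since photoconversion for this profile;
#'   default \code{(timepointIndex - 1) * frameIntervalMin}.
#' @param frameIntervalMin minutes per frame used for the default time.
#' @param unit position unit, "px" (default) or "um"; the choice rescales
#'   the slope linearly and leaves group inference unchanged.
#' @param pixelSizeUm calibration for \code{unit = "um"}.
#' @return one-row data.frame: timepoint_min, slope, intercept, r_squared,
#'   n_bins_used.
#' @export
fitSpatialGradient <- function(binned, timepointMin = NULL,
                               frameIntervalMin = 10,
                               unit = c("px", "um"), pixelSizeUm = 32 / 150) {
  unit <- match.arg(unit)
  if (is.null(timepointMin))
    timepointMin <- (timepointIndex(binned) - 1) * frameIntervalMin
  x <- binCenters(binned, unit = unit, pixelSizeUm = pixelSizeUm)
  y <- binMeans(binned)
  ok <- !is.na(y)
  if (sum(ok) < 3L)
    .stopf("spatial gradient needs >= 3 non-missing bins, have %d", sum(ok))
  fit <- .ols(x[ok], y[ok])
  data.frame(timepoint_min = timepointMin, slope = fit$slope,
             intercept = fit$intercept, r_squared = fit$r2,
             n_bins_used = sum(ok))
}

#' Rate of change of the spatial gradient for one axon
#'
#' The assay's headline statistic: OLS slope of the per-timepoint spatial
#' gradients against time (minutes).  A negative rate means growth-cone
#' enrichment of newly made green protein is increasing over the timelapse.
#'
#' @param gradients data.frame of per-timepoint fits as returned by
#'   \code{\link{fitSpatialGradient}} (rows stacked over timepoints).
#' @param condition condition label recorded in the result ("+UTR"/"-UTR").
#' @param axonId identifier recorded in the result.
#' @param includeT0 keep the t = 0 point (default TRUE; the first stack is
#'   acquired immediately after photoconversion).
#' @return one-row data.frame: axon_id, condition, rate, intercept,
#'   r_squared, n_timepoints_used.
#' @export
fitGradientRate <- function(gradients, condition = NA_character_,
                            axonId = NA_character_, includeT0 = TRUE) {
  g <- gradients
  if (!includeT0) g <- g[g$timepoint_min > 0, , drop = FALSE]
  if (anyDuplicated(g$timepoint_min))
    .stopf("duplicate timepoints in gradient series")
  if (nrow(g) < 3L)
    .stopf("gradient rate needs >= 3 timepoints, have %d", nrow(g))
  fit <- .ols(g$timepoint_min, g$slope)
  data.frame(axon_id = axonId, condition = condition, rate = fit$slope,
             intercept = fit$intercept, r_squared = fit$r2,
             n_timepoints_used = nrow(g))
}

# closed-form simple OLS; r2 defined as 0 for a flat response
.ols <- function(x, y) {
  xb <- mean(x); yb <- mean(y)
  sxx <- sum((x - xb)^2)
  slope <- sum((x - xb) * (y - yb)) / sxx
  intercept <- yb - slope * xb
  sst <- sum((y - yb)^2)
  r2 <- if (sst == 0) 0 else 1 - sum((y - intercept - slope * x)^2) / sst
  list(slope = slope, intercept = intercept, r2 = r2)
}

#' Growth-cone and proximal region means over the timelapse
#'
#' Emits the per-timepoint region table underlying the growth-cone
#' (pixels 1-10, bin 1) versus proximal (pixels 141-150, bin 15) comparison.
#'
#' @param binnedSeries list of \linkS4class{BinnedProfile}, one per
#'   timepoint.
#' @param frameIntervalMin minutes per frame.
#' @return data.frame: timepoint_min, growth_cone, proximal.
#' @export
regionSummary <- function(binnedSeries, frameIntervalMin = 10) {
  do.call(rbind, lapply(binnedSeries, function(b) {
    m <- binMeans(b)
    data.frame(timepoint_min = (timepointIndex(b) - 1) * frameIntervalMin,
               growth_cone = m[1L], proximal = m[length(m)])
  }))
}

#' One-way ANOVA with Tukey HSD pairwise comparisons
#'
#' Wraps \code{stats::aov} and \code{stats::TukeyHSD} (Tukey-Kramer for
#' unequal n) and reports per-group summaries plus pairwise significance
#' flags at the familywise level.
#'
#' @param values numeric response vector.
#' @param groups group labels (>= 3 groups, each with n >= 2).
#' @param level familywise significance level for the pairwise flags
#'   (default 0.05).
#' @return A \code{GroupTestResult} list: test_name, statistic (F), p_value,
#'   groups (data.frame with n, mean, sem), pairwise (data.frame with pair,
#'   diff, p_adj, significant), level.
#' @export
anovaTukey <- function(values, groups, level = 0.05) {
  groups <- factor(groups)
  n <- table(groups)
  if (nlevels(groups) < 3L) .stopf("ANOVA+Tukey needs >= 3 groups")
  if (any(n < 2L))
    .stopf("every group needs n >= 2 (offending: %s)",
           paste(names(n)[n < 2L], collapse = ", "))
  fit <- stats::aov(values ~ groups)
  tab <- summary(fit)[[1L]]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - level)$groups
  pairwise <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                         p_adj = tk[, "p adj"],
                         significant = tk[, "p adj"] < level,
                         row.names = NULL)
  gstat <- vapply(split(values, groups), function(v)
    c(n = length(v), mean = mean(v), sem = stats::sd(v) / sqrt(length(v))),
    numeric(3))
  res <- list(test_name = "one-way ANOVA + Tukey HSD",
              statistic = tab[1L, "F value"], p_value = tab[1L, "Pr(>F)"],
              groups = data.frame(group = colnames(gstat), t(gstat),
                                  row.names = NULL),
              pairwise = pairwise, level = level)
  class(res) <- "GroupTestResult"
  res
}

#' Exact Mann-Whitney U test
#'
#' Two-sided Mann-Whitney U comparing two independent samples.  For
#' tie-free data with \code{length(a) + length(b) <= exactLimit} the p-value
#' is exact, computed by full enumeration of all rank assignments (every
#' subset of ranks sample \code{a} could occupy); otherwise the
#' tie-corrected normal approximation is used.  U counts pairs with
#' \code{a > b} (+1/2 per tie), and the two-sided p is the probability of a
#' U at least as far from its null mean \code{n_a n_b / 2} as observed.
#'
#' @param a,b numeric samples (each non-empty).
#' @param exactLimit enumeration cutoff on \code{n_a + n_b}; the default 16
#'   keeps the assay's 6-versus-10 design exact.
#' @return A \code{GroupTestResult} list with test_name, statistic (U),
#'   p_value, method ("exact enumeration" or "normal approximation"),
#'   groups summary.
#' @export
mannWhitneyExact <- function(a, b, exactLimit = 16L) {
  if (!length(a) || !length(b)) .stopf("both samples must be non-empty")
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- anyDuplicated(c(a, b)) > 0L
  if (!ties && n <= exactLimit) {
    # enumerate every subset of ranks the first sample could occupy
    combos <- utils::combn(n, na)
    Uall <- colSums(matrix(seq_len(n)[combos], nrow = na)) - na * (na + 1) / 2
    mu <- na * nb / 2
    p <- mean(abs(Uall - mu) >= abs(U - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    mu <- na * nb / 2
    tieTab <- table(r)
    sigma2 <- na * nb / 12 * ((n + 1) - sum(tieTab^3 - tieTab) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(U - mu) - 0.5) / sqrt(sigma2)  # continuity correction
      p <- min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
    }
    method <- "normal approximation"
  }
  res <- list(test_name = "Mann-Whitney U", statistic = U, p_value = p,
              method = method,
              groups = data.frame(group = c("a", "b"), n = c(na, nb),
                                  mean = c(mean(a), mean(b)),
                                  sem = c(stats::sd(a) / sqrt(na),
                                          stats::sd(b) / sqrt(nb))))
  class(res) <- "GroupTestResult"
  res
}

#' @export
print.GroupTestResult <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g%s\n", x$test_name, x$statistic,
              x$p_value,
              if (!is.null(x$method)) paste0(" (", x$method, ")") else ""))
  print(x$groups, row.names = FALSE)
  if (!is.null(x$pairwise)) {
    cat(sprintf("pairwise (familywise level %.2g):\n", x$level))
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}
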