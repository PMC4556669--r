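# shared fixture builders; everything is generated in code at test time

# a reduced-scene simulation for unit tests (shorter axon, smaller frame,
# fewer z slices); kinetic rates stay at package defaults
smallSimConfig <- function(...) {
  base <- list(
    pathControlPointsPx = cbind(y = c(24, 22, 26, 24),
                                x = c(6, 90, 180, 280)),
    axonLengthUm = 40, imageShapePx = c(48L, 288L), zSlices = 3L
  )
  over <- list(...)
  base[names(over)] <- over
  do.call(simulationConfig, base)
}

# straight horizontal trace of `n` pixels starting at (y0, x0), tip first
horizontalTrace <- function(n = 200, y0 = 10, x0 = 0, timepoint = 1L) {
  TracePath(cbind(rep(y0, 2), c(x0, x0 + n)), timepointIndex = timepoint)
}

# random tie-free sample pair drawn from a continuous distribution
tieFreePair <- function(na, nb) {
  x <- stats::rnorm(na + nb)
  while (anyDuplicated(x)) x <- stats::rnorm(na + nb)
  list(a = x[seq_len(na)], b = x[-seq_len(na)])
}

# brute-force zipcode scan: O(n^2) double loop over motif occurrences
bruteZipcode <- function(seq, spacerMin, spacerMax) {
  s <- toupper(chartr("Uu", "Tt", seq))
  n <- nchar(s)
  hits <- NULL
  for (i in seq_len(max(0, n - 4))) {
    if (substring(s, i, i + 4) != "GGACT") next
    for (j in seq_len(max(0, n - 2))) {
      if (substring(s, j, j + 2) != "ACA") next
      spacer <- j - (i + 5)
      if (spacer >= spacerMin && spacer <= spacerMax)
        hits <- rbind(hits, data.frame(pos_ggact = i - 1L, pos_aca = j - 1L,
                                       spacer_nt = spacer))
    }
  }
  hits
}

randomDnaSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                  collapse = "")

# cumulative arc length of an n x 2 point matrix (test-side oracle)
.arcOf <- function(p) c(0, cumsum(sqrt(rowSums(diff(p)^2))))
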