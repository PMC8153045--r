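# Independent oracles used across the test files. These re-derive expected
# values through paths that share no code with the package internals.

# Round-half-away-from-zero, explicit (not base round()).
roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

# NCDF label oracle: explicit standardization (n - 1 convention), explicit
# Phi via pnorm, explicit rounding and clamping.
oracleNcdf <- function(x, nClasses) {
  theta <- pnorm((x - mean(x)) / sd(x))
  z <- roundHalfAway(nClasses * theta + 0.5)
  pmin(pmax(z, 1), nClasses)
}

# Brute-force dispersion-entropy oracle: census of all observed patterns
# into a count table keyed by the pattern string, then the Shannon formula.
oracleDispersionEntropy <- function(x, nClasses, m, tau) {
  z <- oracleNcdf(x, nClasses)
  npat <- length(z) - (m - 1) * tau
  pats <- vapply(seq_len(npat), function(i)
    paste(z[i + (0:(m - 1)) * tau], collapse = "-"), character(1))
  p <- as.numeric(table(pats)) / npat
  -sum(p * log(p))
}

# A raw signal whose labels under c = 3 cycle through a de Bruijn sequence of
# order 2, so that all 9 two-label patterns occur equally often.
equiprobableSignal <- function(cycles = 20) {
  labels <- c(rep(c(1, 1, 2, 1, 3, 2, 2, 3, 3), cycles), 1)
  c(-1, 0, 1)[labels]   # symmetric values map back onto the same labels
}

# Two-sided binomial acceptance band around probability p for n trials.
binomialBand <- function(n, p, conf = 0.95) {
  a <- (1 - conf) / 2
  c(qbinom(a, n, p), qbinom(1 - a, n, p)) / n
}

# Build a RoiTimeSeries directly from a generator function called per
# subject/session/run, for tests that need hand-controlled signals.
makeTimeSeries <- function(nSubjects, nRois, nTime, nRuns = 2, nSessions = 2,
                           gen = function(subject, session, run, roi) rnorm(nTime)) {
  series <- lapply(seq_len(nSubjects), function(i) {
    arr <- array(NA_real_, c(nTime, nRois, nRuns, nSessions))
    for (s in seq_len(nSessions))
      for (r in seq_len(nRuns))
        for (k in seq_len(nRois))
          arr[, k, r, s] <- gen(i, s, r, k)
    arr
  })
  RoiTimeSeries(series, sprintf("S%02d", seq_len(nSubjects)),
                sprintf("ROI%02d", seq_len(nRois)),
                paste0("REST", seq_len(nSessions)),
                paste0("run", seq_len(nRuns)))
}
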