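#' Per-ROI test-retest reliability
#'
#' Pearson correlation, across subjects, of the entropy at the same ROI in
#' two sessions. An ROI with zero cross-subject variance in either session
#' has an undefined correlation and is reported as \code{NA} with a warning.
#'
#' @param d1,d2 Subjects x ROIs entropy-profile matrices from two sessions.
#' @return Named numeric vector of per-ROI correlations in [-1, 1].
#' @export
regionalReliability <- function(d1, d2) {
  if (!all(dim(d1) == dim(d2))) stop("subject/ROI mismatch between sessions")
  if (nrow(d1) < 3L) stop("at least three subjects are required")
  r <- vapply(seq_len(ncol(d1)), function(k) {
    if (!(sd(d1[, k]) > 0) || !(sd(d2[, k]) > 0)) return(NA_real_)
    cor(d1[, k], d2[, k])
  }, numeric(1))
  names(r) <- colnames(d1)
  if (anyNA(r))
    warning(sprintf("%d ROI(s) with zero cross-subject variance: reliability undefined (NA)",
                    sum(is.na(r))))
  r
}

#' Entropy null distribution from temporally permuted signals
#'
#' Destroys the temporal structure of every run signal in one session by an
#' independent random shuffle, recomputes the dispersion entropy, and
#' averages runs within the session exactly as the real profiles do. The
#' resulting subject x ROI values form an empirical null for "how much
#' entropy a structureless signal with this amplitude distribution carries";
#' real signals whose entropy is indistinguishable from this distribution are
#' candidates for noise domination.
#'
#' @param ts A \code{\link{RoiTimeSeries}}.
#' @param params A \code{\link{DispersionParams}} object.
#' @param session Session name or index to permute (default the first).
#' @param seed Optional integer seed; fixed seed gives identical samples.
#' @param reps Independent shuffles per signal (default 1).
#' @return List with \code{samples} (subjects x ROIs x reps array, dropped to
#'   a matrix when \code{reps = 1}), \code{quantile05} (5th percentile of all
#'   samples), \code{params} and \code{session}.
#' @export
permutedEntropyNull <- function(ts, params = DispersionParams(), session = 1L,
                                seed = NULL, reps = 1L) {
  stopifnot(is(ts, "RoiTimeSeries"))
  if (!is.null(seed)) set.seed(seed)
  iSe <- if (is.character(session)) match(session, ts@sessionNames) else as.integer(session)
  if (is.na(iSe) || iSe < 1L || iSe > length(ts@sessionNames))
    stop("requested session not present")
  nR <- length(ts@roiIds)
  nRun <- length(ts@runNames)
  nS <- length(ts@subjectIds)
  nT <- dim(ts@series[[1]])[1]
  samples <- array(NA_real_, c(nS, nR, reps),
                   dimnames = list(ts@subjectIds, ts@roiIds, NULL))
  for (i in seq_len(nS)) {
    X <- ts@series[[i]][, , , iSe, drop = FALSE]
    dim(X) <- c(nT, nR * nRun)
    for (r in seq_len(reps)) {
      Xp <- apply(X, 2L, sample, size = nT)
      en <- .entropyMatrix(Xp, params, what = "permuted run signal")
      samples[i, , r] <- rowMeans(matrix(en, nR, nRun))
    }
  }
  if (reps == 1L) {
    dn <- dimnames(samples)[1:2]
    dim(samples) <- c(nS, nR)
    dimnames(samples) <- dn
  }
  list(samples = samples,
       quantile05 = unname(quantile(samples, 0.05, type = 7)),
       params = params, session = ts@sessionNames[iSe])
}

#' Flag unreliable, noise-dominated ROIs
#'
#' Two-threshold screening rule: an ROI is flagged when its test-retest
#' reliability falls below the 5th percentile of the empirical reliability
#' distribution AND its grand-mean entropy exceeds the 5th percentile of the
#' permuted-signal entropy null (i.e. its entropy is inside the null
#' distribution of structureless signals). Both percentiles use linear
#' interpolation between order statistics (R quantile type 7). Flagged ROIs
#' are excluded from downstream reliable-profile analyses.
#'
#' @param reliability Named per-ROI reliability vector from
#'   \code{\link{regionalReliability}} (NAs are excluded from the threshold
#'   and never flagged).
#' @param meanEntropy Per-ROI grand-mean entropy (all subjects and sessions).
#' @param null Result of \code{\link{permutedEntropyNull}}.
#' @param prob Percentile used for both thresholds (default 0.05).
#' @return An \code{S4Vectors::DataFrame} with columns \code{roi_id},
#'   \code{reliability}, \code{mean_entropy}, \code{flagged};
#'   \code{S4Vectors::metadata} holds \code{thReliability}, \code{thEntropy}
#'   and \code{prob}.
#' @export
flagUnreliableRois <- function(reliability, meanEntropy, null, prob = 0.05) {
  if (length(reliability) == 0L) stop("empty ROI set")
  if (length(reliability) != length(meanEntropy))
    stop("reliability and meanEntropy must be ROI-aligned")
  thR <- unname(quantile(reliability, prob, na.rm = TRUE, type = 7))
  thE <- unname(quantile(null$samples, prob, type = 7))
  flagged <- !is.na(reliability) & reliability < thR & meanEntropy > thE
  out <- S4Vectors::DataFrame(
    roi_id = if (is.null(names(reliability))) as.character(seq_along(reliability))
             else names(reliability),
    reliability = unname(reliability),
    mean_entropy = unname(meanEntropy),
    flagged = unname(flagged))
  S4Vectors::metadata(out) <- list(thReliability = thR, thEntropy = thE,
                                   prob = prob)
  out
}

#' Grand-mean entropy per ROI
#'
#' Mean over all subjects and all sessions of an \code{EntropyProfiles}
#' object; the entropy coordinate of the noise-screening rule.
#'
#' @param x An \code{\link{EntropyProfiles}} object.
#' @return Named per-ROI numeric vector (nats).
#' @export
grandMeanEntropy <- function(x) {
  a <- SummarizedExperiment::assays(x)
  rowMeans(Reduce(`+`, as.list(a)) / length(a))
}
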