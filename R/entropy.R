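#' Normal-CDF class mapping of a signal
#'
#' Maps every sample of a signal to one of \code{nClasses} integer labels.
#' Each sample is standardized by the signal's own mean \code{M} and standard
#' deviation \code{D} (sample convention, n - 1), passed through the normal
#' cumulative distribution function, \code{theta = pnorm((s - M) / D)}, and
#' quantized as \code{round(nClasses * theta + 0.5)} with half-away-from-zero
#' rounding, clamped to \code{[1, nClasses]}. Because \code{M} and \code{D}
#' rescale with the signal, the label sequence is invariant under positive
#' affine transforms of the input.
#'
#' @param x Numeric signal; all values must be finite.
#' @param params A \code{\link{DispersionParams}} object.
#' @return Integer vector of labels in \code{1:nClasses}, same length as
#'   \code{x}.
#' @examples
#' ncdfMap(c(-1, 0, 1), DispersionParams())  # 1 2 3
#' @export
ncdfMap <- function(x, params = DispersionParams()) {
  x <- as.numeric(x)
  if (length(x) < 2L) stop("signal must contain at least two samples")
  if (!all(is.finite(x))) stop("signal contains non-finite values")
  D <- sd(x)
  if (!(D > 0)) stop("degenerate input: constant signal (zero standard deviation)")
  theta <- pnorm((x - mean(x)) / D)
  z <- floor(params@nClasses * theta + 1)  # round-half-away-from-zero of c*theta + 0.5
  as.integer(pmin(pmax(z, 1), params@nClasses))
}

## shared input checks for the entropy estimators
.checkSignalLength <- function(n, params) {
  need <- (params@m - 1L) * params@tau + 1L
  if (n < need + 0L)
    stop(sprintf("signal of length %d is too short: need at least %d samples for m = %d, tau = %d",
                 n, need, params@m, params@tau))
}

.classCuts <- function(params) {
  k <- seq_len(params@nClasses - 1L)
  qnorm(k / params@nClasses)
}

#' Dispersion entropy of a signal
#'
#' Shannon entropy (natural logarithm) of the empirical distribution of
#' dispersion patterns. The signal is first symbolized with
#' \code{\link{ncdfMap}}; patterns are windows of \code{m} labels with
#' within-pattern spacing \code{tau}, and consecutive pattern start indices
#' advance by one sample. The result lies in \code{[0, log(nClasses^m)]}
#' nats; the upper bound is attained when all patterns are equiprobable and
#' zero when a single pattern occurs.
#'
#' @param x Numeric signal (finite values, non-constant).
#' @param params A \code{\link{DispersionParams}} object.
#' @return Entropy in nats.
#' @examples
#' set.seed(1)
#' dispersionEntropy(rnorm(1200))  # close to log(9) for white noise
#' @export
dispersionEntropy <- function(x, params = DispersionParams()) {
  x <- as.numeric(x)
  if (!all(is.finite(x))) stop("signal contains non-finite values")
  .checkSignalLength(length(x), params)
  if (!(sd(x) > 0)) stop("degenerate input: constant signal (zero standard deviation)")
  cpp_dispersion_entropy(matrix(x, ncol = 1L), params@nClasses, params@m,
                         params@tau, .classCuts(params))[1L]
}

## Vectorized estimator for a time x signal matrix; errors name the offending
## column. Used by the cohort-level assembly.
.entropyMatrix <- function(X, params, what = "signal") {
  .checkSignalLength(nrow(X), params)
  en <- tryCatch(
    cpp_dispersion_entropy(X, params@nClasses, params@m, params@tau,
                           .classCuts(params)),
    error = function(e) {
      msg <- conditionMessage(e)
      i <- suppressWarnings(as.integer(sub(".*column ([0-9]+)$", "\\1", msg)))
      if (!is.na(i) && !is.null(colnames(X)))
        stop(sprintf("non-finite value in %s '%s'", what, colnames(X)[i]),
             call. = FALSE)
      stop(e)
    })
  if (anyNA(en)) {
    bad <- which(is.na(en))[1L]
    lab <- if (!is.null(colnames(X))) colnames(X)[bad] else as.character(bad)
    stop(sprintf("degenerate input: constant signal in %s '%s'", what, lab))
  }
  en
}

#' Assemble per-subject entropy profiles
#'
#' Computes the dispersion entropy of every subject x ROI x run signal and
#' averages the runs within each session, yielding one ROI x subject matrix
#' per session (the per-subject rows of these matrices are the individual
#' entropy profiles). Profiles from different sessions can be compared for
#' reliability and identification, or averaged with
#' \code{\link{sessionAverage}} for prediction.
#'
#' @param ts A \code{\link{RoiTimeSeries}}.
#' @param params A \code{\link{DispersionParams}} object.
#' @param sessions Character vector of session names to compute (default all).
#' @param parcellation Optional data.frame with columns \code{roi_id} and
#'   \code{network}; attached as \code{rowData}.
#' @return An \code{\link{EntropyProfiles}} object with one assay per session.
#' @export
entropyProfiles <- function(ts, params = DispersionParams(),
                            sessions = sessionNames(ts), parcellation = NULL) {
  stopifnot(is(ts, "RoiTimeSeries"))
  if (!all(sessions %in% ts@sessionNames))
    stop("missing run/session: requested session(s) not present: ",
         paste(setdiff(sessions, ts@sessionNames), collapse = ", "))
  nR <- length(ts@roiIds)
  nRun <- length(ts@runNames)
  nS <- length(ts@subjectIds)
  assays <- lapply(sessions, function(se) {
    iSe <- match(se, ts@sessionNames)
    out <- matrix(NA_real_, nR, nS, dimnames = list(ts@roiIds, ts@subjectIds))
    for (i in seq_len(nS)) {
      a <- ts@series[[i]]
      X <- a[, , , iSe, drop = FALSE]        # time x roi x run
      dim(X) <- c(dim(a)[1], nR * nRun)      # runs stacked after ROIs
      colnames(X) <- paste0(rep(ts@roiIds, nRun), "/subject ", ts@subjectIds[i])
      en <- .entropyMatrix(X, params, what = "run signal")
      out[, i] <- rowMeans(matrix(en, nR, nRun))
    }
    out
  })
  names(assays) <- sessions
  rd <- S4Vectors::DataFrame(roi_id = ts@roiIds, row.names = ts@roiIds)
  if (!is.null(parcellation)) {
    idx <- match(ts@roiIds, parcellation$roi_id)
    if (anyNA(idx)) stop("ROI-count mismatch: parcellation does not cover all ROIs")
    rd$network <- parcellation$network[idx]
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays, rowData = rd,
    colData = S4Vectors::DataFrame(subject_id = ts@subjectIds,
                                   row.names = ts@subjectIds),
    metadata = list(params = params, runAggregation = "mean"))
  new("EntropyProfiles", se)
}

#' Write entropy profiles to a long-format TSV
#'
#' One row per subject x ROI x session with columns \code{subject_id},
#' \code{roi_id}, \code{network} (NA when no parcellation was attached),
#' \code{session}, \code{entropy_nats}.
#'
#' @param x An \code{\link{EntropyProfiles}} object.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
writeEntropyProfiles <- function(x, path) {
  rd <- SummarizedExperiment::rowData(x)
  network <- if ("network" %in% names(rd)) rd$network else NA_character_
  sessions <- SummarizedExperiment::assayNames(x)
  long <- do.call(rbind, lapply(sessions, function(se) {
    m <- SummarizedExperiment::assay(x, se)
    data.frame(subject_id = rep(colnames(m), each = nrow(m)),
               roi_id = rep(rownames(m), times = ncol(m)),
               network = rep(network, times = ncol(m)),
               session = se,
               entropy_nats = as.vector(m),
               stringsAsFactors = FALSE)
  }))
  write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Rank stability of the group entropy profile across parameter settings
#'
#' For each symbolization setting, computes the group-mean entropy per ROI
#' (averaged over subjects, runs and the requested sessions) and returns the
#' Spearman rank correlation between every pair of settings. High values mean
#' the ROI ranking of the entropy profile does not depend on the particular
#' (c, m, tau) choice.
#'
#' @param ts A \code{\link{RoiTimeSeries}}.
#' @param paramsList List of at least two \code{\link{DispersionParams}}.
#' @param sessions Sessions to include (default all).
#' @return A symmetric matrix of Spearman correlations, one row/column per
#'   setting, labelled "c=..,m=..,tau=..".
#' @export
rankStability <- function(ts, paramsList, sessions = sessionNames(ts)) {
  if (length(paramsList) < 2L) stop("at least two parameter settings are required")
  if (length(ts@roiIds) < 2L)
    stop("rank correlation undefined: need at least two ROIs")
  prof <- vapply(paramsList, function(p) {
    ep <- entropyProfiles(ts, p, sessions = sessions)
    rowMeans(Reduce(`+`, as.list(SummarizedExperiment::assays(ep))) /
               length(sessions))
  }, numeric(length(ts@roiIds)))
  colnames(prof) <- vapply(paramsList, function(p)
    sprintf("c=%d,m=%d,tau=%d", p@nClasses, p@m, p@tau), character(1))
  cor(prof, method = "spearman")
}
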