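#' @import methods
#' @importFrom stats cor sd quantile pnorm qnorm pt p.adjust rnorm median
#'   setNames plogis qlogis
#' @importFrom utils read.table write.table
#' @importFrom Rcpp sourceCpp
#' @useDynLib cortexEntropy, .registration = TRUE
NULL

#' Parameters of the dispersion-entropy symbolization
#'
#' Holds the three parameters of the dispersion-entropy estimator: the number
#' of classes \code{nClasses} used by the normal-CDF quantization, the
#' embedding dimension \code{m} (number of class labels per dispersion
#' pattern), and the within-pattern delay \code{tau} (spacing, in samples,
#' between the labels of one pattern). Defaults are \code{nClasses = 3},
#' \code{m = 2}, \code{tau = 1}, the setting used throughout the pipeline;
#' the resulting entropy is bounded by \code{log(nClasses^m)} nats.
#'
#' @slot nClasses integer, number of quantization classes (>= 2).
#' @slot m integer, embedding dimension (>= 1).
#' @slot tau integer, within-pattern delay in samples (>= 1).
#' @export
setClass("DispersionParams",
  representation(nClasses = "integer", m = "integer", tau = "integer"),
  prototype(nClasses = 3L, m = 2L, tau = 1L))

setValidity("DispersionParams", function(object) {
  msg <- character()
  if (length(object@nClasses) != 1L || is.na(object@nClasses) || object@nClasses < 2L)
    msg <- c(msg, "nClasses must be a single integer >= 2")
  if (length(object@m) != 1L || is.na(object@m) || object@m < 1L)
    msg <- c(msg, "m must be a single integer >= 1")
  if (length(object@tau) != 1L || is.na(object@tau) || object@tau < 1L)
    msg <- c(msg, "tau must be a single integer >= 1")
  if (length(msg)) msg else TRUE
})

#' @describeIn DispersionParams-class Constructor.
#' @param nClasses,m,tau see slot descriptions.
#' @return A \code{DispersionParams} object.
#' @examples
#' DispersionParams()            # c = 3, m = 2, tau = 1
#' DispersionParams(nClasses = 4, m = 3)
#' @export
DispersionParams <- function(nClasses = 3, m = 2, tau = 1) {
  new("DispersionParams", nClasses = as.integer(nClasses), m = as.integer(m),
      tau = as.integer(tau))
}

setMethod("show", "DispersionParams", function(object) {
  cat(sprintf("DispersionParams: c = %d, m = %d, tau = %d (max entropy %.4f nats)\n",
              object@nClasses, object@m, object@tau,
              object@m * log(object@nClasses)))
})

#' Maximum attainable dispersion entropy
#'
#' Upper bound \code{log(nClasses^m)} in nats, attained when all dispersion
#' patterns occur with identical probability.
#'
#' @param params A \code{\link{DispersionParams}} object.
#' @return Numeric scalar, nats.
#' @export
maxEntropy <- function(params) params@m * log(params@nClasses)

#' Multi-subject, multi-session ROI time-series container
#'
#' Stores a cohort of parcellated (ROI-level) time series organised as
#' subjects x sessions x runs x ROIs x time. Each subject's data are held as
#' a four-dimensional array with dimensions (time, ROI, run, session); all
#' subjects share the same ROI set, run count and session count.
#'
#' @slot series list of per-subject arrays, dim (time, ROI, run, session).
#' @slot subjectIds character identifiers, one per subject.
#' @slot roiIds character ROI identifiers.
#' @slot sessionNames character session labels (e.g. REST1, REST2).
#' @slot runNames character run labels.
#' @export
setClass("RoiTimeSeries",
  representation(series = "list", subjectIds = "character",
                 roiIds = "character", sessionNames = "character",
                 runNames = "character"))

setValidity("RoiTimeSeries", function(object) {
  n <- length(object@series)
  if (n != length(object@subjectIds))
    return("one series array per subject id is required")
  if (anyDuplicated(object@subjectIds))
    return("subject ids must be unique")
  dims <- c(NA, length(object@roiIds), length(object@runNames),
            length(object@sessionNames))
  for (i in seq_len(n)) {
    a <- object@series[[i]]
    if (!is.array(a) || length(dim(a)) != 4L)
      return(sprintf("series for subject '%s' is not a 4-d array",
                     object@subjectIds[i]))
    if (!all(dim(a)[2:4] == dims[2:4]))
      return(sprintf("series for subject '%s' has dimensions inconsistent with ROI/run/session labels",
                     object@subjectIds[i]))
    if (i > 1L && dim(a)[1] != dim(object@series[[1]])[1])
      return("all subjects must share the same number of time points")
  }
  TRUE
})

#' @describeIn RoiTimeSeries-class Constructor.
#' @param series,subjectIds,roiIds,sessionNames,runNames see slots.
#' @export
RoiTimeSeries <- function(series, subjectIds, roiIds,
                          sessionNames = c("REST1", "REST2"),
                          runNames = c("run1", "run2")) {
  new("RoiTimeSeries", series = series, subjectIds = as.character(subjectIds),
      roiIds = as.character(roiIds), sessionNames = as.character(sessionNames),
      runNames = as.character(runNames))
}

setMethod("show", "RoiTimeSeries", function(object) {
  cat(sprintf("RoiTimeSeries: %d subjects, %d ROIs, %d session(s) x %d run(s), %d time points\n",
              length(object@subjectIds), length(object@roiIds),
              length(object@sessionNames), length(object@runNames),
              if (length(object@series)) dim(object@series[[1]])[1] else 0L))
})

#' @rdname RoiTimeSeries-class
#' @param x A \code{RoiTimeSeries}.
#' @export
nSubjects <- function(x) length(x@subjectIds)

#' @rdname RoiTimeSeries-class
#' @export
subjectIds <- function(x) x@subjectIds

#' @rdname RoiTimeSeries-class
#' @export
roiIds <- function(x) x@roiIds

#' @rdname RoiTimeSeries-class
#' @export
sessionNames <- function(x) x@sessionNames

#' Extract one run of one subject
#'
#' @param x A \code{RoiTimeSeries}.
#' @param subject Subject id or index.
#' @param session Session name or index.
#' @param run Run name or index.
#' @return A time x ROI numeric matrix.
#' @export
getRun <- function(x, subject, session = 1L, run = 1L) {
  si <- if (is.character(subject)) match(subject, x@subjectIds) else as.integer(subject)
  se <- if (is.character(session)) match(session, x@sessionNames) else as.integer(session)
  ru <- if (is.character(run)) match(run, x@runNames) else as.integer(run)
  if (is.na(si) || si < 1L || si > length(x@series)) stop("unknown subject")
  if (is.na(se) || se < 1L || se > length(x@sessionNames)) stop("unknown session")
  if (is.na(ru) || ru < 1L || ru > length(x@runNames)) stop("unknown run")
  m <- x@series[[si]][, , ru, se, drop = FALSE]
  dim(m) <- dim(x@series[[si]])[1:2]
  colnames(m) <- x@roiIds
  m
}

#' Per-session entropy profiles of a cohort
#'
#' A \code{SummarizedExperiment} subclass holding one assay per session, each
#' an ROI x subject matrix of dispersion entropies in nats. \code{rowData}
#' carries the ROI ids and (when available) their functional-network labels;
#' \code{metadata} records the \code{\link{DispersionParams}} used and the
#' run-to-session aggregation rule.
#'
#' @export
#' @import SummarizedExperiment
setClass("EntropyProfiles", contains = "SummarizedExperiment")

setMethod("show", "EntropyProfiles", function(object) {
  cat(sprintf("EntropyProfiles: %d ROIs x %d subjects, sessions: %s\n",
              nrow(object), ncol(object),
              paste(SummarizedExperiment::assayNames(object), collapse = ", ")))
})

#' Extract a subjects x ROIs entropy matrix
#'
#' Orientation follows the downstream analyses (one profile per row).
#'
#' @param x An \code{EntropyProfiles} object.
#' @param session Session name or assay index.
#' @return A subjects x ROIs numeric matrix with subject/ROI dimnames.
#' @export
profileMatrix <- function(x, session = 1L) {
  t(SummarizedExperiment::assay(x, session))
}

#' Session-averaged entropy profiles
#'
#' Averages the per-session entropy matrices (element-wise) over all sessions,
#' the form used for cognition prediction and structure-entropy modelling.
#'
#' @param x An \code{EntropyProfiles} object.
#' @return A subjects x ROIs numeric matrix.
#' @export
sessionAverage <- function(x) {
  a <- SummarizedExperiment::assays(x)
  t(Reduce(`+`, as.list(a)) / length(a))
}

#' Result of a one-direction fingerprint identification
#'
#' @slot direction label of the form "database->target".
#' @slot predictedIds predicted subject id per target subject.
#' @slot trueIds true subject id per target subject.
#' @slot accuracy fraction of correct identifications.
#' @slot similarity target x database Pearson correlation matrix.
#' @export
setClass("IdentificationResult",
  representation(direction = "character", predictedIds = "character",
                 trueIds = "character", accuracy = "numeric",
                 similarity = "matrix"))

setMethod("show", "IdentificationResult", function(object) {
  cat(sprintf("IdentificationResult [%s]: accuracy %.2f%% (%d/%d correct)\n",
              object@direction, 100 * object@accuracy,
              sum(object@predictedIds == object@trueIds),
              length(object@trueIds)))
})

#' Two-direction fingerprint test with permutation inference
#'
#' @slot results list of two \code{IdentificationResult}s, one per direction.
#' @slot accuracy named numeric, observed accuracy per direction.
#' @slot permutationP single pooled permutation p-value (worst direction
#'   against the pooled null).
#' @slot perDirectionP per-direction p-values against the pooled null.
#' @slot nullAccuracies pooled null accuracies.
#' @slot ci95 2 x 2 matrix of bootstrap accuracy CIs (rows = directions).
#' @slot nPermutations total permutations pooled over directions.
#' @slot criterion accuracy considered satisfactory (default 0.6).
#' @slot satisfied logical per direction, accuracy > criterion.
#' @export
setClass("FingerprintResult",
  representation(results = "list", accuracy = "numeric",
                 permutationP = "numeric", perDirectionP = "numeric",
                 nullAccuracies = "numeric", ci95 = "matrix",
                 nPermutations = "integer", criterion = "numeric",
                 satisfied = "logical"))

setMethod("show", "FingerprintResult", function(object) {
  cat("FingerprintResult\n")
  for (d in names(object@accuracy))
    cat(sprintf("  %s: accuracy %.2f%% [%.2f%%, %.2f%%], satisfied: %s\n",
                d, 100 * object@accuracy[[d]],
                100 * object@ci95[d, 1], 100 * object@ci95[d, 2],
                object@satisfied[[d]]))
  cat(sprintf("  permutation p = %.4g (%d permutations pooled)\n",
              object@permutationP, object@nPermutations))
})

#' A synthetic cohort with known ground truth
#'
#' Produced by \code{\link{generateCohort}}; bundles the simulated
#' time series, structural property profiles, per-subject directed
#' connective-probability matrices, cognitive factor scores with family ids,
#' the parcellation, and the latent ground truth that determined all of them.
#'
#' @slot timeseries A \code{\link{RoiTimeSeries}}.
#' @slot structure named list of subjects x ROIs matrices, one per property
#'   (thickness, myelin, curv, sulc, strength, degree).
#' @slot connectivity list of per-subject directed probability matrices.
#' @slot scores data.frame: subject_id, family_id, g, vis, cry, mem, spd.
#' @slot parcellation data.frame: roi_id, hemisphere, network.
#' @slot truth list of latent quantities (AR coefficients, noise-ROI mask,
#'   planted weights, factor loadings, ...).
#' @slot config the \code{cohortConfig} list used.
#' @export
setClass("SyntheticCohort",
  representation(timeseries = "RoiTimeSeries", structure = "list",
                 connectivity = "list", scores = "data.frame",
                 parcellation = "data.frame", truth = "list",
                 config = "list"))

setMethod("show", "SyntheticCohort", function(object) {
  cat(sprintf("SyntheticCohort: %d subjects (%d families), %d ROIs (%d noise), %d networks\n",
              nrow(object@scores), length(unique(object@scores$family_id)),
              nrow(object@parcellation), sum(object@truth$noiseMask),
              length(unique(object@parcellation$network))))
})
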