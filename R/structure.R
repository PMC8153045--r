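#' Symmetrize and threshold a directed connective-probability matrix
#'
#' Converts directed connective probabilities into undirected structural
#' weights by reciprocal averaging, \code{w_ij = (p_ij + p_ji) / 2}, zeroes
#' the diagonal, and removes weights below \code{threshold} (default 0.001, a
#' value that retains roughly 10\% of the links in realistic probability
#' matrices). Reprocessing an already processed matrix is a no-op.
#'
#' @param p Square matrix of directed probabilities in [0, 1].
#' @param threshold Minimum retained weight (weights < threshold become 0).
#' @return Symmetric weight matrix with attribute \code{"threshold"}.
#' @examples
#' p <- matrix(0, 2, 2); p[1, 2] <- 0.004; p[2, 1] <- 0.002
#' symmetrizeThreshold(p)[1, 2]  # 0.003
#' @export
symmetrizeThreshold <- function(p, threshold = 0.001) {
  if (!is.matrix(p) || nrow(p) != ncol(p)) stop("connectivity matrix must be square")
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("connective probabilities must lie in [0, 1]")
  w <- (p + t(p)) / 2
  diag(w) <- 0
  w[w < threshold] <- 0
  attr(w, "threshold") <- threshold
  w
}

#' Node strength and degree of a thresholded structural network
#'
#' Strength is the sum of a node's link weights; degree is the number of its
#' suprathreshold links. Strength under-represents many weak links, degree
#' weighs weak and strong suprathreshold links equally; the two are reported
#' together.
#'
#' @param w Symmetric weight matrix from \code{\link{symmetrizeThreshold}}.
#' @return data.frame with \code{roi_id}, \code{strength}, \code{degree}.
#' @export
nodeMetrics <- function(w) {
  if (!is.matrix(w) || nrow(w) != ncol(w)) stop("weight matrix must be square")
  data.frame(
    roi_id = if (is.null(rownames(w))) as.character(seq_len(nrow(w))) else rownames(w),
    strength = unname(rowSums(w)),
    degree = unname(as.integer(rowSums(w > 0))),
    stringsAsFactors = FALSE)
}

#' Blueprint (cross-ROI) structure-entropy correlations
#'
#' Correlates the group-mean entropy profile (the "blueprint") with the
#' group-mean profile of each structural property across ROIs. Each
#' correlation carries a t-based p-value and a percentile bootstrap CI that
#' resamples ROIs -- the observation unit of this cross-regional analysis --
#' and the p-values are FDR-corrected across properties.
#'
#' @param entropyMean Per-ROI group-mean entropy (flagged ROIs removed).
#' @param structureMeans ROIs x properties matrix (or named list of per-ROI
#'   vectors) of group-mean structural properties, ROI-aligned with
#'   \code{entropyMean}.
#' @param nBoot Bootstrap replicates (default 1000).
#' @param seed Optional integer seed.
#' @param fdrQ FDR level (default 0.05).
#' @return data.frame with one row per property: \code{property}, \code{r},
#'   \code{p}, \code{ciLow}, \code{ciHigh}, \code{pAdjusted},
#'   \code{significant}, \code{n} (ROIs).
#' @export
blueprintCorrelations <- function(entropyMean, structureMeans, nBoot = 1000,
                                  seed = NULL, fdrQ = 0.05) {
  if (is.list(structureMeans) && !is.data.frame(structureMeans))
    structureMeans <- do.call(cbind, structureMeans)
  structureMeans <- as.matrix(structureMeans)
  if (length(entropyMean) < 3L) stop("at least three ROIs are required")
  if (nrow(structureMeans) != length(entropyMean))
    stop("structure means must be ROI-aligned with the entropy blueprint")
  props <- colnames(structureMeans)
  if (is.null(props)) props <- paste0("property", seq_len(ncol(structureMeans)))
  rows <- lapply(seq_along(props), function(j) {
    ct <- pearsonTest(entropyMean, structureMeans[, j], nBoot = nBoot,
                      seed = if (is.null(seed)) NULL else seed + j)
    data.frame(property = props[j], r = ct$r, p = ct$p,
               ciLow = ct$ci95[1], ciHigh = ct$ci95[2], n = ct$n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  adj <- bhAdjust(out$p, q = fdrQ)
  out$pAdjusted <- adj$adjusted
  out$significant <- adj$reject
  out
}

#' Cross-individual structure-entropy correlations per ROI
#'
#' For every ROI and structural property, the Pearson correlation across
#' subjects between the property value and the session-averaged entropy at
#' that ROI; these are the "fingerprint-level" associations, complementary to
#' the blueprint correlations. A network-averaged summary is returned when
#' network labels are supplied.
#'
#' @param entropy Subjects x ROIs session-averaged entropy matrix.
#' @param structure Named list of subjects x ROIs property matrices.
#' @param networks Optional named character vector (network label per ROI).
#' @return List with \code{r} (ROIs x properties matrix; NA with a warning
#'   where a property has zero cross-subject variance) and
#'   \code{networkMean} (networks x properties matrix of mean r, or NULL).
#' @export
regionalStructureCorrelations <- function(entropy, structure, networks = NULL) {
  stopifnot(is.list(structure), length(structure) >= 1L)
  nRoi <- ncol(entropy)
  props <- names(structure)
  r <- matrix(NA_real_, nRoi, length(props),
              dimnames = list(colnames(entropy), props))
  nBad <- 0L
  for (pp in props) {
    S <- structure[[pp]]
    if (!all(dim(S) == dim(entropy))) stop("structure matrices must match the entropy matrix")
    for (k in seq_len(nRoi)) {
      if (!(sd(S[, k]) > 0) || !(sd(entropy[, k]) > 0)) { nBad <- nBad + 1L; next }
      r[k, pp] <- cor(entropy[, k], S[, k])
    }
  }
  if (nBad > 0L)
    warning(sprintf("%d ROI/property pair(s) with zero variance: correlation undefined (NA)", nBad))
  nm <- NULL
  if (!is.null(networks)) {
    lab <- unname(networks[colnames(entropy)])
    nm <- do.call(rbind, lapply(split(seq_len(nRoi), lab), function(i)
      colMeans(r[i, , drop = FALSE], na.rm = TRUE)))
  }
  list(r = r, networkMean = nm)
}

#' Predict entropy profiles from one structural property
#'
#' Trains, for every ROI, a univariate ordinary least-squares regression of
#' the session-averaged entropy on one structural property across subjects,
#' under leave-one-family-out cross-validation, and assembles the out-of-fold
#' regional predictions into predicted entropy profiles. Two read-outs
#' follow: (1) the per-subject Pearson similarity between predicted and
#' observed profiles, which is high whenever the property tracks the
#' cross-ROI blueprint; and (2) identification specificity -- fingerprint
#' identification with the predicted profiles as the database and the
#' observed ones as targets -- which is high only when the property carries
#' subject-specific (fingerprint) information. The identification accuracy is
#' tested against a permutation null that shuffles the predicted-observed
#' pairing.
#'
#' @param entropy Subjects x ROIs session-averaged entropy matrix.
#' @param structure Subjects x ROIs matrix of one structural property.
#' @param family Family id per subject (LOFOV folds).
#' @param nPerm Permutations for the specificity p-value (default 1000).
#' @param nBoot Bootstrap replicates for the accuracy CI (default 1000).
#' @param seed Optional integer seed.
#' @param criterion Satisfactory-accuracy threshold (default 0.6).
#' @return List with \code{predicted} (subjects x ROIs matrix),
#'   \code{similarity} (per-subject predicted-observed correlation),
#'   \code{identification} (an \code{\link{IdentificationResult}}),
#'   \code{accuracy}, \code{permutationP}, \code{ci95}, \code{satisfied}.
#' @export
structureToEntropyPrediction <- function(entropy, structure, family,
                                         nPerm = 1000, nBoot = 1000,
                                         seed = NULL, criterion = 0.6) {
  if (!all(dim(structure) == dim(entropy)))
    stop("structure matrix must match the entropy matrix")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(entropy)
  folds <- .familyFolds(family)
  pred <- matrix(NA_real_, n, ncol(entropy), dimnames = dimnames(entropy))
  degenerate <- 0L
  for (fold in folds) {
    tr <- setdiff(seq_len(n), fold)
    xm <- colMeans(structure[tr, , drop = FALSE])
    ym <- colMeans(entropy[tr, , drop = FALSE])
    xc <- sweep(structure[tr, , drop = FALSE], 2L, xm)
    yc <- sweep(entropy[tr, , drop = FALSE], 2L, ym)
    vx <- colSums(xc^2)
    slope <- ifelse(vx > 0, colSums(xc * yc) / vx, 0)
    if (any(!(vx > 0))) degenerate <- degenerate + sum(!(vx > 0))
    pred[fold, ] <- sweep(structure[fold, , drop = FALSE], 2L, xm) *
      rep(slope, each = length(fold)) + rep(ym, each = length(fold))
  }
  if (degenerate > 0L)
    warning(sprintf("%d fold/ROI fit(s) had a zero-variance regressor; predicted by the training mean",
                    degenerate))
  similarity <- vapply(seq_len(n), function(i) cor(pred[i, ], entropy[i, ]),
                       numeric(1))
  idf <- identifyProfiles(entropy, pred, direction = "predicted->observed")
  nullAcc <- .permutationNull(idf, nPerm)
  permP <- mean(nullAcc >= idf@accuracy)
  ci <- .accuracyBootCI(idf@predictedIds == idf@trueIds, nBoot)
  list(predicted = pred, similarity = similarity, identification = idf,
       accuracy = idf@accuracy, permutationP = permP, ci95 = ci,
       nullAccuracies = nullAcc, criterion = criterion,
       satisfied = idf@accuracy > criterion)
}
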