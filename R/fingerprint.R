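## Input checks shared by the identification functions: subjects x ROIs
## matrices with matching subjects/ROIs and non-degenerate profile rows.
.checkProfilePair <- function(a, b, minRois = 3L) {
  if (!is.matrix(a) || !is.matrix(b)) stop("profiles must be matrices (subjects x ROIs)")
  if (!all(dim(a) == dim(b))) stop("subject/ROI mismatch between the two profile matrices")
  if (!is.null(rownames(a)) && !is.null(rownames(b)) &&
      !identical(rownames(a), rownames(b)))
    stop("subject/ROI mismatch: subject ids differ between matrices")
  if (!is.null(colnames(a)) && !is.null(colnames(b)) &&
      !identical(colnames(a), colnames(b)))
    stop("subject/ROI mismatch: ROI order differs between matrices")
  if (nrow(a) < 2L) stop("at least two subjects are required")
  if (ncol(a) < minRois) stop(sprintf("at least %d ROIs are required", minRois))
  for (m in list(a, b)) {
    v <- apply(m, 1L, sd)
    if (any(!(v > 0))) {
      bad <- which(!(v > 0))[1L]
      id <- if (!is.null(rownames(m))) rownames(m)[bad] else as.character(bad)
      stop(sprintf("zero-variance entropy profile for subject '%s': correlation undefined", id))
    }
  }
  invisible(NULL)
}

.subjectNames <- function(m) {
  if (is.null(rownames(m))) as.character(seq_len(nrow(m))) else rownames(m)
}

#' Identify individuals by entropy-profile matching
#'
#' For every subject in the target set, finds the database subject whose
#' entropy profile has the highest Pearson correlation with the target
#' profile; that subject's id is the predicted identity. Accuracy is the
#' fraction of target subjects whose predicted id equals their own. Ties in
#' the similarity argmax are broken towards the lowest subject index with a
#' warning (exact ties have measure zero on continuous data).
#'
#' @param target,database Subjects x ROIs matrices from two different
#'   sessions, same subjects and ROI order.
#' @param direction Label stored in the result (default
#'   "database->target").
#' @return An \code{\link{IdentificationResult}}; the full similarity matrix
#'   (targets x database) is kept for inspection.
#' @export
identifyProfiles <- function(target, database, direction = "database->target") {
  .checkProfilePair(target, database)
  ids <- .subjectNames(target)
  sim <- cor(t(target), t(database))
  dimnames(sim) <- list(ids, ids)
  best <- apply(sim, 1L, function(r) {
    w <- which(r == max(r))
    if (length(w) > 1L) warning("similarity tie broken towards the lowest subject index")
    w[1L]
  })
  pred <- ids[best]
  new("IdentificationResult", direction = direction, predictedIds = pred,
      trueIds = ids, accuracy = mean(pred == ids), similarity = sim)
}

## Null accuracies by permuting the target ids against fixed predictions.
.permutationNull <- function(result, nPerm) {
  pred <- result@predictedIds
  ids <- result@trueIds
  vapply(seq_len(nPerm), function(i) mean(pred == ids[sample.int(length(ids))]),
         numeric(1))
}

## Percentile bootstrap CI for an identification accuracy, resampling the
## target subjects (their correct/incorrect indicator) with replacement.
.accuracyBootCI <- function(correct, nBoot) {
  if (nBoot <= 0) return(c(NA_real_, NA_real_))
  bootstrapCI(mean, as.numeric(correct), nBoot = nBoot)
}

#' Fingerprint test: both directions, permutation null, bootstrap CI
#'
#' Runs the identification in both directions (session 1 profiles as the
#' database with session 2 as targets, and the reverse), builds a pooled
#' permutation null by shuffling the target identities \code{nPerm} times per
#' direction, and reports for each direction the empirical probability that a
#' null accuracy is at least the observed one. The single pooled p-value is
#' the larger (more conservative) of the two per-direction p-values. An
#' accuracy above \code{criterion} (default 60\%) is flagged as satisfactory;
#' significance alone is not, because chance-level accuracies are routinely
#' significant in large samples.
#'
#' @param d1,d2 Subjects x ROIs entropy-profile matrices from two sessions.
#' @param nPerm Permutations per direction (default 500, so 1000 pooled).
#' @param nBoot Bootstrap replicates for the accuracy CI (default 1000).
#' @param seed Optional integer seed.
#' @param criterion Satisfactory-accuracy threshold (default 0.6).
#' @param labels Session labels used in the direction names.
#' @return A \code{\link{FingerprintResult}}.
#' @export
fingerprintTest <- function(d1, d2, nPerm = 500, nBoot = 1000, seed = NULL,
                            criterion = 0.6, labels = c("R1", "R2")) {
  if (!is.null(seed)) set.seed(seed)
  dir12 <- sprintf("%s->%s", labels[1], labels[2])  # database d1, targets d2
  dir21 <- sprintf("%s->%s", labels[2], labels[1])
  r12 <- identifyProfiles(d2, d1, direction = dir12)
  r21 <- identifyProfiles(d1, d2, direction = dir21)
  null12 <- .permutationNull(r12, nPerm)
  null21 <- .permutationNull(r21, nPerm)
  pooled <- c(null12, null21)
  acc <- c(r12@accuracy, r21@accuracy)
  names(acc) <- c(dir12, dir21)
  pDir <- vapply(acc, function(a) mean(pooled >= a), numeric(1))
  ci <- rbind(.accuracyBootCI(r12@predictedIds == r12@trueIds, nBoot),
              .accuracyBootCI(r21@predictedIds == r21@trueIds, nBoot))
  dimnames(ci) <- list(names(acc), c("low", "high"))
  new("FingerprintResult", results = list(r12, r21), accuracy = acc,
      permutationP = max(pDir), perDirectionP = pDir,
      nullAccuracies = pooled, ci95 = ci,
      nPermutations = as.integer(2L * nPerm), criterion = criterion,
      satisfied = acc > criterion)
}

#' Per-ROI differentiation power
#'
#' Quantifies how much each ROI contributes to fingerprint identification.
#' Profiles are z-scored per subject across ROIs, so the Pearson similarity
#' between a session-1 and a session-2 profile decomposes into per-ROI
#' products \code{phi_ij(n) = z1_i(n) * z2_j(n)}. For subject i and ROI n the
#' empirical probability that a cross-subject product beats the within-subject
#' product is
#' \code{P_i(n) = (#\{phi_ij > phi_ii\} + #\{phi_ji > phi_ii\}) / (2 (N - 1))}
#' (strict inequalities, j != i), and the ROI's differentiation power is
#' \code{DP(n) = -log(mean_i P_i(n))}. When the mean probability is exactly
#' zero it is replaced by \code{1 / (2 N (N - 1))}, the smallest attainable
#' nonzero value, before taking the log. Using the mean rather than the sum
#' of \code{P_i(n)} shifts every DP by \code{log(N)} and leaves the ROI
#' ranking unchanged.
#'
#' @param d1,d2 Subjects x ROIs entropy-profile matrices from two sessions.
#' @return List with \code{dp} (named per-ROI numeric), \code{perSubjectP}
#'   (subjects x ROIs matrix of \code{P_i(n)}), \code{meanP}, and
#'   \code{epsilon} (the zero-probability guard).
#' @export
differentiationPower <- function(d1, d2) {
  .checkProfilePair(d1, d2)
  n <- nrow(d1)
  z1 <- t(scale(t(d1)))
  z2 <- t(scale(t(d2)))
  nRoi <- ncol(d1)
  P <- matrix(NA_real_, n, nRoi, dimnames = dimnames(d1))
  for (k in seq_len(nRoi)) {
    a <- z1[, k]
    b <- z2[, k]
    phi <- outer(a, b)          # phi[i, j] = z1_i(k) * z2_j(k)
    d <- a * b                  # phi_ii
    t1 <- rowSums(phi > d)      # j : phi_ij > phi_ii (d recycles over rows)
    t2 <- colSums(phi > matrix(d, n, n, byrow = TRUE))  # j : phi_ji > phi_ii
    P[, k] <- (t1 + t2) / (2 * (n - 1))
  }
  eps <- 1 / (2 * n * (n - 1))
  meanP <- colMeans(P)
  dp <- -log(pmax(meanP, eps))
  list(dp = dp, perSubjectP = P, meanP = meanP, epsilon = eps)
}
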