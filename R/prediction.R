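#' Closed-form ridge regression
#'
#' Solves \code{b = (X'X + lambda I)^{-1} X'y} on column-centered data; the
#' intercept is the training mean of \code{y}. With \code{lambda = 0} the
#' solution is ordinary least squares, and a singular system at
#' \code{lambda = 0} raises an error advising a positive penalty. Predictors
#' are used as given; the cross-validation driver z-scores them on each
#' training fold before calling this.
#'
#' @param X Subjects x predictors numeric matrix.
#' @param y Numeric outcome vector.
#' @param lambda Ridge penalty >= 0.
#' @return Object of class \code{ridgeModel}: list with \code{b}
#'   (coefficients), \code{k} (intercept = training mean of y),
#'   \code{xCenter} (training column means), \code{lambda}.
#' @examples
#' X <- cbind(a = c(1, -1, 1, -1), b = c(1, 1, -1, -1))
#' ridgeFit(X, c(2, 0, 1, -1), lambda = 1)
#' @export
ridgeFit <- function(X, y, lambda = 0) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("X and y dimensions do not match")
  if (length(lambda) != 1L || !is.finite(lambda) || lambda < 0)
    stop("lambda must be a single number >= 0")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  yc <- y - mean(y)
  A <- crossprod(Xc) + diag(lambda, ncol(X))
  b <- tryCatch(solve(A, crossprod(Xc, yc)),
                error = function(e)
                  stop("singular system (collinear predictors at lambda = 0); use lambda > 0",
                       call. = FALSE))
  structure(list(b = drop(b), k = mean(y), xCenter = ctr, lambda = lambda),
            class = "ridgeModel")
}

#' @rdname ridgeFit
#' @param object A \code{ridgeModel}.
#' @param newdata Matrix of predictors with the training columns.
#' @param ... Unused.
#' @export
predict.ridgeModel <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  drop(sweep(newdata, 2L, object$xCenter) %*% object$b) + object$k
}

## Split subjects into leave-one-family-out folds; errors on degenerate
## family structure.
.familyFolds <- function(family) {
  family <- as.character(family)
  folds <- split(seq_along(family), family)
  if (length(folds) < 2L)
    stop("all subjects belong to one family: no training data for LOFOV")
  folds
}

## z-score columns by training mean/sd; columns constant on the training set
## are mapped to zero (and so receive zero weight).
.foldScale <- function(Xtrain, Xtest) {
  mu <- colMeans(Xtrain)
  sdv <- apply(Xtrain, 2L, sd)
  bad <- !(sdv > 0)
  sdv[bad] <- 1
  Xs <- sweep(sweep(Xtrain, 2L, mu), 2L, sdv, "/")
  Xt <- sweep(sweep(Xtest, 2L, mu), 2L, sdv, "/")
  if (any(bad)) {
    Xs[, bad] <- 0
    Xt[, bad] <- 0
  }
  list(train = Xs, test = Xt)
}

## Fast two-sided t-based p-values for the correlation of each column of X
## with y (used by the optional feature screening inside a training fold).
.columnCorP <- function(X, y) {
  n <- length(y)
  xs <- scale(X)
  ys <- scale(y)
  r <- drop(crossprod(xs, ys)) / (n - 1)
  r[!is.finite(r)] <- 0
  r2 <- pmin(r^2, 1 - 1e-15)
  tt <- abs(r) * sqrt((n - 2) / (1 - r2))
  2 * pt(-tt, df = n - 2)
}

#' Ridge prediction under leave-one-family-out cross-validation
#'
#' Predicts an outcome from entropy profiles with closed-form ridge
#' regression, holding out one family at a time so that siblings never
#' straddle the train/test split. Inside every training fold the predictors
#' are z-scored, the outcome is z-scored (predictions are mapped back through
#' the fold's mean/sd), and, optionally, predictors are screened by the
#' training-fold correlation p-value. The penalty is chosen from
#' \code{lambdaGrid} as the value maximizing the correlation between observed
#' and out-of-fold predicted scores -- the procedure reports the same
#' correlations it used for selection, so the selected accuracy is mildly
#' optimistic; this is deliberate and documented rather than corrected.
#' A negative observed-predicted correlation is clamped to zero in
#' \code{accuracy}; the unclamped value, its t-based p-value and a percentile
#' bootstrap CI over subjects are also returned.
#'
#' @param X Subjects x ROIs predictor matrix (reliable ROIs only,
#'   session-averaged).
#' @param y Numeric outcome (cognitive factor score).
#' @param family Family id per subject; each family forms one fold.
#' @param lambdaGrid Candidate penalties (default \code{10^(-2:5)}).
#' @param screenP Optional feature-screening p-value threshold applied within
#'   each training fold (default NULL = no screening, predictors enter as a
#'   whole).
#' @param nBoot Bootstrap replicates for the accuracy CI (default 1000).
#' @param seed Optional integer seed for the bootstrap.
#' @return Object of class \code{lofovPrediction}: list with
#'   \code{predicted}, \code{observed}, \code{accuracy} (clamped at 0),
#'   \code{rawR}, \code{p}, \code{ci95}, \code{lambda} (selected),
#'   \code{gridR} (correlation per candidate lambda),
#'   \code{meanAbsWeight} (per-ROI mean |coefficient| across folds at the
#'   selected lambda), \code{nFamilies}.
#' @export
lofovPredict <- function(X, y, family, lambdaGrid = 10^(-2:5), screenP = NULL,
                         nBoot = 1000, seed = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (length(y) != n || length(family) != n)
    stop("X, y and family must describe the same subjects")
  if (!all(is.finite(y))) stop("outcome contains non-finite values")
  folds <- .familyFolds(family)
  p <- ncol(X)
  nL <- length(lambdaGrid)
  pred <- matrix(NA_real_, n, nL)
  wsum <- matrix(0, p, nL)            # running sum of |b| over folds
  for (fold in folds) {
    tr <- setdiff(seq_len(n), fold)
    keep <- seq_len(p)
    if (!is.null(screenP)) {
      pv <- .columnCorP(X[tr, , drop = FALSE], y[tr])
      keep <- which(pv < screenP)
      if (length(keep) == 0L)
        stop("feature screening removed every predictor in a training fold")
    }
    sc <- .foldScale(X[tr, keep, drop = FALSE], X[fold, keep, drop = FALSE])
    my <- mean(y[tr]); sy <- sd(y[tr])
    if (!(sy > 0)) stop("outcome constant within a training fold")
    ys <- (y[tr] - my) / sy
    G <- crossprod(sc$train)
    Xty <- crossprod(sc$train, ys)
    for (l in seq_len(nL)) {
      b <- tryCatch(solve(G + diag(lambdaGrid[l], length(keep)), Xty),
                    error = function(e)
                      stop("singular system in a training fold; use lambda > 0",
                           call. = FALSE))
      pred[fold, l] <- drop(sc$test %*% b) * sy + my
      wsum[keep, l] <- wsum[keep, l] + abs(drop(b))
    }
  }
  gridR <- apply(pred, 2L, cor, y = y)
  sel <- which.max(gridR)             # ties resolve to the smallest lambda
  rawR <- gridR[sel]
  pt_ <- pearsonTest(y, pred[, sel])
  ci <- if (nBoot > 0)
    bootstrapCI(function(d) cor(d[, 1], d[, 2]), cbind(y, pred[, sel]),
                nBoot = nBoot, seed = seed) else NULL
  maw <- wsum[, sel] / length(folds)
  names(maw) <- colnames(X)
  structure(list(predicted = pred[, sel], observed = y,
                 accuracy = max(0, rawR), rawR = rawR, p = pt_$p, ci95 = ci,
                 lambda = lambdaGrid[sel], gridR = setNames(gridR, lambdaGrid),
                 meanAbsWeight = maw, nFamilies = length(folds)),
            class = "lofovPrediction")
}

#' @export
print.lofovPrediction <- function(x, ...) {
  cat(sprintf("LOFOV ridge prediction: accuracy r = %.3f (raw %.3f), p = %.3g, lambda = %g, %d families\n",
              x$accuracy, x$rawR, x$p, x$lambda, x$nFamilies))
  invisible(x)
}

#' Per-network prediction of cognitive scores
#'
#' Repeats the LOFOV ridge prediction restricted to the ROIs of each
#' functional network, for one or several outcomes, and corrects the
#' resulting p-values for multiplicity with Benjamini-Hochberg FDR across the
#' whole family of network x outcome tests. Networks retaining fewer than two
#' ROIs are skipped with a warning (this mirrors the depletion of small
#' networks by the reliability screen).
#'
#' @param X Subjects x ROIs predictor matrix (reliable ROIs).
#' @param scores data.frame with \code{family_id} and one column per outcome.
#' @param networks Named character vector: network label per ROI (names =
#'   colnames of X).
#' @param outcomes Outcome columns of \code{scores} to predict.
#' @param lambdaGrid,screenP,nBoot Passed to \code{\link{lofovPredict}}.
#' @param fdrQ FDR level for the rejection flags (default 0.05).
#' @param seed Optional integer seed (bootstrap CIs).
#' @return data.frame with one row per network x outcome: \code{network},
#'   \code{outcome}, \code{nRois}, \code{accuracy}, \code{rawR}, \code{p},
#'   \code{pAdjusted}, \code{significant}, \code{lambda}, \code{ciLow},
#'   \code{ciHigh}.
#' @export
perNetworkPrediction <- function(X, scores, networks,
                                 outcomes = c("g", "vis", "cry", "mem", "spd"),
                                 lambdaGrid = 10^(-2:5), screenP = NULL,
                                 nBoot = 1000, fdrQ = 0.05, seed = NULL) {
  if (is.null(colnames(X))) stop("X must have ROI column names")
  if (!all(colnames(X) %in% names(networks)))
    stop("every ROI in X needs a network label")
  if (!all(outcomes %in% names(scores)))
    stop("missing outcome column(s): ", paste(setdiff(outcomes, names(scores)), collapse = ", "))
  nets <- unique(unname(networks[colnames(X)]))
  rows <- list()
  for (net in nets) {
    roi <- colnames(X)[networks[colnames(X)] == net]
    if (length(roi) < 2L) {
      warning(sprintf("network '%s' retains %d ROI(s); skipped", net, length(roi)))
      next
    }
    for (oc in outcomes) {
      fit <- lofovPredict(X[, roi, drop = FALSE], scores[[oc]],
                          scores$family_id, lambdaGrid = lambdaGrid,
                          screenP = screenP, nBoot = nBoot, seed = seed)
      rows[[length(rows) + 1L]] <- data.frame(
        network = net, outcome = oc, nRois = length(roi),
        accuracy = fit$accuracy, rawR = fit$rawR, p = fit$p,
        lambda = fit$lambda,
        ciLow = if (is.null(fit$ci95)) NA_real_ else fit$ci95[1],
        ciHigh = if (is.null(fit$ci95)) NA_real_ else fit$ci95[2],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  adj <- bhAdjust(out$p, q = fdrQ)
  out$pAdjusted <- adj$adjusted
  out$significant <- adj$reject
  out
}
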