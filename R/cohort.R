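## Resting-state network labels and their relative sizes (ROIs per network in
## a whole-cortex 360-area parcellation), used to apportion synthetic ROIs.
.networkRatios <- c(VIS = 59, SM = 52, ATT = 44, SAL = 49, LIM = 28,
                    FP = 45, DMN = 83)

## Largest-remainder apportionment of nRois across the seven networks.
.apportionNetworks <- function(nRois, ratios = .networkRatios) {
  share <- ratios / sum(ratios) * nRois
  base <- floor(share)
  rem <- nRois - sum(base)
  if (rem > 0) {
    extra <- order(share - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  stats::setNames(as.integer(base), names(ratios))
}

#' Configuration of a synthetic resting-state cohort
#'
#' Defines the study conditions emulated by \code{\link{generateCohort}}: a
#' two-session, two-run resting-state design with ~1200-sample runs, a
#' seven-network parcellation with network sizes proportional to a
#' whole-cortex atlas, family structure with 1-3 siblings, a small fraction
#' of pure-noise ROIs concentrated in the limbic-like network, structural
#' properties coupled to signal irregularity at the group (blueprint) and
#' individual (fingerprint) level, and cognitive factor scores linearly
#' loaded on the entropy profile. All stochastic defaults are documented in
#' the package vignette.
#'
#' @param nSubjects Number of subjects.
#' @param nRois Number of ROIs.
#' @param nTimepoints Samples per run (default 1200).
#' @param nRuns Runs per session (default 2).
#' @param nSessions Sessions (default 2).
#' @param networkSizes Optional named integer vector of ROIs per network
#'   (must sum to \code{nRois}); by default apportioned from whole-cortex
#'   atlas ratios.
#' @param noiseRoiFraction Fraction of ROIs that are pure white noise with no
#'   subject-specific signal, placed in the LIM network first (default 0.05).
#' @param familySizeProbs Named probabilities of family sizes (default sizes
#'   1:3 with probabilities 0.55/0.30/0.15).
#' @param siblingShare Fraction of the variance of shared individual
#'   deviations (structural deviations and latent factors) common to
#'   siblings (default 0.5).
#' @param baselinePhi Baseline AR(1) coefficient of the simulated BOLD-like
#'   signals (default 0.3).
#' @param nFactors Number of latent factors generating correlated individual
#'   deviations across ROIs (default 15).
#' @param factorSd Per-ROI standard deviation of the factor component of the
#'   latent irregularity (default 0.25).
#' @param factorDecay Geometric decay of the factor scales, so a few dominant
#'   modes carry most of the shared individual variance (default 0.85).
#' @param idiosyncraticSd SD of the purely individual, unshared component
#'   (default 0.15).
#' @param sessionJitterSd SD of the session-level jitter added to the AR
#'   coefficient (default 0.04; this sets the test-retest reliability).
#' @param blueprintCouplings Named signed couplings of the standardized
#'   structural blueprints into the cross-ROI irregularity blueprint.
#' @param individualCouplings Named signed couplings of standardized
#'   individual structural deviations into individual irregularity
#'   deviations.
#' @param blueprintNoiseSd SD of the structural-unexplained part of the
#'   irregularity blueprint (default 0.10).
#' @param cognitiveR2 Named population R-squared of each cognitive outcome on
#'   the expected entropy profile.
#' @param nCognitiveFactors Number of leading latent factors the cognitive
#'   weights load on (default 3).
#' @param connectivity List of parameters of the weighted random graph:
#'   \code{logPropensitySd}, \code{subjectPropensitySd}, \code{pairNoiseSd},
#'   \code{directionNoiseSd}, \code{targetDensity}, \code{threshold}.
#' @return A validated list of class \code{CohortConfig}.
#' @export
cohortConfig <- function(nSubjects = 100, nRois = 100, nTimepoints = 1200,
                         nRuns = 2, nSessions = 2, networkSizes = NULL,
                         noiseRoiFraction = 0.05,
                         familySizeProbs = c("1" = 0.55, "2" = 0.30, "3" = 0.15),
                         siblingShare = 0.5, baselinePhi = 0.3,
                         nFactors = 15, factorSd = 0.25, factorDecay = 0.85,
                         idiosyncraticSd = 0.15, sessionJitterSd = 0.04,
                         blueprintCouplings = c(thickness = 0.25, myelin = -0.08,
                                                curv = -0.08, sulc = -0.08,
                                                strength = -0.10, degree = -0.18),
                         individualCouplings = c(thickness = 0, myelin = 0.10,
                                                 curv = 0.10, sulc = 0.14,
                                                 strength = 0, degree = 0),
                         blueprintNoiseSd = 0.10,
                         cognitiveR2 = c(g = 0.30, vis = 0.15, cry = 0.20,
                                         mem = 0.15, spd = 0.10),
                         nCognitiveFactors = 3,
                         connectivity = list(logPropensitySd = 0.4,
                                             subjectPropensitySd = 0.12,
                                             pairNoiseSd = 0.8,
                                             directionNoiseSd = 0.6,
                                             targetDensity = 0.10,
                                             threshold = 0.001)) {
  if (is.null(networkSizes)) networkSizes <- .apportionNetworks(nRois)
  cfg <- list(nSubjects = as.integer(nSubjects), nRois = as.integer(nRois),
              nTimepoints = as.integer(nTimepoints), nRuns = as.integer(nRuns),
              nSessions = as.integer(nSessions), networkSizes = networkSizes,
              noiseRoiFraction = noiseRoiFraction,
              familySizeProbs = familySizeProbs, siblingShare = siblingShare,
              baselinePhi = baselinePhi, nFactors = as.integer(nFactors),
              factorSd = factorSd, factorDecay = factorDecay,
              idiosyncraticSd = idiosyncraticSd,
              sessionJitterSd = sessionJitterSd,
              blueprintCouplings = blueprintCouplings,
              individualCouplings = individualCouplings,
              blueprintNoiseSd = blueprintNoiseSd,
              cognitiveR2 = cognitiveR2,
              nCognitiveFactors = as.integer(nCognitiveFactors),
              connectivity = connectivity)
  class(cfg) <- "CohortConfig"
  validateCohortConfig(cfg)
  cfg
}

#' @rdname cohortConfig
#' @param config A \code{CohortConfig} to validate.
#' @export
validateCohortConfig <- function(config) {
  stopifnot(inherits(config, "CohortConfig"))
  with(config, {
    if (nSubjects < 2L) stop("infeasible config: need at least two subjects")
    if (nRois < 3L) stop("infeasible config: need at least three ROIs")
    if (sum(networkSizes) != nRois)
      stop("infeasible config: network sizes must sum to nRois")
    if (noiseRoiFraction < 0 || noiseRoiFraction >= 1)
      stop("infeasible config: noiseRoiFraction must lie in [0, 1)")
    if (abs(sum(familySizeProbs) - 1) > 1e-8)
      stop("infeasible config: family size probabilities must sum to 1")
    if (siblingShare < 0 || siblingShare > 1)
      stop("infeasible config: siblingShare must lie in [0, 1]")
    if (baselinePhi <= 0 || baselinePhi >= 0.95)
      stop("infeasible config: baselinePhi must lie in (0, 0.95)")
    if (any(cognitiveR2 < 0) || any(cognitiveR2 > 1))
      stop("infeasible config: cognitive R-squared values must lie in [0, 1]")
    if (sessionJitterSd < 0) stop("infeasible config: sessionJitterSd must be >= 0")
    if (nCognitiveFactors > nFactors)
      stop("infeasible config: nCognitiveFactors cannot exceed nFactors")
    if (factorDecay <= 0 || factorDecay > 1)
      stop("infeasible config: factorDecay must lie in (0, 1]")
  })
  invisible(config)
}

## Sibling-structured standard-normal matrix: siblings share sqrt(share) of a
## family-level draw, so within-family correlation is `share` and marginals
## stay N(0, 1).
.familyNormal <- function(famIdx, k, share) {
  nFam <- max(famIdx)
  base <- matrix(rnorm(nFam * k), nFam, k)
  own <- matrix(rnorm(length(famIdx) * k), length(famIdx), k)
  sqrt(share) * base[famIdx, , drop = FALSE] + sqrt(1 - share) * own
}

## Latent scales of the morphometric properties (blueprint mean, blueprint
## SD across ROIs, individual-deviation SD).
.morphometry <- list(
  thickness = c(mean = 2.6, bpSd = 0.25, devSd = 0.12),   # mm
  myelin    = c(mean = 1.4, bpSd = 0.15, devSd = 0.08),   # T1w/T2w ratio
  curv      = c(mean = 0.10, bpSd = 0.04, devSd = 0.02),  # 1/mm
  sulc      = c(mean = 0.0, bpSd = 0.55, devSd = 0.15))   # mm

#' Generate a synthetic cohort with known ground truth
#'
#' Simulates every input the analysis pipeline consumes. Per-ROI structural
#' blueprints and individual structural deviations feed a latent
#' irregularity field \code{a[i, n]} through signed couplings; the AR(1)
#' coefficient of each subject x ROI signal is a logistic squash of
#' \code{-a[i, n]} into (0, 0.95), so higher latent irregularity means lower
#' temporal autocorrelation and higher dispersion entropy. Each session adds
#' Gaussian jitter to the AR coefficient (shared by the session's runs) and
#' each run draws fresh innovations. Noise ROIs are i.i.d. white noise in
#' every run with no subject effect. Per-subject directed connective
#' probability matrices are drawn from a propensity-weighted random graph
#' calibrated so that symmetrization and thresholding retains approximately
#' the configured link density; node strength and degree computed from those
#' matrices are the connectivity entries of the structural profiles.
#' Cognitive outcomes load linearly on the expected entropy profile with
#' noise calibrated to the configured population R-squared. All randomness
#' flows through R's RNG, so a fixed seed reproduces the cohort bitwise.
#'
#' @param config A \code{\link{cohortConfig}} list.
#' @param seed Optional integer seed.
#' @return A \code{\link{SyntheticCohort}}.
#' @export
generateCohort <- function(config = cohortConfig(), seed = NULL) {
  validateCohortConfig(config)
  if (!is.null(seed)) set.seed(seed)
  nS <- config$nSubjects
  nR <- config$nRois
  nT <- config$nTimepoints
  nRun <- config$nRuns
  nSes <- config$nSessions

  roiIds <- sprintf("ROI%03d", seq_len(nR))
  network <- rep(names(config$networkSizes), config$networkSizes)
  parcellation <- data.frame(roi_id = roiIds,
                             hemisphere = rep_len(c("L", "R"), nR),
                             network = network, stringsAsFactors = FALSE)

  ## noise ROIs: LIM-like regions first, spillover at random
  nNoise <- round(config$noiseRoiFraction * nR)
  lim <- which(network == "LIM")
  noiseIdx <- if (nNoise <= length(lim)) sort(sample(lim, nNoise)) else
    sort(c(lim, sample(setdiff(seq_len(nR), lim), nNoise - length(lim))))
  noiseMask <- seq_len(nR) %in% noiseIdx

  ## family structure
  sizes <- as.integer(names(config$familySizeProbs))
  famSizes <- integer(0)
  while (sum(famSizes) < nS)
    famSizes <- c(famSizes, sample(sizes, 1L, prob = config$familySizeProbs))
  famIdx <- rep(seq_along(famSizes), famSizes)[seq_len(nS)]
  familyIds <- sprintf("F%04d", famIdx)
  subjectIds <- sprintf("S%04d", seq_len(nS))

  ## --- structural connectivity -------------------------------------------
  cc <- config$connectivity
  lgBlue <- cc$logPropensitySd * rnorm(nR)
  lgDev <- .familyNormal(famIdx, nR, config$siblingShare)
  connectivity <- vector("list", nS)
  strength <- matrix(NA_real_, nS, nR, dimnames = list(subjectIds, roiIds))
  degree <- strength
  off <- row(matrix(0, nR, nR)) != col(matrix(0, nR, nR))
  for (i in seq_len(nS)) {
    lg <- lgBlue + cc$subjectPropensitySd * lgDev[i, ]
    pair <- matrix(rnorm(nR * nR, sd = cc$pairNoiseSd), nR, nR)
    pair <- (pair + t(pair)) / sqrt(2)
    dirn <- matrix(rnorm(nR * nR, sd = cc$directionNoiseSd), nR, nR)
    lp <- outer(lg, lg, `+`) + pair + dirn
    wsym0 <- (exp(lp) + exp(t(lp))) / 2
    cut <- quantile(wsym0[off], 1 - cc$targetDensity, type = 7)
    p <- exp(lp) * (cc$threshold / cut)
    p[p > 1] <- 1
    diag(p) <- 0
    dimnames(p) <- list(roiIds, roiIds)
    connectivity[[i]] <- p
    met <- nodeMetrics(symmetrizeThreshold(p, cc$threshold))
    strength[i, ] <- met$strength
    degree[i, ] <- met$degree
  }
  names(connectivity) <- subjectIds

  ## --- morphometry --------------------------------------------------------
  structure_ <- list()
  zeta <- list()   # standardized individual deviations, sibling-structured
  bp <- list()     # latent blueprints in property units
  for (pp in names(.morphometry)) {
    sc <- .morphometry[[pp]]
    bp[[pp]] <- sc[["mean"]] + sc[["bpSd"]] * rnorm(nR)
    zeta[[pp]] <- .familyNormal(famIdx, nR, config$siblingShare)
    m <- rep(bp[[pp]], each = nS) + sc[["devSd"]] * zeta[[pp]]
    dim(m) <- c(nS, nR)
    dimnames(m) <- list(subjectIds, roiIds)
    structure_[[pp]] <- m
  }
  structure_$strength <- strength
  structure_$degree <- degree

  ## standardized blueprints (morphometry: latent; connectivity: realized)
  zbp <- cbind(
    thickness = drop(scale(bp$thickness)), myelin = drop(scale(bp$myelin)),
    curv = drop(scale(bp$curv)), sulc = drop(scale(bp$sulc)),
    strength = drop(scale(colMeans(strength))),
    degree = drop(scale(colMeans(degree))))
  ## standardized individual deviations per property
  .colStandardize <- function(m) {
    d <- sweep(m, 2L, colMeans(m))
    sdv <- apply(d, 2L, sd)
    sdv[!(sdv > 0)] <- 1
    sweep(d, 2L, sdv, "/")
  }
  zdev <- list(thickness = zeta$thickness, myelin = zeta$myelin,
               curv = zeta$curv, sulc = zeta$sulc,
               strength = .colStandardize(strength),
               degree = .colStandardize(degree))

  ## --- latent irregularity and AR coefficients ---------------------------
  bcp <- config$blueprintCouplings
  icp <- config$individualCouplings
  blueprintA <- drop(zbp[, names(bcp), drop = FALSE] %*% bcp) +
    config$blueprintNoiseSd * rnorm(nR)
  ## decaying factor spectrum: a few dominant modes of individual variation,
  ## scaled so the expected per-ROI factor variance equals factorSd^2
  sk <- config$factorDecay^(seq_len(config$nFactors) - 1L)
  sk <- config$factorSd * sk / sqrt(sum(sk^2))
  L <- sweep(matrix(rnorm(nR * config$nFactors), nR, config$nFactors), 2L, sk, "*")
  f <- .familyNormal(famIdx, config$nFactors, config$siblingShare)
  dev <- f %*% t(L) +
    config$idiosyncraticSd * matrix(rnorm(nS * nR), nS, nR)
  for (pp in names(icp)) if (icp[[pp]] != 0) dev <- dev + icp[[pp]] * zdev[[pp]]
  a <- rep(blueprintA, each = nS) + dev
  dim(a) <- c(nS, nR)
  phi <- 0.95 * plogis(qlogis(config$baselinePhi / 0.95) - a)
  phi[, noiseMask] <- 0
  dimnames(phi) <- list(subjectIds, roiIds)

  phiSession <- array(phi, c(nS, nR, nSes),
                      dimnames = list(subjectIds, roiIds, NULL))
  if (config$sessionJitterSd > 0) {
    jit <- array(rnorm(nS * nR * nSes, sd = config$sessionJitterSd),
                 c(nS, nR, nSes))
    jit[, noiseMask, ] <- 0
    phiSession <- pmin(pmax(phiSession + jit, 0), 0.949)
  }

  ## --- time series --------------------------------------------------------
  sessionNames <- paste0("REST", seq_len(nSes))
  runNames <- paste0("run", seq_len(nRun))
  series <- vector("list", nS)
  for (i in seq_len(nS)) {
    ## columns ordered (roi, run, session) with roi fastest; innovations are
    ## drawn from R's RNG inside the compiled recursion
    phivec <- as.vector(phiSession[i, , rep(seq_len(nSes), each = nRun)])
    arr <- cpp_ar1_gen(nT, phivec)
    dim(arr) <- c(nT, nR, nRun, nSes)
    series[[i]] <- arr
  }
  ts <- RoiTimeSeries(series, subjectIds, roiIds, sessionNames, runNames)

  ## --- cognitive scores ---------------------------------------------------
  entProxy <- -sweep(phi, 2L, colMeans(phi))   # expected entropy deviations
  outcomes <- names(config$cognitiveR2)
  weights <- matrix(0, nR, length(outcomes), dimnames = list(roiIds, outcomes))
  signal <- matrix(0, nS, length(outcomes), dimnames = list(subjectIds, outcomes))
  scores <- data.frame(subject_id = subjectIds, family_id = familyIds,
                       stringsAsFactors = FALSE)
  for (oc in outcomes) {
    v <- rnorm(config$nCognitiveFactors)
    w <- drop(L[, seq_len(config$nCognitiveFactors), drop = FALSE] %*% v)
    w[noiseMask] <- 0
    nrm <- sqrt(sum(w^2))
    if (nrm > 0) w <- w / nrm
    weights[, oc] <- w
    sig <- drop(entProxy %*% w)
    r2 <- config$cognitiveR2[[oc]]
    if (sd(sig) > 0 && r2 > 0) {
      signal[, oc] <- drop(scale(sig))
      scores[[oc]] <- sqrt(r2) * signal[, oc] + sqrt(1 - r2) * rnorm(nS)
    } else {
      scores[[oc]] <- rnorm(nS)
    }
  }

  truth <- list(noiseMask = noiseMask, phi = phi, phiSession = phiSession,
                blueprintA = blueprintA, factorLoadings = L, factors = f,
                weights = weights, signal = signal, zbp = zbp,
                sessionJitterSd = config$sessionJitterSd,
                blueprintCouplings = bcp, individualCouplings = icp)
  new("SyntheticCohort", timeseries = ts, structure = structure_,
      connectivity = connectivity, scores = scores,
      parcellation = parcellation, truth = truth, config = unclass(config))
}

#' Map fine parcel labels to coarse network labels by highest overlap
#'
#' Each fine region is assigned the coarse label covering the plurality of
#' its vertices; ties break towards the alphabetically first coarse label.
#'
#' @param fine,coarse Equal-length per-vertex label vectors.
#' @return Named vector: coarse label per fine region.
#' @export
assignNetworksByOverlap <- function(fine, coarse) {
  if (length(fine) != length(coarse)) stop("label vectors must have equal length")
  if (length(fine) == 0L) stop("empty region: no vertices")
  tab <- table(fine, coarse)
  if (any(rowSums(tab) == 0L)) stop("empty region: a fine region has no vertices")
  lab <- colnames(tab)[apply(tab, 1L, which.max)]  # which.max: first = sorted-first label
  stats::setNames(lab, rownames(tab))
}
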