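## Stage timer: logs to stderr only, so report files stay byte-reproducible.
.stageLog <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  message(sprintf("[%s] started", name))
  out <- force(expr)
  message(sprintf("[%s] done in %.1f s", name, proc.time()[["elapsed"]] - t0))
  out
}

.writeReport <- function(x, dir, name) {
  jsonlite::write_json(x, file.path(dir, name), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
}

#' Run the full entropy-profile analysis
#'
#' Orchestrates every stage on one cohort, in dependency order: entropy
#' profiling of both sessions, reliability screening against the
#' permuted-signal null, fingerprint identification and differentiation
#' power on the reliable ROIs, ridge/LOFOV prediction of the cognitive
#' scores (whole cortex and per network), and the structural analyses
#' (connectivity metrics, blueprint correlations, cross-individual
#' correlations, and structure-based entropy-profile prediction per
#' property). One JSON report per stage plus a top-level summary is written
#' to \code{outDir}; floats are serialized at full precision and nothing
#' time-dependent is written, so an identical cohort, configuration and seed
#' produce byte-identical reports. Progress and stage timings go to stderr.
#'
#' @param config A \code{\link{cohortConfig}} describing the cohort to
#'   simulate; ignored when \code{cohort} is supplied.
#' @param outDir Output directory for the report bundle.
#' @param seed Integer seed governing every stochastic step (simulation,
#'   permutations, bootstraps).
#' @param cohort Optional pre-built \code{\link{SyntheticCohort}} (e.g. from
#'   \code{\link{readCohort}}).
#' @param params \code{\link{DispersionParams}} for the entropy stage.
#' @param nPerm Permutations per identification direction.
#' @param nBoot Bootstrap replicates for CIs.
#' @param lambdaGrid Ridge penalty grid.
#' @param fdrQ FDR level for multiplicity-corrected families.
#' @param connectivityThreshold Structural weight threshold.
#' @param perNetwork Also run the per-network predictions (default TRUE).
#' @return Invisibly, a list with all stage results.
#' @export
runFullAnalysis <- function(config = cohortConfig(), outDir, seed = 1,
                            cohort = NULL, params = DispersionParams(),
                            nPerm = 500, nBoot = 1000,
                            lambdaGrid = 10^(-2:5), fdrQ = 0.05,
                            connectivityThreshold = 0.001,
                            perNetwork = TRUE) {
  ## validate everything before any computation
  validateCohortConfig(config)
  stopifnot(is(params, "DispersionParams"), nPerm >= 1, nBoot >= 0)
  if (!is.null(cohort)) {
    stopifnot(is(cohort, "SyntheticCohort"))
    if (!all(c("subject_id", "family_id") %in% names(cohort@scores)))
      stop("cohort scores lack subject_id/family_id columns")
  }
  if (!dir.exists(outDir) && !dir.create(outDir, recursive = TRUE))
    stop("cannot create output directory: ", outDir)

  if (is.null(cohort))
    cohort <- .stageLog("simulate", generateCohort(config, seed = seed))
  .writeReport(cohort@config, outDir, "config.json")

  nets <- stats::setNames(cohort@parcellation$network, cohort@parcellation$roi_id)
  ep <- .stageLog("entropy", entropyProfiles(cohort@timeseries, params,
                                             parcellation = cohort@parcellation))
  writeEntropyProfiles(ep, file.path(outDir, "entropy_profiles.tsv"))
  d1 <- profileMatrix(ep, 1L)
  d2 <- profileMatrix(ep, 2L)

  rel <- .stageLog("reliability", {
    r <- regionalReliability(d1, d2)
    null <- permutedEntropyNull(cohort@timeseries, params, session = 1L,
                                seed = seed + 1L)
    flagUnreliableRois(r, grandMeanEntropy(ep), null)
  })
  reliable <- rel$roi_id[!rel$flagged]
  relMeta <- S4Vectors::metadata(rel)
  relReport <- list(thresholds = relMeta,
                    nFlagged = sum(rel$flagged), nRetained = length(reliable),
                    flaggedRois = rel$roi_id[rel$flagged],
                    table = as.data.frame(rel))
  .writeReport(relReport, outDir, "reliability.json")
  relTsv <- as.data.frame(rel)
  relTsv$network <- unname(nets[relTsv$roi_id])
  write.table(relTsv[, c("roi_id", "network", "reliability", "mean_entropy",
                         "flagged")],
              file.path(outDir, "reliability.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  fp <- .stageLog("fingerprint", {
    fpr <- fingerprintTest(d1[, reliable, drop = FALSE],
                           d2[, reliable, drop = FALSE],
                           nPerm = nPerm, nBoot = nBoot, seed = seed + 2L)
    dp <- differentiationPower(d1[, reliable, drop = FALSE],
                               d2[, reliable, drop = FALSE])
    list(test = fpr, dp = dp)
  })
  .writeReport(list(accuracy = as.list(fp$test@accuracy),
                    permutationP = fp$test@permutationP,
                    perDirectionP = as.list(fp$test@perDirectionP),
                    ci95 = apply(fp$test@ci95, 1L, as.list),
                    nPermutations = fp$test@nPermutations,
                    criterion = fp$test@criterion,
                    satisfied = as.list(fp$test@satisfied),
                    dp = as.list(fp$dp$dp)),
               outDir, "fingerprint.json")

  avg <- sessionAverage(ep)[, reliable, drop = FALSE]
  outcomes <- intersect(c("g", "vis", "cry", "mem", "spd"),
                        names(cohort@scores))
  pred <- .stageLog("prediction", {
    whole <- lapply(stats::setNames(outcomes, outcomes), function(oc)
      lofovPredict(avg, cohort@scores[[oc]], cohort@scores$family_id,
                   lambdaGrid = lambdaGrid, nBoot = nBoot,
                   seed = seed + 3L))
    byNet <- if (perNetwork)
      perNetworkPrediction(avg, cohort@scores, nets, outcomes = outcomes,
                           lambdaGrid = lambdaGrid, nBoot = 0,
                           fdrQ = fdrQ) else NULL
    list(whole = whole, byNetwork = byNet)
  })
  .writeReport(list(
    wholeCortex = lapply(pred$whole, function(f)
      list(accuracy = f$accuracy, rawR = f$rawR, p = f$p,
           ci95 = as.list(f$ci95), lambda = f$lambda,
           nFamilies = f$nFamilies)),
    meanAbsWeight = lapply(pred$whole, function(f) as.list(f$meanAbsWeight)),
    byNetwork = pred$byNetwork), outDir, "prediction.json")

  struct <- .stageLog("structure", {
    metrics <- lapply(cohort@connectivity, function(p)
      nodeMetrics(symmetrizeThreshold(p, connectivityThreshold)))
    strength <- do.call(rbind, lapply(metrics, function(m) m$strength))
    degree <- do.call(rbind, lapply(metrics, function(m) m$degree))
    dimnames(strength) <- dimnames(degree) <-
      list(names(metrics), cohort@parcellation$roi_id)
    props <- cohort@structure
    props$strength <- strength
    props$degree <- degree
    propsRel <- lapply(props, function(m) m[, reliable, drop = FALSE])
    bp <- blueprintCorrelations(
      grandMeanEntropy(ep)[reliable],
      vapply(propsRel, colMeans, numeric(length(reliable))),
      nBoot = nBoot, seed = seed + 4L, fdrQ = fdrQ)
    avgRel <- sessionAverage(ep)[, reliable, drop = FALSE]
    regional <- regionalStructureCorrelations(avgRel, propsRel, networks = nets)
    s2e <- lapply(stats::setNames(names(propsRel), names(propsRel)), function(pp)
      structureToEntropyPrediction(avgRel, propsRel[[pp]],
                                   cohort@scores$family_id,
                                   nPerm = 2L * nPerm, nBoot = nBoot,
                                   seed = seed + 5L))
    list(blueprint = bp, regional = regional, s2e = s2e)
  })
  .writeReport(list(
    blueprint = struct$blueprint,
    networkMeanR = as.data.frame(struct$regional$networkMean),
    structurePrediction = lapply(struct$s2e, function(x)
      list(accuracy = x$accuracy, permutationP = x$permutationP,
           ci95 = as.list(x$ci95), medianSimilarity = median(x$similarity),
           satisfied = x$satisfied))), outDir, "structure.json")

  summary <- list(
    nSubjects = nrow(cohort@scores), nRois = nrow(cohort@parcellation),
    seed = seed,
    reliability = list(thReliability = relMeta$thReliability,
                       thEntropy = relMeta$thEntropy,
                       nFlagged = sum(rel$flagged)),
    fingerprint = list(accuracy = as.list(fp$test@accuracy),
                       permutationP = fp$test@permutationP),
    prediction = lapply(pred$whole, function(f)
      list(accuracy = f$accuracy, p = f$p)),
    blueprint = stats::setNames(as.list(struct$blueprint$r),
                                struct$blueprint$property),
    structureIdentification = lapply(struct$s2e, function(x)
      list(accuracy = x$accuracy, permutationP = x$permutationP)))
  .writeReport(summary, outDir, "summary.json")

  invisible(list(cohort = cohort, profiles = ep, reliability = rel,
                 fingerprint = fp, prediction = pred, structure = struct,
                 summary = summary))
}
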