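## Full-precision TSV writers/readers: %.17g round-trips doubles exactly.
.writeNumericTsv <- function(m, path, rowIds = NULL, colIds = NULL) {
  ch <- sprintf("%.17g", m)
  dim(ch) <- dim(m)
  if (!is.null(colIds)) colnames(ch) <- colIds
  if (!is.null(rowIds)) {
    ch <- cbind(id = rowIds, ch)
  }
  write.table(ch, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = !is.null(colIds) || !is.null(rowIds))
}

.readNumericTsv <- function(path, header, nExpectedCols = NULL, idColumn = FALSE) {
  d <- tryCatch(read.table(path, sep = "\t", header = header,
                           stringsAsFactors = FALSE,
                           colClasses = NA, check.names = FALSE),
                error = function(e)
                  stop(sprintf("parse error in file '%s': %s", path,
                               conditionMessage(e)), call. = FALSE))
  ids <- NULL
  if (idColumn) {
    ids <- as.character(d[[1]])
    d <- d[, -1, drop = FALSE]
  }
  m <- as.matrix(d)
  if (!is.numeric(m))
    stop(sprintf("parse error in file '%s': non-numeric entries", path), call. = FALSE)
  if (!is.null(nExpectedCols) && ncol(m) != nExpectedCols)
    stop(sprintf("parse error in file '%s': expected %d data columns, found %d",
                 path, nExpectedCols, ncol(m)), call. = FALSE)
  if (!is.null(ids)) rownames(m) <- ids
  m
}

#' Write a synthetic cohort to a directory of plain-text files
#'
#' Serializes all pipeline inputs in the package's on-disk formats: one TSV
#' matrix per subject/session/run (ROIs as rows, samples as columns) with a
#' JSON sidecar (subject_id, session, run, TR); a parcellation TSV; a long
#' structural-profile TSV (subject_id, roi_id, property, value); one square
#' connectivity TSV per subject; a scores TSV; a JSON manifest; and the
#' ground truth (JSON plus full-precision TSVs for the latent AR
#' coefficients). Numeric values are written with 17 significant digits so
#' that \code{\link{readCohort}} reproduces every array exactly.
#'
#' @param cohort A \code{\link{SyntheticCohort}}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(is(cohort, "SyntheticCohort"))
  for (d in file.path(dir, c("", "timeseries", "connectivity", "truth")))
    if (!dir.exists(d) && !dir.create(d, recursive = TRUE))
      stop("cannot create directory: ", d)
  ts <- cohort@timeseries
  manifest <- list(subject_ids = ts@subjectIds, roi_ids = ts@roiIds,
                   session_names = ts@sessionNames, run_names = ts@runNames,
                   n_timepoints = dim(ts@series[[1]])[1], tr = 0.72,
                   properties = names(cohort@structure))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(cohort@config, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write.table(cohort@parcellation, file.path(dir, "parcellation.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  sc <- cohort@scores
  num <- vapply(sc, is.numeric, logical(1))
  sc[num] <- lapply(sc[num], function(x) sprintf("%.17g", x))
  write.table(sc, file.path(dir, "scores.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  long <- do.call(rbind, lapply(names(cohort@structure), function(pp) {
    m <- cohort@structure[[pp]]
    data.frame(subject_id = rep(rownames(m), times = ncol(m)),
               roi_id = rep(colnames(m), each = nrow(m)),
               property = pp, value = sprintf("%.17g", as.vector(m)),
               stringsAsFactors = FALSE)
  }))
  write.table(long, file.path(dir, "structure.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (id in names(cohort@connectivity))
    .writeNumericTsv(cohort@connectivity[[id]],
                     file.path(dir, "connectivity", paste0(id, ".tsv")),
                     colIds = ts@roiIds)
  for (i in seq_along(ts@subjectIds)) {
    for (s in seq_along(ts@sessionNames)) {
      for (r in seq_along(ts@runNames)) {
        stem <- sprintf("%s_%s_%s", ts@subjectIds[i], ts@sessionNames[s],
                        ts@runNames[r])
        m <- t(ts@series[[i]][, , r, s])   # ROIs as rows, samples as columns
        .writeNumericTsv(m, file.path(dir, "timeseries", paste0(stem, ".tsv")))
        jsonlite::write_json(list(subject_id = ts@subjectIds[i],
                                  session = ts@sessionNames[s],
                                  run = ts@runNames[r], tr = 0.72),
                             file.path(dir, "timeseries", paste0(stem, ".json")),
                             auto_unbox = TRUE)
      }
    }
  }
  tr <- cohort@truth
  .writeNumericTsv(tr$phi, file.path(dir, "truth", "phi.tsv"),
                   rowIds = rownames(tr$phi), colIds = colnames(tr$phi))
  for (s in seq_len(dim(tr$phiSession)[3]))
    .writeNumericTsv(tr$phiSession[, , s],
                     file.path(dir, "truth", sprintf("phi_session%d.tsv", s)),
                     rowIds = ts@subjectIds, colIds = ts@roiIds)
  .writeNumericTsv(tr$weights, file.path(dir, "truth", "weights.tsv"),
                   rowIds = rownames(tr$weights), colIds = colnames(tr$weights))
  scalars <- list(noiseMask = tr$noiseMask,
                  sessionJitterSd = tr$sessionJitterSd,
                  blueprintCouplings = as.list(tr$blueprintCouplings),
                  individualCouplings = as.list(tr$individualCouplings))
  jsonlite::write_json(scalars, file.path(dir, "truth", "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort written by \code{\link{writeCohort}}
#'
#' @param dir Directory produced by \code{\link{writeCohort}}.
#' @return A \code{\link{SyntheticCohort}} whose data arrays equal the
#'   written cohort's exactly (the truth list is restored up to the fields
#'   serialized by \code{writeCohort}).
#' @export
readCohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  config <- jsonlite::read_json(file.path(dir, "config.json"),
                                simplifyVector = TRUE)
  parcellation <- read.table(file.path(dir, "parcellation.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE)
  scores <- read.table(file.path(dir, "scores.tsv"), sep = "\t", header = TRUE,
                       stringsAsFactors = FALSE)
  nT <- manifest$n_timepoints
  nR <- length(manifest$roi_ids)
  series <- lapply(manifest$subject_ids, function(id) {
    arr <- array(NA_real_, c(nT, nR, length(manifest$run_names),
                             length(manifest$session_names)))
    for (s in seq_along(manifest$session_names)) {
      for (r in seq_along(manifest$run_names)) {
        stem <- sprintf("%s_%s_%s", id, manifest$session_names[s],
                        manifest$run_names[r])
        m <- .readNumericTsv(file.path(dir, "timeseries", paste0(stem, ".tsv")),
                             header = FALSE, nExpectedCols = nT)
        if (nrow(m) != nR)
          stop(sprintf("parse error in file '%s': expected %d ROI rows, found %d",
                       file.path(dir, "timeseries", paste0(stem, ".tsv")),
                       nR, nrow(m)), call. = FALSE)
        arr[, , r, s] <- t(m)
      }
    }
    arr
  })
  ts <- RoiTimeSeries(series, manifest$subject_ids, manifest$roi_ids,
                      manifest$session_names, manifest$run_names)
  long <- read.table(file.path(dir, "structure.tsv"), sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE)
  structure_ <- lapply(split(long, long$property), function(d) {
    m <- matrix(NA_real_, length(manifest$subject_ids), nR,
                dimnames = list(manifest$subject_ids, manifest$roi_ids))
    m[cbind(match(d$subject_id, manifest$subject_ids),
            match(d$roi_id, manifest$roi_ids))] <- d$value
    m
  })[manifest$properties]
  connectivity <- lapply(manifest$subject_ids, function(id) {
    m <- .readNumericTsv(file.path(dir, "connectivity", paste0(id, ".tsv")),
                         header = TRUE, nExpectedCols = nR)
    rownames(m) <- manifest$roi_ids
    m
  })
  names(connectivity) <- manifest$subject_ids
  truthScalars <- jsonlite::read_json(file.path(dir, "truth", "truth.json"),
                                      simplifyVector = TRUE)
  phi <- .readNumericTsv(file.path(dir, "truth", "phi.tsv"), header = TRUE,
                         idColumn = TRUE)
  nSes <- length(manifest$session_names)
  phiSession <- array(NA_real_, c(nrow(phi), nR, nSes),
                      dimnames = list(manifest$subject_ids, manifest$roi_ids, NULL))
  for (s in seq_len(nSes))
    phiSession[, , s] <- .readNumericTsv(
      file.path(dir, "truth", sprintf("phi_session%d.tsv", s)),
      header = TRUE, idColumn = TRUE)
  weights <- .readNumericTsv(file.path(dir, "truth", "weights.tsv"),
                             header = TRUE, idColumn = TRUE)
  truth <- list(noiseMask = truthScalars$noiseMask, phi = phi,
                phiSession = phiSession, weights = weights,
                sessionJitterSd = truthScalars$sessionJitterSd,
                blueprintCouplings = unlist(truthScalars$blueprintCouplings),
                individualCouplings = unlist(truthScalars$individualCouplings))
  new("SyntheticCohort", timeseries = ts, structure = structure_,
      connectivity = connectivity, scores = scores,
      parcellation = parcellation, truth = truth, config = as.list(config))
}
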