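test_that("cohort generation is bitwise deterministic under a fixed seed", {
  cfg <- cohortConfig(nSubjects = 6, nRois = 14, nTimepoints = 120)
  a <- generateCohort(cfg, seed = 5)
  b <- generateCohort(cfg, seed = 5)
  expect_identical(a@timeseries@series, b@timeseries@series)
  expect_identical(a@structure, b@structure)
  expect_identical(a@connectivity, b@connectivity)
  expect_identical(a@scores, b@scores)
  expect_identical(a@truth, b@truth)
  c_ <- generateCohort(cfg, seed = 6)
  expect_false(identical(a@scores, c_@scores))
})

test_that("configuration invariants are enforced", {
  expect_error(cohortConfig(cognitiveR2 = c(g = 1.2)), "R-squared")
  expect_error(cohortConfig(noiseRoiFraction = 1), "noiseRoiFraction")
  expect_error(cohortConfig(nRois = 20, networkSizes = c(VIS = 5, DMN = 5)),
               "sum to nRois")
  expect_error(cohortConfig(familySizeProbs = c("1" = 0.5, "2" = 0.3)), "sum to 1")
  expect_error(cohortConfig(baselinePhi = 0.99), "baselinePhi")
  expect_error(cohortConfig(factorDecay = 0), "factorDecay")
  # network apportionment: sums match, DMN largest and LIM smallest
  sizes <- cohortConfig(nRois = 100)$networkSizes
  expect_equal(sum(sizes), 100)
  expect_equal(names(which.max(sizes)), "DMN")
  expect_equal(names(which.min(sizes)), "LIM")
})

test_that("cohort structure matches its configuration", {
  co <- tinyCohort()
  cfg <- co@config
  expect_equal(nrow(co@scores), cfg$nSubjects)
  expect_equal(nrow(co@parcellation), cfg$nRois)
  expect_length(co@connectivity, cfg$nSubjects)
  # families partition subjects with sizes within the configured support
  sizes <- table(co@scores$family_id)
  expect_true(all(sizes %in% 1:3))
  # noise ROIs live in the LIM network first
  noiseNets <- co@parcellation$network[co@truth$noiseMask]
  expect_true(all(noiseNets == "LIM"))
  # directed probabilities are valid and asymmetric
  p <- co@connectivity[[1]]
  expect_true(all(p >= 0 & p <= 1))
  expect_false(isTRUE(all.equal(p, t(p))))
  expect_equal(unname(diag(p)), rep(0, cfg$nRois))
})

test_that("noise ROIs reach the entropy ceiling and planted irregularity orders entropy", {
  co <- cachedCohort("small1200", function()
    generateCohort(cohortConfig(nSubjects = 8, nRois = 20), seed = 31))
  ep <- entropyProfiles(co@timeseries)
  avg <- sessionAverage(ep)
  nm <- co@truth$noiseMask
  expect_true(any(nm))
  expect_true(all(abs(avg[, nm] - log(9)) < 0.05))
  # monotone entropy control: measured entropy decreases in planted phi
  phi <- co@truth$phi[, !nm]
  en <- avg[, !nm]
  expect_lt(cor(as.vector(phi), as.vector(en), method = "spearman"), -0.95)
})

test_that("network assignment by vertex overlap matches a counting oracle", {
  # fine region fully inside one coarse region
  expect_equal(unname(assignNetworksByOverlap(rep("f1", 10), rep("VIS", 10))),
               "VIS")
  # 60/40 split: majority wins
  expect_equal(unname(assignNetworksByOverlap(rep("f1", 10),
                                              rep(c("DMN", "VIS"), c(6, 4)))),
               "DMN")
  set.seed(8)
  fine <- sample(paste0("f", 1:12), 600, replace = TRUE)
  coarse <- sample(c("VIS", "SM", "DMN"), 600, replace = TRUE)
  map <- assignNetworksByOverlap(fine, coarse)
  for (f in unique(fine)) {
    counts <- table(coarse[fine == f])
    expect_equal(unname(map[f]), names(counts)[which.max(counts)])
  }
  expect_error(assignNetworksByOverlap(character(0), character(0)), "empty")
  expect_error(assignNetworksByOverlap("a", c("x", "y")), "equal length")
})

test_that("write/read round trip reproduces every array exactly", {
  co <- generateCohort(cohortConfig(nSubjects = 4, nRois = 10, nTimepoints = 40),
                       seed = 77)
  dir <- withr::local_tempdir()
  writeCohort(co, dir)
  back <- readCohort(dir)
  for (i in seq_along(co@timeseries@series))
    expect_identical(back@timeseries@series[[i]], co@timeseries@series[[i]])
  for (pp in names(co@structure))
    expect_equal(back@structure[[pp]], co@structure[[pp]])
  for (id in names(co@connectivity))
    expect_equal(unname(back@connectivity[[id]]), unname(co@connectivity[[id]]))
  expect_equal(back@scores$g, co@scores$g)
  expect_identical(back@scores$family_id, co@scores$family_id)
  expect_equal(unname(back@truth$phi), unname(co@truth$phi))
  expect_identical(back@truth$noiseMask, co@truth$noiseMask)
  # manifest carries the documented fields
  man <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  expect_true(all(c("subject_ids", "roi_ids", "session_names", "run_names",
                    "n_timepoints", "tr") %in% names(man)))
  # sidecar JSON names the subject, session and run
  side <- jsonlite::read_json(file.path(dir, "timeseries", "S0001_REST1_run1.json"))
  expect_equal(side$subject_id, "S0001")
  expect_equal(side$session, "REST1")
})

test_that("truncated on-disk files produce a parse error naming the file", {
  co <- generateCohort(cohortConfig(nSubjects = 3, nRois = 8, nTimepoints = 30),
                       seed = 78)
  dir <- withr::local_tempdir()
  writeCohort(co, dir)
  victim <- file.path(dir, "timeseries", "S0002_REST2_run1.tsv")
  lines <- readLines(victim)
  writeLines(lines[1:3], victim)
  expect_error(readCohort(dir), "S0002_REST2_run1")
})
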