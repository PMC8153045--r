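# Lazily built, cached cohorts shared between test files (building the large
# ones once keeps the suite fast; the cache lives for one test run).
.cohortCache <- new.env(parent = emptyenv())

cachedCohort <- function(name, maker) {
  if (is.null(.cohortCache[[name]])) assign(name, maker(), envir = .cohortCache)
  .cohortCache[[name]]
}

# Small default-structure cohort for unit tests.
tinyCohort <- function() {
  cachedCohort("tiny", function()
    generateCohort(cohortConfig(nSubjects = 12, nRois = 21, nTimepoints = 300),
                   seed = 42))
}

# N = 200, 100 ROIs, 5% noise ROIs: shared by the screening and reliability
# attenuation checks.
screeningCohort <- function() {
  cachedCohort("screening200", function()
    generateCohort(cohortConfig(nSubjects = 200), seed = 2024))
}

screeningProfiles <- function() {
  cachedCohort("screening200profiles", function()
    entropyProfiles(screeningCohort()@timeseries,
                    parcellation = screeningCohort()@parcellation))
}
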