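test_that("NCDF mapping follows the standardization and rounding conventions", {
  # sample-SD standardization makes D = 1 for this signal, so theta is the
  # standard normal CDF at -1, 0, 1
  x <- c(-1, 0, 1)
  expect_identical(ncdfMap(x), c(1L, 2L, 3L))
  theta <- pnorm(x / sd(x))
  expect_equal(theta, c(pnorm(-1), 0.5, pnorm(1)))
  expect_identical(ncdfMap(x), as.integer(oracleNcdf(x, 3)))

  set.seed(11)
  for (cc in 2:5) {
    y <- rnorm(500)
    expect_identical(ncdfMap(y, DispersionParams(nClasses = cc)),
                     as.integer(oracleNcdf(y, cc)))
  }
})

test_that("label mapping and entropy are invariant under positive affine transforms", {
  set.seed(21)
  p <- DispersionParams()
  for (i in 1:10) {
    x <- rnorm(400)
    a <- runif(1, 0.1, 10); b <- runif(1, -5, 5)
    expect_identical(ncdfMap(a * x + b, p), ncdfMap(x, p))
    expect_identical(dispersionEntropy(a * x + b, p), dispersionEntropy(x, p))
  }
})

test_that("degenerate and malformed signals raise informative errors", {
  expect_error(ncdfMap(c(4, 4, 4, 4)), "constant signal")
  expect_error(dispersionEntropy(c(4, 4, 4, 4)), "constant signal")
  expect_error(dispersionEntropy(c(1, NA, 3, 2)), "non-finite")
  expect_error(ncdfMap(c(1, Inf, 3)), "non-finite")
  expect_error(dispersionEntropy(c(1, 2), DispersionParams(m = 3)), "too short")
  expect_error(DispersionParams(nClasses = 1), "nClasses")
})

test_that("entropy matches the brute-force pattern-census oracle", {
  set.seed(31)
  for (cc in c(2, 3, 4)) {
    for (m in c(2, 3)) {
      for (tau in c(1, 2)) {
        p <- DispersionParams(nClasses = cc, m = m, tau = tau)
        for (i in 1:3) {
          x <- rnorm(300)
          expect_equal(dispersionEntropy(x, p),
                       oracleDispersionEntropy(x, cc, m, tau),
                       tolerance = 1e-13)
        }
      }
    }
  }
})

test_that("analytic values: equiprobable patterns reach log(c^m), alternating signal gives log 2", {
  # de Bruijn labelled signal: all 9 patterns equally often at c = 3, m = 2
  expect_equal(dispersionEntropy(equiprobableSignal(20)), log(9), tolerance = 1e-12)
  # strictly alternating two-level signal, c = 2: patterns (1,2) and (2,1)
  # each with probability 1/2
  x <- rep_len(c(0, 1), 61)
  expect_equal(dispersionEntropy(x, DispersionParams(nClasses = 2)), log(2),
               tolerance = 1e-12)
})

test_that("entropy respects its analytic bounds on random signals", {
  set.seed(41)
  for (i in 1:20) {
    p <- DispersionParams(nClasses = sample(2:4, 1), m = sample(2:3, 1),
                          tau = sample(1:2, 1))
    en <- dispersionEntropy(rnorm(200), p)
    expect_gte(en, 0)
    expect_lte(en, maxEntropy(p) + 1e-12)
  }
})

test_that("expected entropy decreases monotonically with the AR(1) coefficient", {
  set.seed(51)
  phis <- seq(0, 0.9, by = 0.1)
  meanEn <- vapply(phis, function(ph) {
    mean(vapply(1:20, function(i) {
      e <- rnorm(1200)
      dispersionEntropy(stats::filter(e, ph, method = "recursive"))
    }, numeric(1)))
  }, numeric(1))
  expect_lt(cor(phis, meanEn, method = "spearman"), -0.95)
  expect_true(all(diff(meanEn) < 0))
})

test_that("entropy profiles average the two runs of a session", {
  # two runs with different, known signals: the matrix entry must be the mean
  # of the two run entropies
  set.seed(61)
  sig <- array(rnorm(200 * 2 * 2 * 2), c(200, 2, 2, 2))
  ts <- makeTimeSeries(3, 2, 200,
                       gen = function(i, s, r, k) sig[, k, r, s] + i)
  ep <- entropyProfiles(ts)
  for (s in 1:2) {
    m <- profileMatrix(ep, s)
    for (k in 1:2) {
      manual <- mean(c(dispersionEntropy(sig[, k, 1, s]),
                       dispersionEntropy(sig[, k, 2, s])))
      # signals only differ by an additive subject offset: affine invariance
      # makes every subject's entry equal the manual run mean
      expect_equal(unname(m[, k]), rep(manual, 3))
    }
  }
  # session average is the element-wise mean of the session matrices
  expect_equal(sessionAverage(ep),
               (profileMatrix(ep, 1) + profileMatrix(ep, 2)) / 2)
})

test_that("profile assembly matches looping dispersionEntropy over runs", {
  co <- tinyCohort()
  ep <- entropyProfiles(co@timeseries)
  m1 <- profileMatrix(ep, 1)
  ts <- co@timeseries
  for (i in c(1, 7)) {
    for (k in c(2, 15)) {
      manual <- mean(vapply(1:2, function(r)
        dispersionEntropy(getRun(ts, i, 1, r)[, k]), numeric(1)))
      expect_equal(unname(m1[i, k]), manual, tolerance = 1e-14)
    }
  }
  expect_error(entropyProfiles(ts, sessions = "REST9"), "session")
})

test_that("profile TSV export carries every subject/ROI/session value", {
  co <- tinyCohort()
  ep <- entropyProfiles(co@timeseries, parcellation = co@parcellation)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeEntropyProfiles(ep, path)
  long <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  m1 <- profileMatrix(ep, "REST1")
  row <- long[long$subject_id == "S0003" & long$roi_id == "ROI010" &
                long$session == "REST1", ]
  expect_equal(row$entropy_nats, unname(m1["S0003", "ROI010"]))
  expect_equal(row$network,
               co@parcellation$network[co@parcellation$roi_id == "ROI010"])
  expect_equal(nrow(long), nrow(co@parcellation) * 12 * 2)
})

test_that("rank stability across parameter settings behaves as specified", {
  co <- tinyCohort()
  rs <- rankStability(co@timeseries,
                      list(DispersionParams(), DispersionParams()))
  expect_equal(unname(rs[1, 2]), 1)
  rs2 <- rankStability(co@timeseries,
                       list(DispersionParams(nClasses = 3),
                            DispersionParams(nClasses = 4),
                            DispersionParams(m = 3)))
  expect_true(all(rs2[upper.tri(rs2)] > 0.9))
  expect_error(rankStability(co@timeseries, list(DispersionParams())),
               "at least two")
  one <- makeTimeSeries(3, 1, 100)
  expect_error(rankStability(one, list(DispersionParams(), DispersionParams(nClasses = 4))),
               "undefined")
})
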