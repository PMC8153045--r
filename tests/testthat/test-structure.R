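test_that("symmetrization and thresholding follow the arithmetic contract", {
  p <- matrix(0, 3, 3)
  p[1, 2] <- 0.004; p[2, 1] <- 0.002          # mean 0.003: retained
  p[1, 3] <- 0.001; p[3, 1] <- 0.0005         # mean 0.00075: zeroed
  w <- symmetrizeThreshold(p)
  expect_equal(w[1, 2], 0.003)
  expect_equal(w[2, 1], 0.003)
  expect_equal(w[1, 3], 0)
  expect_equal(unname(diag(w)), rep(0, 3))
  expect_equal(w, t(w), ignore_attr = TRUE)
  # idempotence: reprocessing is a no-op
  expect_equal(unname(symmetrizeThreshold(w)), unname(w))
  expect_error(symmetrizeThreshold(matrix(0, 2, 3)), "square")
  expect_error(symmetrizeThreshold(matrix(2, 2, 2)), "\\[0, 1\\]")
})

test_that("retained link fraction matches a direct census", {
  set.seed(1)
  p <- matrix(runif(50 * 50, 0, 0.002), 50, 50)
  diag(p) <- 0
  w <- symmetrizeThreshold(p, threshold = 0.0018)
  sym <- (p + t(p)) / 2; diag(sym) <- 0
  off <- row(p) != col(p)
  expect_equal(sum(w[off] > 0), sum(sym[off] >= 0.0018))
})

test_that("node strength and degree match hand values and an adjacency census", {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- w[1, 3] <- w[3, 1] <- w[2, 3] <- w[3, 2] <- 0.1
  m <- nodeMetrics(w)
  expect_equal(m$strength, rep(0.2, 3))
  expect_equal(m$degree, rep(2L, 3))
  w2 <- rbind(cbind(w, 0), 0)                  # add an isolated node
  m2 <- nodeMetrics(w2)
  expect_equal(m2$strength[4], 0)
  expect_equal(m2$degree[4], 0L)
  set.seed(2)
  p <- matrix(runif(30 * 30, 0, 0.003), 30, 30); diag(p) <- 0
  wr <- symmetrizeThreshold(p)
  mr <- nodeMetrics(wr)
  for (i in c(1, 17, 30)) {
    expect_equal(mr$strength[i], sum(wr[i, ]))
    expect_equal(mr$degree[i], sum(wr[i, ] != 0))
  }
  # strength and degree correlate positively on homogeneous random graphs
  expect_gt(cor(mr$strength, mr$degree), 0)
})

test_that("blueprint correlations recover planted loadings and self-correlation", {
  set.seed(3)
  en <- rnorm(300)
  self <- blueprintCorrelations(en, cbind(same = en), nBoot = 50, seed = 1)
  expect_equal(self$r, 1)
  expect_equal(self$p, 0)
  # planted loadings: +0.6 on a thickness-like and -0.5 on a degree-like map
  thick <- 0.6 * en + sqrt(1 - 0.36) * rnorm(300)
  deg <- -0.5 * en + sqrt(1 - 0.25) * rnorm(300)
  indep <- rnorm(300)
  res <- blueprintCorrelations(en, cbind(thickness = thick, degree = deg,
                                         indep = indep),
                               nBoot = 200, seed = 2)
  expect_lt(abs(res$r[res$property == "thickness"] - 0.6), 0.1)
  expect_lt(abs(res$r[res$property == "degree"] + 0.5), 0.1)
  expect_true(all(res$significant[res$property != "indep"]))
  expect_true(res$ciLow[1] <= res$r[1] && res$r[1] <= res$ciHigh[1])
  expect_error(blueprintCorrelations(en[1:2], cbind(a = 1:2)), "three ROIs")
})

test_that("cross-individual regional correlations behave at the extremes", {
  set.seed(4)
  en <- matrix(rnorm(40 * 6), 40, 6, dimnames = list(NULL, paste0("R", 1:6)))
  res <- regionalStructureCorrelations(en, list(same = en))
  expect_equal(unname(res$r[, "same"]), rep(1, 6))
  # independent property: r spread approximately 1/sqrt(N - 1) around zero
  set.seed(5)
  en2 <- matrix(rnorm(200 * 50), 200, 50)
  indep <- matrix(rnorm(200 * 50), 200, 50)
  r2 <- regionalStructureCorrelations(en2, list(x = indep))$r
  expect_lt(abs(mean(r2)), 0.03)
  expect_lt(abs(sd(r2) - 1 / sqrt(199)), 0.02)
  # zero-variance property: NA with warning; network summary averages r
  bad <- en; bad[, 2] <- 3
  expect_warning(r3 <- regionalStructureCorrelations(en, list(x = bad),
                 networks = setNames(rep(c("A", "B"), each = 3), paste0("R", 1:6))),
                 "zero variance")
  expect_true(is.na(r3$r[2, "x"]))
  expect_equal(dim(r3$networkMean), c(2L, 1L))
})

test_that("noiseless affine structure-entropy coupling gives perfect prediction and identification", {
  set.seed(6)
  n <- 20; p <- 12
  struct <- matrix(rnorm(n * p), n, p,
                   dimnames = list(sprintf("S%02d", 1:n), paste0("R", 1:p)))
  slopes <- runif(p, 0.5, 2); icept <- rnorm(p)
  en <- sweep(sweep(struct, 2, slopes, `*`), 2, icept, `+`)
  res <- structureToEntropyPrediction(en, struct, family = seq_len(n),
                                      nPerm = 100, nBoot = 50, seed = 7)
  expect_equal(unname(res$similarity), rep(1, n), tolerance = 1e-6)
  expect_equal(res$accuracy, 1)
  expect_true(res$satisfied)
  expect_lt(res$permutationP, 0.05)
})

test_that("zero-variance regressors fall back to the training mean with a warning", {
  set.seed(7)
  n <- 12
  struct <- matrix(rnorm(n * 4), n, 4,
                   dimnames = list(sprintf("S%02d", 1:n), paste0("R", 1:4)))
  struct[, 2] <- 1
  en <- matrix(rnorm(n * 4), n, 4, dimnames = dimnames(struct))
  expect_warning(res <- structureToEntropyPrediction(en, struct,
                 family = seq_len(n), nPerm = 20, nBoot = 0, seed = 8),
                 "zero-variance regressor")
  # the constant-regressor ROI is predicted by the training mean in each fold
  expect_lt(diff(range(res$predicted[, 2])), diff(range(en[, 2])))
})
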