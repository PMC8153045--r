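test_that("identification on identical matrices with distinct rows is perfect", {
  set.seed(1)
  m <- matrix(rnorm(50), 10, 5, dimnames = list(sprintf("S%02d", 1:10), NULL))
  res <- identifyProfiles(m, m)
  expect_equal(res@accuracy, 1)
  expect_identical(res@predictedIds, res@trueIds)
})

test_that("hand-built three-subject example reproduces the correlation argmax", {
  db <- rbind(a = c(1, 2, 3, 4), b = c(4, 3, 2, 1), c = c(1, 3, 2, 4))
  tg <- rbind(a = c(1, 2, 3, 4), b = c(4, 3, 2, 1), c = c(2, 2.5, 2.5, 3))
  # independent oracle: full 3 x 3 correlation table + argmax per target row
  sim <- matrix(NA_real_, 3, 3)
  for (i in 1:3) for (j in 1:3) sim[i, j] <- cor(tg[i, ], db[j, ])
  # the row-mean target ties between database subjects a and c (r = 0.9487
  # both); the tie resolves to the lowest index with a warning
  expect_equal(sim[3, 1], sim[3, 3], tolerance = 1e-12)
  expect_warning(res <- identifyProfiles(tg, db), "tie")
  expect_equal(unname(res@similarity), sim, tolerance = 1e-12)
  oraclePred <- rownames(db)[apply(sim, 1, which.max)]
  expect_identical(res@predictedIds, oraclePred)
  expect_equal(res@accuracy, 2 / 3)
})

test_that("identification is invariant to common positive affine rescaling", {
  set.seed(2)
  tg <- matrix(rnorm(60), 10, 6)
  db <- tg + matrix(rnorm(60, sd = 0.3), 10, 6)
  r0 <- identifyProfiles(tg, db)
  r1 <- identifyProfiles(3.7 * tg + 2, 0.4 * db - 1)
  expect_identical(r1@predictedIds, r0@predictedIds)
  expect_equal(r1@accuracy, r0@accuracy)
})

test_that("profile mismatches and degenerate rows are rejected", {
  m <- matrix(rnorm(30), 5, 6, dimnames = list(paste0("S", 1:5), NULL))
  expect_error(identifyProfiles(m, m[, 1:5]), "mismatch")
  m2 <- m; rownames(m2) <- paste0("X", 1:5)
  expect_error(identifyProfiles(m, m2), "mismatch")
  m3 <- m; m3[2, ] <- 7
  expect_error(identifyProfiles(m3, m), "S2")
  expect_error(identifyProfiles(m[1, , drop = FALSE], m[1, , drop = FALSE]),
               "two subjects")
})

test_that("accuracy under full exchangeability concentrates near 1/N", {
  set.seed(3)
  n <- 100
  correct <- 0L
  nSeeds <- 3L
  for (s in seq_len(nSeeds)) {
    base <- rnorm(40)
    tg <- matrix(base, n, 40, byrow = TRUE) + matrix(rnorm(n * 40), n, 40)
    db <- matrix(base, n, 40, byrow = TRUE) + matrix(rnorm(n * 40), n, 40)
    res <- identifyProfiles(tg, db)
    correct <- correct + sum(res@predictedIds == res@trueIds)
  }
  band <- binomialBand(nSeeds * n, 1 / n)
  expect_gte(correct / (nSeeds * n), band[1])
  expect_lte(correct / (nSeeds * n), band[2])
})

test_that("permutation test: zero accuracy gives p = 1, N = 2 matches enumeration", {
  # two subjects engineered so each is identified as the other
  tg <- rbind(S1 = c(1, 2, 3, 5), S2 = c(5, 3, 2, 1))
  db <- rbind(S1 = c(5, 3, 2.5, 1), S2 = c(1, 2.5, 3, 5))
  fp <- fingerprintTest(db, tg, nPerm = 100, nBoot = 50, seed = 7)
  expect_equal(unname(fp@accuracy), c(0, 0))
  expect_equal(fp@permutationP, 1)

  # N = 2, perfect identification: only two permutations exist (identity and
  # swap); exact enumeration gives p = 1/2, and the seeded sampled null must
  # agree closely
  tg2 <- rbind(S1 = c(1, 2, 3, 4), S2 = c(4, 3, 1, 2))
  fp2 <- fingerprintTest(tg2, tg2, nPerm = 1000, nBoot = 0, seed = 8)
  expect_equal(unname(fp2@accuracy), c(1, 1))
  expect_true(all(fp2@nullAccuracies %in% c(0, 1)))
  expect_lt(abs(fp2@permutationP - 0.5), 0.05)
})

test_that("separable profiles give p = 0 and CI bounds bracket the accuracy", {
  set.seed(9)
  tg <- matrix(rnorm(50 * 20), 50, 20)
  db <- tg + matrix(rnorm(50 * 20, sd = 0.1), 50, 20)
  fp <- fingerprintTest(tg, db, nPerm = 250, nBoot = 200, seed = 10)
  expect_equal(unname(fp@accuracy), c(1, 1))
  expect_equal(fp@permutationP, 0)
  expect_true(all(fp@ci95[, 1] <= fp@accuracy & fp@accuracy <= fp@ci95[, 2]))
  expect_true(all(fp@satisfied))
})

test_that("differentiation power matches a direct evaluation of its formula", {
  set.seed(12)
  d1 <- matrix(rnorm(4 * 5), 4, 5)
  d2 <- matrix(rnorm(4 * 5), 4, 5)
  res <- differentiationPower(d1, d2)
  z1 <- t(apply(d1, 1, function(r) (r - mean(r)) / sd(r)))
  z2 <- t(apply(d2, 1, function(r) (r - mean(r)) / sd(r)))
  n <- 4
  for (k in 1:5) {
    P <- numeric(n)
    for (i in 1:n) {
      cnt <- 0L
      for (j in setdiff(1:n, i)) {
        if (z1[i, k] * z2[j, k] > z1[i, k] * z2[i, k]) cnt <- cnt + 1L
        if (z1[j, k] * z2[i, k] > z1[i, k] * z2[i, k]) cnt <- cnt + 1L
      }
      P[i] <- cnt / (2 * (n - 1))
    }
    expect_equal(unname(res$perSubjectP[, k]), P)
    expect_equal(unname(res$dp[k]), -log(max(mean(P), 1 / (2 * n * (n - 1)))))
  }
})

test_that("DP zero-probability guard and mean-vs-sum ranking equivalence hold", {
  # two subjects, three ROIs, first ROI engineered so both within-subject
  # products beat both cross products: P = 0 there, DP hits -log(eps)
  d1 <- rbind(S1 = c(3, 1, 2), S2 = c(-3, 2, 1))
  d2 <- rbind(S1 = c(3, 2, 1), S2 = c(-3, 1, 2))
  res <- differentiationPower(d1, d2)
  expect_equal(unname(res$perSubjectP[, 1]), c(0, 0))
  expect_equal(unname(res$dp[1]), -log(1 / (2 * 2 * 1)))  # log 4

  set.seed(13)
  a <- matrix(rnorm(20 * 8), 20, 8)
  b <- matrix(rnorm(20 * 8), 20, 8)
  r2 <- differentiationPower(a, b)
  sumForm <- -log(colSums(r2$perSubjectP))
  expect_identical(order(r2$dp), order(sumForm))
})

test_that("per-subject probabilities average to 1/2 for independent sessions", {
  set.seed(14)
  d1 <- matrix(rnorm(60 * 12), 60, 12)
  d2 <- d1[sample(60), ]               # subject-permuted copy: no pairing
  res <- differentiationPower(d1, d2)
  expect_lt(abs(mean(res$perSubjectP) - 0.5), 0.03)
})
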