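# Agreement statistics: ICC(A,1), Bland-Altman, rater simulation.

test_that("perfect agreement gives ICC 1 with CI upper bound 1", {
  x <- c(3, 7, 11, 2, 9, 14)
  r <- iccA1(cbind(x, x))
  expect_equal(r@icc, 1)
  expect_equal(r@ciHigh, 1)
  expect_error(iccA1(matrix(5, 4, 2)), "zero variance")
  expect_error(iccA1(matrix(rnorm(2), 1, 2)), "subjects")
})

test_that("absolute agreement penalizes systematic offsets", {
  set.seed(71)
  subj <- rnorm(25, 50, 10)
  iccAt <- function(delta) iccA1(cbind(subj, subj + delta))@icc
  expect_lt(iccAt(2), 1)
  expect_lt(iccAt(6), iccAt(2))
  expect_lt(iccAt(12), iccAt(6))
})

test_that("ICC(A,1) matches the independent ANOVA oracle to 1e-10", {
  set.seed(72)
  for (i in 1:100) {
    n <- sample(5:30, 1)
    k <- sample(2:5, 1)
    subj <- rnorm(n, 0, runif(1, 0.5, 3))
    tab <- sapply(seq_len(k), function(j) subj + rnorm(1, 0, 0.5) + rnorm(n, 0, runif(1, 0.2, 1)))
    expect_equal(iccA1(tab)@icc, iccOracleAov(tab), tolerance = 1e-10)
  }
})

test_that("ICC is invariant to row permutation and global shifts, not column shifts", {
  set.seed(73)
  subj <- rnorm(20, 0, 2)
  tab <- cbind(subj + rnorm(20, 0, 0.5), subj + rnorm(20, 0, 0.5), subj + rnorm(20, 0, 0.5))
  r0 <- iccA1(tab)@icc
  expect_equal(iccA1(tab[sample(20), ])@icc, r0)
  expect_equal(iccA1(tab + 57.3)@icc, r0)
  tabOff <- tab; tabOff[, 2] <- tabOff[, 2] + 3
  expect_lt(iccA1(tabOff)@icc, r0)
})

test_that("ICC estimator and CI recover the generating variance components", {
  # two-way model, sigma^2 subject/rater/error = 0.90/0.01/0.09: ICC = 0.90
  ss <- 0.90; sr <- 0.01; se <- 0.09
  trueIcc <- ss / (ss + sr + se)
  set.seed(74)
  est <- numeric(500); covered <- logical(500)
  for (i in 1:500) {
    subj <- rnorm(28, 0, sqrt(ss))
    tab <- simulateRaters(subj, rnorm(2, 0, sqrt(sr)), sqrt(se), seed = 7400 + i)
    r <- iccA1(tab)
    est[i] <- r@icc
    covered[i] <- r@ciLow <= trueIcc && r@ciHigh >= trueIcc
  }
  expect_lt(abs(mean(est) - trueIcc), 0.02)
  expect_gte(mean(covered), 0.92)
  expect_lte(mean(covered), 0.98)
})

test_that("Bland-Altman reproduces its definition and the printed examples", {
  x <- c(10, 12, 9, 14)
  r <- blandAltman(cbind(x, x))
  expect_equal(c(r@bias, r@sdDiff, r@loaLow, r@loaHigh), c(0, 0, 0, 0))
  pts <- attr(r, "points")
  expect_equal(pts$mean, x)

  # fibrosis comparison (LGE-Dixon vs conventional LGE): bias 1.43, SD 2.82
  loaFib <- loaFromSummary(1.43, 2.82)
  expect_equal(round(loaFib[["loaLow"]], 2), -4.10)
  expect_equal(round(loaFib[["loaHigh"]], 2), 6.96)
  # EAT comparison (LGE-Dixon vs PD-Dixon): bias -0.35, SD 3.03
  loaEat <- loaFromSummary(-0.35, 3.03)
  expect_equal(round(loaEat[["loaLow"]], 2), -6.29)

  expect_equal(unname(loaFromSummary(0, 1)), c(-1.96, 1.96))
  expect_error(loaFromSummary(0, -1), "non-negative")
  expect_error(blandAltman(cbind(1, 2)), "subjects")
})

test_that("limits of agreement always span 2 x 1.96 x SD", {
  set.seed(75)
  for (i in 1:25) {
    tab <- matrix(rnorm(2 * sample(3:40, 1), sd = runif(1, 0.1, 50)), ncol = 2)
    r <- blandAltman(tab)
    expect_equal(r@loaHigh - r@loaLow, 2 * 1.96 * r@sdDiff)
  }
})

test_that("rater simulation is seeded and matches its generating model", {
  tv <- c(10, 20, 30)
  t0 <- simulateRaters(tv, c(0, 1), 0, seed = 5)
  expect_equal(t0[, 1], tv)
  expect_equal(t0[, 2], tv + 1)
  expect_identical(
    simulateRaters(tv, c(0, 1), 0.5, seed = 5),
    simulateRaters(tv, c(0, 1), 0.5, seed = 5)
  )
  expect_error(simulateRaters(tv, c(0, 1), -0.5), "non-negative")

  # empirical ICC over replicates ~ closed-form variance-components value
  ss <- 4; sr <- 0.25; se <- 1
  trueIcc <- ss / (ss + sr + se)
  set.seed(76)
  est <- sapply(1:200, function(i) {
    subj <- rnorm(30, 0, sqrt(ss))
    iccA1(simulateRaters(subj, rnorm(2, 0, sqrt(sr)), sqrt(se), seed = 7600 + i))@icc
  })
  expect_lt(abs(mean(est) - trueIcc), 0.03)
})
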