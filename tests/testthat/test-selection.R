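test_that("EDF schedule satisfies its boundary conditions and closed form", {
  expect_equal(edfRatio(1, 50, 428), 1)
  expect_equal(edfRatio(50, 50, 428), 2 / 428, tolerance = 1e-12)
  expect_equal(edfRatio(1, 7, 100), 1)
  # closed form at an interior run
  k <- log(428 / 2) / 49
  expect_equal(edfRatio(25, 50, 428), exp(k) * exp(-k * 25),
               tolerance = 1e-12)
  expect_error(edfRatio(1, 10, 2), "p > 2")
})

test_that("CARS retained counts follow the capped EDF schedule", {
  set.seed(41)
  X <- matrix(rnorm(30 * 60), 30)
  y <- rnorm(30)
  cfg <- carsConfig(nRuns = 25, seed = 3)
  res <- carsSelect(X, y, cfg)
  expected <- pmax(2, ceiling(edfRatio(seq_len(25), 25, 60) * 60 - 1e-9))
  expect_equal(res@retainedCountByRun, as.integer(expected))
  expect_true(all(diff(res@retainedCountByRun) <= 0))
  expect_equal(res@retainedCountByRun[25], 2L)
  expect_equal(res@selectedIndices,
               as.integer(sort(res@subsets[[res@bestRun]])))
})

test_that("CARS is reproducible under a fixed seed", {
  set.seed(42)
  X <- matrix(rnorm(40 * 50), 40)
  y <- X[, 5] + rnorm(40, 0, 0.5)
  r1 <- carsSelect(X, y, carsConfig(nRuns = 15, seed = 9))
  r2 <- carsSelect(X, y, carsConfig(nRuns = 15, seed = 9))
  expect_identical(r1@selectedIndices, r2@selectedIndices)
  expect_identical(r1@rmsecvByRun, r2@rmsecvByRun)
})

test_that("CARS recovers planted informative variables", {
  for (s in 1:3) {
    set.seed(500 + s)
    X <- matrix(rnorm(60 * 100), 60)
    y <- 3 * X[, 10] - 2 * X[, 50] + rnorm(60, 0, 0.2)
    res <- carsSelect(X, y, carsConfig(seed = s))
    expect_true(all(c(10L, 50L) %in% res@selectedIndices))
  }
})

test_that("pure-noise predictors yield no spurious RMSECV collapse", {
  set.seed(43)
  X <- matrix(rnorm(40 * 60), 40)
  y <- rnorm(40)
  res <- carsSelect(X, y, carsConfig(nRuns = 20, seed = 1))
  # the winning subset cannot beat the full-variable model by more than
  # sampling noise; argmin is still well-defined
  expect_gte(min(res@rmsecvByRun), res@rmsecvByRun[1] - 2 * sd(y))
  expect_equal(res@bestRun, which.min(res@rmsecvByRun))
})

test_that("correlation selection matches the textbook formula", {
  set.seed(44)
  y <- rnorm(30)
  T <- cbind(exact = y, anti = -y + 5,
             noise = rnorm(30), weak = 0.1 * y + rnorm(30))
  rep <- correlationSelect(T, y, threshold = 0.3)
  expect_equal(as.numeric(rep@r["exact"]), 1, tolerance = 1e-12)
  expect_equal(as.numeric(rep@r["anti"]), -1, tolerance = 1e-12)
  expect_true(all(c("exact", "anti") %in% rep@selected))
  for (j in colnames(T))
    expect_equal(as.numeric(rep@r[j]), brute_pearson(T[, j], y),
                 tolerance = 1e-12)
  # constant columns get r = 0 and are never selected
  rep2 <- correlationSelect(cbind(T, flat = rep(2, 30)), y)
  expect_equal(as.numeric(rep2@r["flat"]), 0)
  expect_false("flat" %in% rep2@selected)
})

test_that("selection threshold is strict", {
  # a column engineered to have |r| exactly at the threshold is excluded
  y <- c(-1, 0, 1)
  x <- c(-1, 2, 1)
  Tm <- matrix(x, dimnames = list(NULL, "x"))
  r <- correlationSelect(Tm, y, threshold = 0)@r["x"]
  rep <- correlationSelect(Tm, y, threshold = abs(r))
  expect_false("x" %in% rep@selected)
})

test_that("low-level fusion concatenates blocks in order", {
  set.seed(45)
  X <- matrix(rnorm(8 * 20), 8, dimnames = list(NULL, paste0("wl", 1:20)))
  T <- matrix(rnorm(8 * 4), 8, dimnames = list(NULL, paste0("t", 1:4)))
  F <- fuseLow(X, T)
  expect_equal(dim(F), c(8, 24))
  expect_equal(F[, 7], X[, 7])
  expect_equal(colnames(F), c(colnames(X), colnames(T)))
  expect_identical(fuseLow(X, NULL), X)
  expect_error(fuseLow(X, T[1:5, ]), "mismatch")
})

test_that("mid-level fusion keeps exactly the selected variables", {
  set.seed(46)
  X <- matrix(rnorm(10 * 15), 10, dimnames = list(NULL, paste0("wl", 1:15)))
  T <- matrix(rnorm(10 * 4), 10, dimnames = list(NULL, paste0("t", 1:4)))
  M <- fuseMid(X, c(3L, 8L), T, c("t2", "t4"))
  expect_equal(dim(M), c(10, 4))
  expect_equal(colnames(M), c("wl3", "wl8", "t2", "t4"))
  expect_equal(M[, 1], X[, 3])
  # all-variable selection reproduces low-level fusion
  expect_equal(fuseMid(X, 1:15, T, colnames(T)), fuseLow(X, T))
  # minimal 1 + 1 selection preserves order
  expect_equal(colnames(fuseMid(X, 5L, T, "t1")), c("wl5", "t1"))
  expect_error(fuseMid(X, integer(0), T, character(0)), "empty")
})
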