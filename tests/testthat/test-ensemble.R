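simSmall <- function(seed = 21, n = 120, m = 60, q = 10, h2 = 0.8) {
  simulateDataset(simParams(n = n, m = m, nQtn = q, h2 = h2, seed = seed))
}

test_that("holdout/base-train partition is exact for every strategy", {
  d <- simSmall()
  tr <- 1:100
  for (st in c("random", "CA", "PP")) {
    parts <- splitHoldout(tr, blendConfig(H = 0.3, strategy = st, seed = 2),
                          G = d@G, y = d@y)
    expect_length(parts$holdoutIdx, 30L)
    expect_length(parts$baseTrainIdx, 70L)
    expect_length(intersect(parts$holdoutIdx, parts$baseTrainIdx), 0L)
    expect_setequal(c(parts$holdoutIdx, parts$baseTrainIdx), tr)
  }
  expect_error(splitHoldout(1:5, blendConfig(H = 0.3), G = d@G, y = d@y),
               "at least 10")
})

test_that("PP holdout represents both modes of a bimodal phenotype", {
  set.seed(22)
  G <- genotypeMatrix(matrix(sample(0:2, 100 * 10, TRUE), 100, 10))
  y <- c(rnorm(50, -5), rnorm(50, 5))
  parts <- splitHoldout(1:100, blendConfig(H = 0.3, strategy = "PP", K = 8,
                                           seed = 3), G = G, y = y)
  expect_true(any(y[parts$holdoutIdx] < 0))
  expect_true(any(y[parts$holdoutIdx] > 0))
})

test_that("elastic net reaches the least-squares limit on noiseless linear data", {
  set.seed(23)
  X <- matrix(rnorm(60 * 5), 60, 5)
  y <- drop(X %*% c(2, -1, 0.5, 0, 3)) + 1
  bundle <- fitBaseLearners(X, y, seed = 1)
  z <- makeMetaFeatures(bundle, X)
  expect_equal(dim(z), c(60L, 3L))
  expect_identical(colnames(z), c("svr", "tree", "enet"))
  expect_lt(max(abs(z[, "enet"] - y)), 1e-3)
})

test_that("a constant response degenerates all base learners to that constant", {
  set.seed(24)
  X <- matrix(rnorm(30 * 4), 30, 4)
  bundle <- fitBaseLearners(X, rep(7, 30), seed = 1)
  z <- makeMetaFeatures(bundle, matrix(rnorm(8 * 4), 8, 4))
  expect_true(all(z == 7))
})

test_that("base learners are deterministic under a fixed seed", {
  set.seed(25)
  X <- matrix(rnorm(40 * 6), 40, 6)
  y <- rnorm(40)
  z1 <- makeMetaFeatures(fitBaseLearners(X, y, seed = 9), X)
  z2 <- makeMetaFeatures(fitBaseLearners(X, y, seed = 9), X)
  expect_identical(z1, z2)
  expect_error(makeMetaFeatures(fitBaseLearners(X, y, seed = 9),
                                matrix(0, 4, 5)), "mismatch")
})

test_that("the meta-learner equals closed-form least squares on full-rank designs", {
  Z <- matrix(c(1.0, 0.2, 3.1,
                2.0, 1.1, 0.4,
                0.5, 2.2, 1.9,
                3.3, 0.7, 2.8,
                1.7, 1.5, 0.1,
                2.9, 2.4, 3.6), ncol = 3, byrow = TRUE)
  y <- c(2.1, 1.4, 3.3, 0.7, 2.2, 4.0)
  m <- fitMeta(Z, y)
  A <- cbind(1, Z)
  oracle <- drop(solve(crossprod(A), crossprod(A, y)))  # normal equations
  expect_equal(unname(metaCoefficients(m)), oracle, tolerance = 1e-8)
})

test_that("a perfect base learner yields zero holdout residuals", {
  set.seed(26)
  y <- rnorm(20)
  Z <- cbind(y, rnorm(20), rnorm(20))
  m <- fitMeta(Z, y)
  fitted <- m@intercept + drop(Z %*% m@coefficients)
  expect_equal(fitted, y, tolerance = 1e-8)
})

test_that("collinear meta features still give finite coefficients", {
  set.seed(27)
  a <- rnorm(12)
  Z <- cbind(a, a, a)  # fully collinear
  m <- fitMeta(Z, a + rnorm(12, sd = 0.1))
  expect_true(all(is.finite(metaCoefficients(m))))
})

test_that("blending achieves high accuracy on strongly heritable data", {
  d <- simulateDataset(simParams(n = 600, m = 500, nQtn = 50, h2 = 0.8,
                                 seed = 28))
  sp <- outerSplit(600, 0.2, seed = 1)
  ens <- fitBlending(d@G, d@y, trainIdx = trainIdx(sp),
                     config = blendConfig(H = 0.3, strategy = "random", seed = 2))
  pred <- predict(ens, d@G)[testIdx(sp)]
  acc <- pearsonAccuracy(pred, phenoValues(d@y)[testIdx(sp)])
  expect_gte(as.numeric(acc), 0.6)
})

test_that("all three strategies produce valid, deterministic ensembles", {
  d <- simSmall(seed = 29, n = 150, m = 80)
  sp <- outerSplit(150, 0.2, seed = 5)
  for (st in c("random", "CA", "PP")) {
    e1 <- fitBlending(d@G, d@y, trainIdx = trainIdx(sp),
                      config = blendConfig(H = 0.25, strategy = st, seed = 6))
    expect_length(holdoutIdx(e1), round(0.25 * 120))
    expect_setequal(c(holdoutIdx(e1), baseTrainIdx(e1)), trainIdx(sp))
    e2 <- fitBlending(d@G, d@y, trainIdx = trainIdx(sp),
                      config = blendConfig(H = 0.25, strategy = st, seed = 6))
    expect_identical(predict(e1, d@G), predict(e2, d@G))
  }
})

test_that("prediction honours the meta model and is permutation-equivariant", {
  d <- simSmall(seed = 30)
  ens <- fitBlending(d@G, d@y, config = blendConfig(H = 0.3, seed = 7))

  # constant meta model: all predictions equal its intercept
  cm <- ens
  cm@meta <- new("MetaModel", intercept = 4.2, coefficients = c(0, 0, 0))
  expect_equal(unname(predict(cm, d@G)), rep(4.2, 120))

  # row permutation of the input permutes the output
  X <- dosages(d@G)
  perm <- sample(nrow(X))
  expect_equal(unname(predict(ens, X[perm, ])), unname(predict(ens, X))[perm])

  # marker mismatch is a named shape error
  Gbad <- genotypeMatrix(dosages(d@G)[, 1:30])
  expect_error(predict(ens, Gbad), "marker")
})
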