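test_that("CA stratification recovers well-separated genotype groups", {
  d <- rbind(matrix(0, 25, 10), matrix(2, 25, 10))
  # a dash of distinct rows so k-means has more than two unique points
  d[c(1, 26), 1] <- 1
  G <- genotypeMatrix(d)
  a <- stratifyCA(G, stratifyConfig("CA", K = 2, seed = 1))
  lab <- strataLabels(a)
  expect_true(all(lab[1:25] == lab[1]))
  expect_true(all(lab[26:50] == lab[26]))
  expect_false(lab[1] == lab[26])
  expect_equal(sum(strataCounts(a)), 50L)
  expect_equal(strataWeights(a), c(0.5, 0.5))
})

test_that("K = 1 puts everyone in a single full-weight stratum", {
  G <- makeToyGenotypes(n = 10)
  a <- stratifyCA(G, stratifyConfig("CA", K = 1, seed = 1))
  expect_identical(strataLabels(a), rep(1L, 10))
  expect_equal(strataWeights(a), 1.0)
})

test_that("K = 8 CA strata on simulated individuals are complete and occupied", {
  d <- simulateDataset(simParams(n = 500, m = 50, nQtn = 10, h2 = 0.5, seed = 2))
  a <- stratifyCA(d@G, stratifyConfig("CA", K = 8, seed = 3))
  K <- length(strataWeights(a))
  expect_true(K >= 1 && K <= 8)
  expect_equal(sum(strataCounts(a)), 500L)
  expect_true(all(strataCounts(a) > 0))
  # every individual gets exactly one label in 1..K
  expect_true(all(strataLabels(a) %in% seq_len(K)))
  expect_length(strataLabels(a), 500L)
  # proportional allocation: weights mirror cluster sizes
  expect_equal(strataWeights(a), strataCounts(a) / 500)
  expect_error(stratifyCA(makeToyGenotypes(n = 5), stratifyConfig("CA", K = 9)),
               "exceeds")
})

test_that("PP equal-width intervals split evenly spaced phenotypes evenly", {
  a <- stratifyPP(0:9, stratifyConfig("PP", K = 2, seed = 1))
  expect_equal(strataCounts(a), c(5L, 5L))
  expect_identical(strataLabels(a), rep(1:2, each = 5L))
})

test_that("PP interval probabilities are normalized and match a density oracle", {
  set.seed(11)
  for (rep in 1:5) {
    y <- rgamma(300, shape = 2) + rnorm(300, sd = 0.2)
    a <- stratifyPP(y, stratifyConfig("PP", K = 5, seed = 1))
    expect_equal(sum(strataWeights(a)), 1, tolerance = 1e-6)
    expect_true(all(strataWeights(a) >= 0))
  }

  # oracle: integrate stats::density() (same Gaussian kernel, same bandwidth)
  # over each interval by fine trapezoidal sums
  set.seed(12)
  y <- rnorm(400)
  K <- 4L
  a <- stratifyPP(y, stratifyConfig("PP", K = K, seed = 1))
  breaks <- seq(min(y), max(y), length.out = K + 1)
  dens <- density(y, bw = bw.nrd0(y), from = min(y), to = max(y), n = 4096)
  mass <- vapply(seq_len(K), function(k) {
    inside <- dens$x >= breaks[k] & dens$x <= breaks[k + 1]
    sum(diff(dens$x[inside]) *
          (head(dens$y[inside], -1) + tail(dens$y[inside], -1)) / 2)
  }, numeric(1))
  expect_equal(strataWeights(a), mass / sum(mass), tolerance = 0.01)
})

test_that("PP on a normal phenotype concentrates mass in the central intervals", {
  set.seed(13)
  y <- rnorm(2000)
  a <- stratifyPP(y, stratifyConfig("PP", K = 8, seed = 1))
  w <- strataWeights(a)
  expect_length(w, 8L)
  expect_true(min(w[4:5]) >= max(w[-(4:5)]))
  expect_error(stratifyPP(rep(1, 10), stratifyConfig("PP")), "constant")
})

test_that("empirical-count PP weights equal interval frequencies", {
  set.seed(14)
  y <- rexp(200)
  a <- stratifyPP(y, stratifyConfig("PP", K = 6, seed = 1, ppEmpirical = TRUE))
  expect_equal(strataWeights(a), strataCounts(a) / 200)
})

test_that("stratum quotas follow largest-remainder apportionment", {
  # proportional two-stratum case
  expect_equal(stratumQuotas(c(0.6, 0.4), c(6L, 4L), 5L), c(3L, 2L))
  # cap-and-redistribute: target 4.5 capped at occupancy 2, overflow to the rest
  expect_equal(stratumQuotas(c(0.9, 0.1), c(2L, 8L), 5L), c(2L, 3L))
  # remainder distribution, oracle-checked
  expect_equal(stratumQuotas(c(0.5, 0.27, 0.23), c(99L, 99L, 99L), 7L),
               oracleLargestRemainder(c(0.5, 0.27, 0.23), 7))

  set.seed(15)
  for (rep in 1:50) {
    K <- sample(2:6, 1)
    w <- runif(K); w <- w / sum(w)
    occ <- sample(3:20, K, replace = TRUE)
    total <- sample(seq_len(sum(occ)), 1)
    q <- stratumQuotas(w, occ, total)
    expect_identical(sum(q), total)           # exact total, always
    expect_true(all(q <= occ))                # never overdraws a stratum
    expect_true(all(q >= 0L))
    # without binding caps it is plain largest-remainder
    if (all(total * w < occ - 1))
      expect_identical(q, oracleLargestRemainder(w, total))
  }
  expect_error(stratumQuotas(c(0.5, 0.5), c(2L, 2L), 5L), "requested")
})

test_that("stratified samples hit round(H * n) exactly for arbitrary strata", {
  set.seed(16)
  for (rep in 1:20) {
    n <- sample(20:80, 1)
    K <- sample(1:5, 1)
    labels <- sample(seq_len(K), n, replace = TRUE)
    labels[seq_len(K)] <- seq_len(K)  # guarantee occupancy
    occ <- tabulate(labels, K)
    w <- runif(K); w <- w / sum(w)
    a <- new("StrataAssignment", labels = as.integer(labels), weights = w,
             occupied = occ, strategy = "CA")
    H <- runif(1, 0.1, 0.6)
    hold <- stratifiedSample(a, H, seed = rep)
    expect_length(hold, round(H * n))
    expect_false(any(duplicated(hold)))
    expect_true(all(hold %in% seq_len(n)))
  }
})

test_that("sampling is deterministic under a fixed seed", {
  d <- simulateDataset(simParams(n = 60, m = 30, nQtn = 5, h2 = 0.5, seed = 17))
  a <- stratifyPP(phenoValues(d@y), stratifyConfig("PP", K = 4, seed = 1))
  expect_identical(stratifiedSample(a, 0.3, seed = 5),
                   stratifiedSample(a, 0.3, seed = 5))
  expect_identical(randomSample(20, 0.25, seed = 5), randomSample(20, 0.25, seed = 5))
  expect_length(randomSample(20, 0.25, seed = 5), 5L)
})

test_that("single-stratum stratified sampling matches simple random sampling in distribution", {
  n <- 8L; H <- 0.5
  a <- new("StrataAssignment", labels = rep(1L, n), weights = 1,
           occupied = n, strategy = "CA")
  nSeeds <- 6000L
  fStrat <- table(vapply(seq_len(nSeeds),
                         function(s) subsetKey(stratifiedSample(a, H, seed = s)),
                         character(1)))
  fRand <- table(vapply(seq_len(nSeeds),
                        function(s) subsetKey(randomSample(n, H, seed = 20000 + s)),
                        character(1)))
  expect_length(fStrat, choose(8, 4))  # all 70 subsets reachable
  expect_length(fRand, choose(8, 4))
  # both uniform over the 70 subsets
  expect_gt(chisq.test(as.vector(fStrat))$p.value, 1e-4)
  expect_gt(chisq.test(as.vector(fRand))$p.value, 1e-4)
  # and mutually consistent
  keys <- names(fStrat)
  tab <- rbind(as.vector(fStrat[keys]), as.vector(fRand[keys]))
  expect_gt(suppressWarnings(chisq.test(tab))$p.value, 1e-4)
})
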