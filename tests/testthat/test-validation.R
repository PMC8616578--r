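# Gap statistic, silhouette, subsampled ARI, Mahalanobis separation, PAIRS,
# covariance-regime experiment.

test_that("the gap selection rule takes the largest significant jump", {
  # crafted curves: jump at 3, none afterwards
  gap <- c(0, 0.1, 0.9, 0.95, 0.97)
  se <- rep(0.05, 5)
  expect_equal(lofcEncode:::selectGapK(gap, se), 3L)
  # no significant jump anywhere falls back to 1
  expect_equal(lofcEncode:::selectGapK(c(0, 0.01, 0.02), rep(0.05, 3)), 1L)
})

test_that("the gap statistic finds no structure in a single Gaussian cloud", {
  picks <- vapply(1:10, function(seed) {
    x <- withr::with_seed(seed, matrix(rnorm(150 * 5), 150, 5))
    suppressWarnings(gapStatistic(x, Kmax = 6, nRef = 50, seed = seed))$selectedK
  }, integer(1))
  expect_gte(mean(picks == 1), 0.9)
})

test_that("the gap statistic recovers three well-separated clusters", {
  picks <- vapply(1:10, function(seed) {
    b <- blobs(K = 3, n = 50, d = 5, sep = 10, seed = seed)
    suppressWarnings(gapStatistic(b$x, Kmax = 6, nRef = 50, seed = seed))$selectedK
  }, integer(1))
  expect_gte(mean(picks == 3), 0.9)
})

test_that("silhouette matches a brute-force enumeration exactly", {
  # four points on a line, labelled by pair: hand-enumerable a(i), b(i)
  x <- matrix(c(0, 1, 10, 11), 4, 1)
  lab <- c(1, 1, 2, 2)
  expect_equal(silhouetteScore(x, lab), bruteSilhouette(x, lab),
               tolerance = 1e-12)
  byHand <- mean(c(1 - 1 / 10.5, 1 - 1 / 9.5, 1 - 1 / 9.5, 1 - 1 / 10.5))
  expect_equal(silhouetteScore(x, lab), byHand, tolerance = 1e-12)
  # random instances, N <= 50
  for (seed in 1:5) {
    b <- blobs(K = 3, n = 12, d = 4, sep = 3, seed = seed)
    expect_equal(silhouetteScore(b$x, b$labels),
                 bruteSilhouette(b$x, b$labels), tolerance = 1e-12)
  }
  # two tight, distant clusters approach the upper bound
  b <- blobs(K = 2, n = 20, d = 3, sep = 1000, seed = 1)
  expect_gt(silhouetteScore(b$x, b$labels), 0.99)
  expect_error(silhouetteScore(b$x, rep(1, 40)), "two clusters")
})

test_that("random labels on one cloud give silhouette near zero", {
  vals <- vapply(1:6, function(seed) withr::with_seed(seed, {
    x <- matrix(rnorm(200 * 4), 200, 4)
    silhouetteScore(x, sample(1:2, 200, replace = TRUE))
  }), numeric(1))
  expect_lt(max(abs(vals)), 0.05)
})

test_that("subsampled ARI is 1 for separable data and bounded by 1", {
  b <- blobs(K = 3, n = 30, d = 4, sep = 30, seed = 6)
  a <- ariSubsample(b$x, 3, nRep = 10, seed = 2)
  expect_equal(a, rep(1, 10))
  expect_error(ariSubsample(b$x, 1, nRep = 2), "at least 2")
  expect_error(ariSubsample(b$x, 3, frac = 1.4), "frac")
  # chance-corrected null: shuffled labels agree at ARI ~ 0
  lab <- rep(1:5, 40)
  shuf <- withr::with_seed(7, sample(lab))
  expect_lt(abs(ari(lab, shuf)), 0.05)
  expect_equal(ari(lab, lab), 1)
})

test_that("Mahalanobis separation matches the chi distribution for a Gaussian", {
  d <- 5
  x <- withr::with_seed(8, matrix(rnorm(2000 * d), 2000, d))
  own <- mahalanobisSeparation(x, rep(1, 2000))[1, 1]
  chiMean <- sqrt(2) * gamma((d + 1) / 2) / gamma(d / 2)
  expect_lt(abs(own - chiMean) / chiMean, 0.05)
})

test_that("Mahalanobis distances are zero at the target mean and Euclidean under identity", {
  # cluster B engineered to have exactly identity sample covariance, zero mean
  d <- 3
  base <- withr::with_seed(9, matrix(rnorm(40 * d), 40, d))
  base <- sweep(base, 2, colMeans(base))
  W <- chol(stats::cov(base))
  B <- base %*% solve(W)                  # cov(B) = I exactly
  A <- matrix(c(0, 0, 0, 3, 4, 0), 2, d, byrow = TRUE)
  x <- rbind(A, B)
  lab <- c(1, 1, rep(2, 40))
  D <- suppressWarnings(mahalanobisSeparation(x, lab))
  # distances from A's points to B: point at mu_B -> 0, other -> its norm
  dists <- sqrt(rowSums(A^2))
  expect_equal(D[1, 2], mean(dists), tolerance = 1e-8)
})

test_that("PAIRS is calibrated on its own reference distribution", {
  res <- vapply(1:60, function(seed) {
    x <- withr::with_seed(5000 + seed, matrix(rnorm(100 * 6), 100, 6))
    p <- pairsStatistic(x, kNeighbors = 3, nRef = 100, seed = seed)
    c(p$pairs, p$p < 0.05)
  }, numeric(2))
  # two-sided rejection at the nominal few percent, statistic centred on 0
  expect_lte(mean(res[2, ]), 0.12)
  expect_lt(abs(mean(res[1, ])), 0.02)
})

test_that("PAIRS detects data concentrated on a few rays", {
  x <- withr::with_seed(10, {
    dirs <- matrix(rnorm(5 * 6), 5, 6)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    ray <- sample(1:5, 300, replace = TRUE)
    dirs[ray, ] * abs(rnorm(300, 3, 0.5)) + matrix(rnorm(300 * 6, sd = 0.05), 300, 6)
  })
  p <- pairsStatistic(x, kNeighbors = 3, nRef = 60, seed = 1)
  expect_gt(p$pairs, 0)
  expect_lt(p$p, 0.05)
  expect_lte(p$pairs, 1)
  expect_error(lofcEncode:::meanNeighborAngles(x, 300), "smaller")
})

test_that("high-dimensional references need only the nearest neighbour", {
  expect_equal(selectPairsK(300, 200, seed = 1, nDraws = 5), 1L)
})

test_that("the regime experiment collapses to one cluster when clusters coincide", {
  res <- suppressWarnings(regimeExperiment(
    totalCov = smoothCov(40), withinCov = smoothCov(40, variance = 0.1),
    scales = 1e-6, nRep = 3, nRef = 50, seed = 3, replicates = 10))
  expect_true(all(res$K[res$method == "gap"] == 1))
  expect_error(regimeExperiment(totalCov = -diag(10), scales = 1,
                                nRep = 1), "positive semidefinite")
})
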