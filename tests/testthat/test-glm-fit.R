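# Penalised Poisson GLM: fitting, convexity, recovery, CV partitions,
# held-out R2, model comparison.

test_that("with an all-zero design the MLE recovers the background log rate", {
  s <- generateSession(taskConfig(nTrials = 100), seed = 6)  # 16000 bins
  sp <- simulateSpikes(s, constantNeuron(5), seed = 6)
  d <- buildDesignMatrix(s)
  d@X[] <- 0
  f <- fitGLM(sp, d, xi = 0.1)
  expect_true(f@converged)
  expect_lt(abs(f@theta0 - log(0.25)), 0.05)
  expect_equal(unname(f@theta), rep(0, 135))
})

test_that("the ridge limit shrinks kernels to zero but not the background", {
  sp <- fxSpikes()[[3]]
  d <- fxDesign()
  f <- fitGLM(sp, d, xi = 1e8)
  expect_lt(max(abs(f@theta)), 1e-3)
  expect_lt(abs(f@theta0 - log(mean(spikeCounts(sp)))), 0.05)
  expect_error(fitGLM(sp, d, xi = -1), "non-negative")
})

test_that("the objective is convex: random restarts agree on the optimum", {
  s <- generateSession(taskConfig(nTrials = 60), seed = 14)
  nr <- makeArchetypes(taskConfig(nTrials = 60, seed = 14), seed = 14)
  sp <- simulateSpikes(s, nr[[5]], seed = 14)
  d <- buildDesignMatrix(s)
  ref <- fitGLM(sp, d, xi = 1)
  for (i in 1:9) {
    init <- withr::with_seed(i, rnorm(ncol(d@X) + 1, sd = 0.05))
    f <- fitGLM(sp, d, xi = 1, init = init)
    expect_lt(max(abs(f@theta - ref@theta)), 1e-4)
  }
})

test_that("kernel reconstruction is linear in the weights", {
  f <- fxFit3()
  f2 <- f
  f2@theta <- 2 * f@theta
  expect_equal(kernels(f2), 2 * kernels(f))
})

test_that("planted kernels are recovered from simulated spikes", {
  # single-seed version of the recovery property (full sweep in the
  # acceptance suite): 400 trials, mid-grid penalty
  seed <- 3
  cfg <- taskConfig(nTrials = 400, seed = seed)
  s <- generateSession(cfg)
  nr <- makeArchetypes(cfg, seed = seed)
  sp <- simulateSpikes(s, nr[[3]], seed = seed)
  d <- buildDesignMatrix(s)
  f <- fitGLM(sp, d, xi = 3)
  expect_gte(kernelRecovery(f, nr[[3]]), 0.8)
  # the fitted model reproduces the held-out PSTH (trial-averaged)
  holdout <- simulateSpikes(s, nr[[3]], seed = seed + 1000)
  nb <- d@nBinsPerTrial
  predPSTH <- colMeans(matrix(predictRate(f, d), ncol = nb, byrow = TRUE))
  obsPSTH <- colMeans(smoothRows(spikeCounts(holdout)))
  r2 <- 1 - sum((obsPSTH - predPSTH)^2) / sum((obsPSTH - mean(obsPSTH))^2)
  expect_gt(r2, 0.5)
})

test_that("trial partitions are balanced, stratified, and deterministic", {
  s <- fxSession()
  s2 <- s
  # force an exactly balanced contingency table
  n <- nTrials(s)
  tr <- trialTable(s)
  tr$outcome <- rep(c("win", "loss"), length.out = n)
  tr$prevOutcome <- c("none", tr$outcome[-n])
  tr$choice <- rep(c("left", "left", "right", "right"), length.out = n)
  s2@trials <- tr
  sch <- partitionTrials(s2, seed = 8)
  expect_equal(sort(unique(sch$labels)), 1:5)
  wins <- sch$balanceReport[, "win"]
  expect_lte(diff(range(wins)), 1)
  expect_gt(sch$chisqP, 0.9)
  sch2 <- partitionTrials(s2, seed = 8)
  expect_identical(sch$labels, sch2$labels)
  expect_false(identical(sch$labels, partitionTrials(s2, seed = 9)$labels))
})

test_that("held-out R2 has its fixed points and rewards the true rates", {
  sp <- fxSpikes()[[3]]
  d <- fxDesign()
  cnt <- spikeCounts(sp)
  test <- 1:80
  sm <- as.numeric(t(smoothRows(cnt[test, , drop = FALSE])))
  # predicting the mean of the held-out data gives exactly 0
  expect_equal(r2Heldout(rep(mean(sm), length(sm)), sp, d, trials = test), 0)
  # perfect prediction gives exactly 1
  expect_equal(r2Heldout(sm, sp, d, trials = test), 1)
  # the generative rates score positive and improve with more data
  tru <- sp@truth
  M <- 9
  theta <- numeric(ncol(d@X))
  for (v in names(tru@weights)) {
    i <- match(v, d@variables)
    theta[((i - 1) * M + 1):(i * M)] <- tru@weights[[v]]
  }
  lam <- exp(as.numeric(d@X %*% theta) + tru@background)
  lamMat <- matrix(lam, nrow = nrow(cnt), byrow = TRUE)
  r2small <- r2Heldout(as.numeric(t(lamMat[1:40, ])), sp, d, trials = 1:40)
  r2big <- r2Heldout(as.numeric(t(lamMat)), sp, d,
                     trials = seq_len(nrow(cnt)))
  expect_gt(r2small, 0)
  expect_gt(r2big, r2small - 0.05)
  # degenerate held-out data is refused
  zero <- matrix(0L, 4, ncol(cnt))
  expect_error(r2Heldout(rep(0, 4 * ncol(cnt)), zero, d, trials = 1:4),
               "zero-variance")
})

test_that("variant comparison is a paired two-sided signed-rank test", {
  base <- rnorm(20, 10)
  tab <- cbind(base = base, same = base, worse = base + 1)
  res <- compareVariants(tab, reference = "base")
  same <- res[res$variantB == "same", ]
  expect_equal(same$p, 1)
  expect_equal(same$medianDiff, 0)
  worse <- res[res$variantB == "worse", ]
  expect_lt(worse$p, 0.01)
  expect_equal(worse$medianDiff, 1)
  # swapping the pair flips the sign of the median difference, same p
  resSwap <- compareVariants(cbind(worse = base + 1, base = base))
  expect_equal(resSwap$medianDiff, -1)
  expect_equal(resSwap$p, worse$p)
  expect_error(compareVariants(tab[1:5, ]), "6")
})
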