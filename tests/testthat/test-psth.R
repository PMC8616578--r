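# PSTHs and the two feature spaces.

test_that("the trial-start PSTH grid has 121 bins and a flat unit is flat", {
  s <- generateSession(taskConfig(nTrials = 200), seed = 17)
  sp <- simulateSpikes(s, constantNeuron(10), seed = 17)
  p <- computePSTH(sp, s)
  expect_length(p, 121)
  expect_false(any(is.na(p)))
  # every smoothed bin within 3 SE of 10 Hz (smoothing leaves the mean)
  seBin <- sqrt(10 / 0.05 / 200 / 5)      # Poisson rate SE after 5-bin boxcar
  expect_lt(max(abs(p - mean(p))), 4 * seBin)
  expect_lt(abs(mean(p) - 10), 3 * sqrt(10 / 0.05 / 200 / 121))
})

test_that("the boxcar spreads a single spike into a 250 ms bump", {
  s <- generateSession(taskConfig(nTrials = 1), seed = 1)
  st <- new("SpikeTrains", unitId = "one", spikeTimes = list(0.5),
            counts = matrix(0L, 1, 160), binCenters = seq(-1.975, 5.975, 0.05),
            window = c(-2, 6), coverage = c(-2.05, 8.05), truth = NULL)
  p <- computePSTH(st, s, smoothBins = 5L)
  bump <- which(p > 0)
  expect_length(bump, 5)
  expect_equal(names(p)[bump[3]], "0.5")
  expect_equal(unname(p[bump]), rep(1 / 0.05 / 5, 5))  # mass 1 spread over 5 bins
  expect_error(computePSTH(st, s, conditionFilter = FALSE), "empty condition")
})

test_that("z-scored PSTH rows and their PCA reconstruct the data", {
  fs <- fxPsthFS()
  Z <- fs@raw
  expect_lt(max(abs(rowMeans(Z))), 1e-10)
  expect_lt(max(abs(apply(Z, 1, sd) - 1)), 1e-10)
  # retention rule: k is minimal with cumulative variance above 0.95
  cv <- cumsum(fs@varExplained)
  expect_gt(cv[fs@k], 0.95)
  if (fs@k > 1) expect_lte(cv[fs@k - 1], 0.95)
  # full-rank PCA reproduces Z
  pop <- fxClusterPop()
  full <- buildPsthFeatureSpace(psthMatrix(pop$spikes, pop$session),
                                varThreshold = 1 - 1e-12)
  rec <- featureScores(full) %*% t(full@loadings)
  rec <- sweep(rec, 2, -full@center)
  expect_lt(max(abs(rec - full@raw)), 1e-8)
})

test_that("a rank-one population needs a single component", {
  profile <- sin(seq(0, 3 * pi, length.out = 121))
  psths <- rbind(10 + 2 * outer(rep(1, 6), profile),
                 10 - 3 * outer(rep(1, 6), profile))
  fs <- buildPsthFeatureSpace(psths)
  expect_equal(fs@k, 1L)
  # constant rows are flagged and dropped
  psths2 <- rbind(psths, matrix(7, 1, 121))
  expect_warning(fs2 <- buildPsthFeatureSpace(psths2), "constant")
  expect_equal(nrow(featureScores(fs2)), 12)
})

test_that("the conditional feature space has the 19 defined features", {
  pop <- fxClusterPop()
  fs <- fixture("condFS", function()
    buildConditionalFeatureSpace(pop$spikes, pop$session))
  expect_length(fs@featureNames, 19)
  expect_equal(ncol(fs@raw), 19L)
  expect_identical(fs@source, "conditional")
  # a strong win response shows up as win > loss and rich > poor volumes
  rewardUnits <- grep("rewardLocked", rownames(fs@raw))
  expect_true(all(fs@raw[rewardUnits, "win"] > fs@raw[rewardUnits, "loss"]))
})

test_that("a condition-blind unit yields identical features", {
  s <- generateSession(taskConfig(nTrials = 60), seed = 23)
  # identical deterministic spike pattern on every trial: constant 20 Hz
  times <- seq(-1.9, 7.9, by = 0.05)
  st <- new("SpikeTrains", unitId = "metronome",
            spikeTimes = replicate(60, times, simplify = FALSE),
            counts = matrix(1L, 60, 160),
            binCenters = seq(-1.975, 5.975, 0.05), window = c(-2, 6),
            coverage = c(-2.05, 8.05), truth = NULL)
  f <- lofcEncode:::conditionalFeatures(st, s)
  expect_lt(diff(range(f, na.rm = TRUE)), 1e-9)
})

test_that("empty condition cells are imputed at the marginal mean and logged", {
  # a single offered volume leaves expected-value bins empty
  s <- generateSession(taskConfig(nTrials = 80, volumes = 48,
                                  clickRateMap = c("48" = 20)), seed = 29)
  sp1 <- simulateSpikes(s, constantNeuron(8), seed = 29)
  sp2 <- simulateSpikes(s, constantNeuron(6), seed = 30)
  expect_message(fs <- buildConditionalFeatureSpace(list(u1 = sp1, u2 = sp2), s),
                 "imputing")
  expect_false(any(is.na(fs@raw)))
})
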