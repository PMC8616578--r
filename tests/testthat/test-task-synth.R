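# Synthetic session generator and ground-truth Poisson units.

test_that("generated trials respect the event-time ordering and EV identities", {
  s <- fxSession()
  tr <- trialTable(s)
  expect_true(all(tr$tGo > 0 & tr$tGo < tr$tExitCenter &
                  tr$tExitCenter < tr$tChoice))
  expect_equal(tr$EVLeft, tr$pLeft * tr$VLeft)
  expect_equal(tr$EVRight, tr$pRight * tr$VRight)
  expect_true(all(tr$VRewarded %in% c(0, 6, 12, 24, 48)))
  expect_true(all(tr$VRewarded[tr$outcome != "win"] == 0))
  expect_equal(tr$sessionProgress, (tr$index) / (nTrials(s) - 1))
  # history fields depend on earlier trials only
  expect_equal(tr$prevOutcome[-1], tr$outcome[-nTrials(s)])
  expect_equal(tr$prevOutcome[1], "none")
  expect_equal(tr$prevRewardRate[-1],
               cumsum(tr$VRewarded)[-nTrials(s)] / seq_len(nTrials(s) - 1))
})

test_that("sessions are reproducible from their seed and reject bad configs", {
  a <- generateSession(taskConfig(nTrials = 30), seed = 5)
  b <- generateSession(taskConfig(nTrials = 30), seed = 5)
  expect_identical(trialTable(a), trialTable(b))
  expect_error(taskConfig(nTrials = 0), "positive")
  expect_error(taskConfig(probLevels = c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("degenerate configurations produce the expected outcomes", {
  # all-safe offers: every completed trial is a win
  s <- generateSession(taskConfig(nTrials = 100, probLevels = 1,
                                  pOptOut = 0.2), seed = 3)
  expect_true(all(trialTable(s)$outcome[trialTable(s)$outcome != "opt_out"] == "win"))
  # no opt-outs requested
  s2 <- generateSession(taskConfig(nTrials = 100, pOptOut = 0), seed = 3)
  expect_equal(nTrials(s2), 100L)
  expect_false(any(trialTable(s2)$outcome == "opt_out"))
})

test_that("empirical win frequency matches the offered probability", {
  s <- generateSession(taskConfig(nTrials = 1000, pOptOut = 0), seed = 9)
  tr <- trialTable(s)
  pCh <- ifelse(tr$choice == "left", tr$pLeft, tr$pRight)
  for (p in unique(round(pCh, 2))) {
    sel <- abs(pCh - p) < 1e-9
    n <- sum(sel)
    k <- sum(tr$outcome[sel] == "win")
    ci <- qbinom(c(0.005, 0.995), n, p)
    expect_gte(k, ci[1])
    expect_lte(k, ci[2])
  }
})

test_that("click trains are Poisson at the volume-mapped rate", {
  s <- generateSession(taskConfig(nTrials = 500, volumes = 48,
                                  clickRateMap = c("48" = 40)), seed = 4)
  tr <- trialTable(s)
  ev <- eventTimes(s)
  for (side in c("clickL", "clickR")) {
    n <- tabulate(ev$trial[ev$event == side], nTrials(s))
    d <- n - 40 * tr$tGo          # cue period = trial start to go cue
    expect_lt(abs(mean(d)), 3 * sd(d) / sqrt(length(d)))
  }
})

test_that("a kernel-free unit reproduces textbook Poisson count statistics", {
  s <- generateSession(taskConfig(nTrials = 100), seed = 6)
  sp <- simulateSpikes(s, constantNeuron(5), seed = 6)
  y <- as.numeric(spikeCounts(sp))   # 16000 bins at mean 0.25
  m <- mean(y)
  se <- sd(y) / sqrt(length(y))
  expect_lt(abs(m - 0.25), 3 * se)
  # variance equals the mean (Poisson), within 3 SE of the variance estimate
  v <- var(y)
  seVar <- sqrt((mean((y - m)^4) - v^2) / length(y))
  expect_lt(abs(v - m), 3 * seVar)
  # exponential link: shifting the background by log 2 doubles the rate
  sp2 <- simulateSpikes(s, constantNeuron(10), seed = 6)
  expect_lt(abs(mean(spikeCounts(sp2)) / m - 2), 0.15)
})

test_that("a positive win kernel elevates post-reward rates on wins", {
  s <- generateSession(taskConfig(nTrials = 200, seed = 21))
  nr <- makeArchetypes(taskConfig(nTrials = 200, seed = 21), seed = 21)
  sp <- simulateSpikes(s, nr[[5]], seed = 21)   # rewardLocked
  r <- epochRates(sp, s, "postChoice")
  tr <- trialTable(s)
  tt <- t.test(r[tr$outcome == "win"], r[tr$outcome == "loss"],
               alternative = "greater")
  expect_lt(tt$p.value, 0.01)
})

test_that("archetypes are distinct and the planted positive is archetype 3 only", {
  nr <- fxNeurons()
  expect_length(nr, 5)
  expect_setequal(vapply(nr, function(n) n@archetype, ""),
                  archetypeNamesForTest())
  maps <- lapply(nr, function(n) n@weights)
  expect_length(unique(maps), 5)
  b <- buildBasis()
  lag <- (seq_len(nrow(b@evaluation)) - 0.5) * b@dt
  late <- lag > 2 & lag < 3.5    # lags reaching the pre-choice epoch
  for (n in nr) {
    kw <- n@weights
    kW <- if (!is.null(kw$prevWin)) as.numeric(b@evaluation %*% kw$prevWin) else numeric(nrow(b@evaluation))
    kL <- if (!is.null(kw$prevLoss)) as.numeric(b@evaluation %*% kw$prevLoss) else numeric(nrow(b@evaluation))
    lateAsym <- max(abs(kW[late] - kL[late]))
    if (n@archetype == "preChoiceRewardHistory") {
      expect_gt(lateAsym, 0.1)
      expect_gt(max(kW[late]), 0.3)
    } else {
      expect_lt(lateAsym, 1e-9)
    }
    # every archetype carries outcome and choice kernels
    expect_true(all(c("win", "loss", "leftChoice", "rightChoice") %in% names(kw)))
  }
})

test_that("runaway kernel weights are reported, not clipped", {
  s <- generateSession(taskConfig(nTrials = 20), seed = 2)
  bad <- constantNeuron(5)
  bad@weights <- list(win = rep(10, 9))
  expect_error(simulateSpikes(s, bad, seed = 1), "overflow")
})
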