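# Epoch-rate regressions and cluster enrichment.

# epoch rates planted from a linear model on the session's conditions
plantRates <- function(tr, f, sd = 1, seed = 1) {
  withr::with_seed(seed, f(tr) + rnorm(nrow(tr), 0, sd))
}

test_that("the five-trials-back regression recovers a planted lag-1 effect", {
  s <- generateSession(taskConfig(nTrials = 300, pOptOut = 0), seed = 41)
  tr <- trialTable(s)
  oc <- ifelse(tr$outcome == "win", 1, -1)
  r <- plantRates(tr, function(tr) 10 + 2 * c(0, oc[-nrow(tr)]), sd = 1)
  res <- historyRegression(r, s)
  co <- res$coefficients
  est <- setNames(co$estimate, co$term)
  se1 <- 1 / sqrt(sum(!is.na(r)) ) * 3   # generous 3-SE band at n ~ 300
  expect_lt(abs(est[["h1"]] - 2), 0.3)
  expect_lt(max(abs(est[c("h2", "h3", "h4", "h5")])), 0.3)
  expect_lt(co$p[co$term == "h1"], 0.001)
  expect_lt(res$modelP, 0.001)
  # flipping the outcome codes flips every history coefficient exactly
  s2 <- s
  tr2 <- tr
  tr2$outcome <- ifelse(tr$outcome == "win", "loss", "win")
  tr2$prevOutcome <- c("none", tr2$outcome[-nrow(tr2)])
  s2@trials <- tr2
  res2 <- historyRegression(r, s2)
  est2 <- setNames(res2$coefficients$estimate, res2$coefficients$term)
  expect_equal(unname(est2[paste0("h", 1:5)]),
               unname(-est[paste0("h", 1:5)]), tolerance = 1e-10)
})

test_that("history coefficients are calibrated on rate-independent nulls", {
  s <- generateSession(taskConfig(nTrials = 150, pOptOut = 0), seed = 43)
  hits <- 0; total <- 0
  for (i in 1:200) {
    r <- withr::with_seed(1000 + i, rnorm(150, 10, 2))
    res <- historyRegression(r, s)
    p <- res$coefficients$p[res$coefficients$term %in% paste0("h", 1:5)]
    hits <- hits + sum(p < 0.05); total <- total + length(p)
  }
  expect_gt(hits / total, 0.02)
  expect_lt(hits / total, 0.08)
})

test_that("outcome adaptation is classified by the sign rule", {
  s <- generateSession(taskConfig(nTrials = 300, pOptOut = 0.05), seed = 45)
  tr <- trialTable(s)
  oc <- ifelse(tr$outcome == "win", 1, ifelse(tr$outcome == "loss", -1, 0))
  poc <- c(0, oc[-nrow(tr)])
  rAdapt <- plantRates(tr, function(tr) 8 + 3 * oc - 1.5 * poc, sd = 1)
  resA <- outcomeAdaptationRegression(rAdapt, s)
  expect_equal(resA$classification, "adaptive")
  rSame <- plantRates(tr, function(tr) 8 + 3 * oc + 1.5 * poc, sd = 1)
  expect_equal(outcomeAdaptationRegression(rSame, s)$classification,
               "modulated-non-adaptive")
  rNull <- plantRates(tr, function(tr) rep(8, nrow(tr)), sd = 1)
  expect_equal(outcomeAdaptationRegression(rNull, s)$classification,
               "not-significant")
  # classification is invariant to rate rescaling (Hz vs spikes per bin)
  expect_equal(outcomeAdaptationRegression(rAdapt * 0.05, s)$classification,
               "adaptive")
})

test_that("volume adaptation uses rewarded volume and the sign rule", {
  s <- generateSession(taskConfig(nTrials = 300, pOptOut = 0.05), seed = 47)
  tr <- trialTable(s)
  poc <- c(0, ifelse(tr$outcome == "win", 1,
                     ifelse(tr$outcome == "loss", -1, 0))[-nrow(tr)])
  rA <- plantRates(tr, function(tr) 5 + 0.1 * tr$VRewarded - 0.8 * poc, sd = 1)
  resA <- volumeAdaptationRegression(rA, s)
  expect_equal(resA$classification, "adaptive")
  est <- setNames(resA$coefficients$estimate, resA$coefficients$term)
  expect_lt(abs(est[["vol"]] - 0.1), 0.03)
  rB <- plantRates(tr, function(tr) 5 + 0.1 * tr$VRewarded + 0.8 * poc, sd = 1)
  expect_equal(volumeAdaptationRegression(rB, s)$classification,
               "modulated-non-adaptive")
})

test_that("the RPE regression recovers its coefficient and rejects degenerate sessions", {
  s <- generateSession(taskConfig(nTrials = 300, pOptOut = 0), seed = 49)
  tr <- trialTable(s)
  pCh <- ifelse(tr$choice == "left", tr$pLeft, tr$pRight)
  vCh <- ifelse(tr$choice == "left", tr$VLeft, tr$VRight)
  rpe <- tr$VRewarded - pCh * vCh
  r <- plantRates(tr, function(tr) 6 + 0.2 * rpe, sd = 1)
  res <- rpeRegression(r, s)
  est <- setNames(res$coefficients$estimate, res$coefficients$term)
  expect_lt(abs(est[["rpe"]] - 0.2), 3 * 0.02)
  expect_lt(res$coefficients$p[res$coefficients$term == "rpe"], 0.001)
  # all-safe sessions have zero-variance RPE
  sSafe <- generateSession(taskConfig(nTrials = 100, probLevels = 1,
                                      pOptOut = 0), seed = 50)
  expect_error(rpeRegression(rep(5, 100) + rnorm(100), sSafe),
               "zero-variance RPE")
})

test_that("cluster enrichment produces exact binomial intervals", {
  cls <- c(rep("adaptive", 10), rep("not-significant", 10))
  lab <- rep(1:2, each = 10)
  enr <- clusterEnrichment(cls, lab)
  expect_equal(enr$prob, c(1, 0))
  expect_equal(enr$lo[2], 0)
  expect_equal(enr$hi[1], 1)
  ciA <- binom.test(10, 10)$conf.int
  expect_equal(c(enr$lo[1], enr$hi[1]), as.numeric(ciA))
  # planted enrichment separates; uniform planting overlaps
  expect_gt(enr$lo[1], enr$prob[2])
  unif <- clusterEnrichment(rep(c("adaptive", "not-significant"), 10), lab)
  expect_true(unif$lo[1] <= unif$hi[2] && unif$lo[2] <= unif$hi[1])
  expect_error(clusterEnrichment(cls, lab[1:5]), "cover")
})
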