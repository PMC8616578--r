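# Reduced designs, CPD, mutual information, d', cluster averages.

test_that("reduced designs erase condition identity but conserve mass", {
  d <- fxDesign()
  red <- reducedDesign(d, "reward")
  tr <- d@trials
  i <- which(tr$outcome == "win")[1]
  # both outcome streams now carry 1/2 at the trial's reward bin
  for (v in c("win", "loss")) {
    e <- red@events[red@events$trial == i & red@events$variable == v, ]
    expect_equal(nrow(e), 1L)
    expect_equal(e$amp, 0.5)
    expect_equal(e$bin, d@events$bin[d@events$trial == i &
                                     d@events$variable == "win"])
  }
  # column sums conserved over the group
  sumGroup <- function(ev) sum(ev$amp[ev$variable %in% c("win", "loss")])
  expect_equal(sumGroup(red@events), sumGroup(d@events))
  expect_error(reducedDesign(d, "sneezes"), "unknown covariate group")
  # erasing a group that is absent from the design changes nothing
  dnh <- buildDesignMatrix(fxSession(), "noHistory")
  expect_equal(reducedDesign(dnh, "rewardHistory")@X, dnh@X)
})

test_that("CPD is exactly zero when the reduced design equals the full design", {
  dnh <- buildDesignMatrix(fxSession(), "noHistory")
  sp <- fxSpikes()[[5]]
  f <- fitGLM(sp, dnh, xi = 1)
  res <- cpd(f, sp, dnh, "rewardHistory", nShuffles = 20, seed = 1)
  expect_equal(unname(res$raw), rep(0, length(res$raw)))
  expect_false(any(res$significant))
  expect_equal(unname(res$corrected), rep(0, length(res$corrected)))
})

test_that("CPD flags the planted reward-history unit, not the history-free one", {
  d <- fxDesign()
  c3 <- cpd(fxFit3(), fxSpikes()[[3]], d, "rewardHistory", nShuffles = 100,
            seed = 1)
  c5 <- cpd(fxFit5(), fxSpikes()[[5]], d, "rewardHistory", nShuffles = 100,
            seed = 1)
  late <- c3$time > 2 & c3$time < 3.6     # pre-choice epoch
  early <- c3$time > -0.1 & c3$time < 1
  expect_gt(sum(c3$significant[late]), 5)
  expect_gt(sum(c3$significant[early]), 0)
  # the history-free unit shows far weaker evidence and a near-zero median
  expect_lt(mean(c5$significant), mean(c3$significant))
  expect_lt(median(abs(c5$corrected)), 0.02)
  # corrected values are zeroed wherever non-significant
  expect_true(all(c3$corrected[!c3$significant] == 0))
})

test_that("CPD of the reward group shows up after reward delivery", {
  d <- fxDesign()
  c5 <- cpd(fxFit5(), fxSpikes()[[5]], d, "reward", nShuffles = 100, seed = 2)
  post <- c5$time > 0 & c5$time < 1.5
  pre <- c5$time < -0.5
  expect_gt(sum(c5$significant[post]), 5)
  expect_lt(mean(c5$significant[pre]), 0.3)
})

# toy fit with hand-set kernels and (numerically) no parameter uncertainty
toyFit <- function(design, winWeights, theta0) {
  M <- 9
  theta <- setNames(numeric(ncol(design@X)), colnames(design@X))
  i <- match("win", design@variables)
  theta[((i - 1) * M + 1):(i * M)] <- winWeights
  new("GLMFit", theta = theta, theta0 = theta0, xi = 0,
      nll = c(train = 0), r2Test = 1,
      kernelCov = diag(1e-12, ncol(design@X) + 1), converged = TRUE,
      variables = design@variables, basis = design@basis)
}

test_that("MI matches a brute-force evaluation on an exact Poisson mixture", {
  s <- fxSession()
  # snap side-port entry to bin centres so every trial sees the same lag
  tr <- trialTable(s)
  tr$tChoice <- (floor((tr$tChoice + 2) / 0.05) + 0.5) * 0.05 - 2
  s2 <- s
  s2@trials <- tr
  d <- buildDesignMatrix(s2)
  b <- d@basis
  # win kernel worth log(20) at lag bin 3 (tau = 0.1 s); losses stay at 1 Hz
  w <- numeric(9)
  w[5] <- log(20) / b@evaluation[3, 5]
  fit <- toyFit(d, w, log(1 * 0.05))
  res <- mutualInformation(fit, d, "reward", nSamples = 100, nShuffles = 30,
                           seed = 1)
  j <- which.min(abs(res$time - 0.10))
  # brute force: truncated Poisson mixture over counts 0..10
  done <- tr$outcome %in% c("win", "loss")
  pWin <- mean(tr$outcome[done] == "win")
  pk <- function(lam) {
    p <- dpois(0:9, lam)
    c(p, 1 - sum(p))
  }
  H <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  pyW <- pk(20 * 0.05); pyL <- pk(1 * 0.05)
  pY <- pWin * pyW + (1 - pWin) * pyL
  exact <- (H(pY) - pWin * H(pyW) - (1 - pWin) * H(pyL)) / log(2)
  expect_gt(exact, 0.1)
  expect_lt(abs(res$raw[j] - exact), 0.005)
  # information bounds: MI cannot exceed the stimulus entropy
  expect_lte(max(res$raw, na.rm = TRUE), res$HX + 1e-9)
  expect_error(mutualInformation(fit, d, "clicks"), "trial-level")
})

test_that("MI is zero when the generative model ignores the covariate", {
  d <- fxDesign()
  fit <- toyFit(d, numeric(9), log(0.25))   # 5 Hz, no kernels at all
  res <- mutualInformation(fit, d, "rewardHistory", nSamples = 50,
                           nShuffles = 30, seed = 3)
  expect_lt(max(abs(res$raw), na.rm = TRUE), 1e-6)
  # at this vanishing scale significance is a coin flip against an equally
  # vanishing null; the rate stays at its nominal few percent
  expect_lte(mean(res$significant), 0.15)
})

test_that("d' matches its analytic value for Gaussian rates", {
  withr::with_seed(12, {
    a <- matrix(rnorm(200, 10, 2), 200, 1)
    b <- matrix(rnorm(200, 14, 2), 200, 1)
  })
  dp <- lofcEncode:::dprimeStat(a, b)
  # true d' = |14 - 10| / 2 = 2, SE ~ sqrt(2/n + d'^2/(2n)) per condition
  se <- sqrt(2 / 200 + 4 / 400)
  expect_lt(abs(dp - 2), 3 * se)
})

test_that("d' separates previous wins from losses only for the planted unit", {
  s <- fxSession()
  dp3 <- dprime(fxSpikes()[[3]], s, nShuffles = 300, seed = 4)
  dp5 <- dprime(fxSpikes()[[5]], s, nShuffles = 300, seed = 4)
  late <- dp3$time > 2 & dp3$time < 3.6
  expect_gt(sum(dp3$significant[late]), 5)
  expect_lt(sum(dp5$significant[late], na.rm = TRUE),
            sum(dp3$significant[late]))
  # identical condition distributions: corrected d' near zero on average
  expect_lt(abs(mean(dp5$corrected, na.rm = TRUE)), 0.15)
  expect_error(dprime(fxSpikes()[[3]], s,
                      conditionA = rep(FALSE, nTrials(s))), "populated")
})

test_that("cluster averages respect exclusions and neuron order", {
  mk <- function(u, vals, outlier = FALSE) {
    structure(list(metric = "cpd", unit = "percent", group = "reward",
                   align = "choice", time = 1:4, raw = vals,
                   corrected = vals, nullMean = rep(0, 4),
                   ciHi = rep(0, 4), significant = vals > 0,
                   outlier = outlier), class = "metricSeries")
  }
  ml <- list(a = mk("a", c(1, 2, 3, 4)), b = mk("b", c(3, 4, 5, 6)),
             c = mk("c", c(10, 10, 10, 10)))
  lab <- c(a = 1, b = 1, c = 2)
  avg <- clusterAverage(ml, lab)
  expect_equal(avg$mean[avg$cluster == 1], c(2, 3, 4, 5))
  expect_equal(avg$sem[avg$cluster == 1], rep(1, 4))
  # single-neuron cluster: SEM undefined, flagged as NA
  expect_true(all(is.na(avg$sem[avg$cluster == 2])))
  # permuting neurons leaves the averages unchanged
  avg2 <- clusterAverage(ml[c(3, 1, 2)], lab[c(3, 1, 2)])
  expect_equal(avg2$mean, avg$mean)
  # outlier units are dropped from the averages
  ml$b$outlier <- TRUE
  avg3 <- clusterAverage(ml, lab)
  expect_equal(avg3$mean[avg3$cluster == 1], c(1, 2, 3, 4))
  expect_error(clusterAverage(ml, c(a = 1, b = 1)), "cover")
})
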