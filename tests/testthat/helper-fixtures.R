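# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# A mid-sized session with one unit per archetype, its design matrix, and a
# GLM fit of the planted reward-history unit: the workhorse for the GLM and
# metric tests.
fxSession <- function() fixture("session", function() {
  generateSession(taskConfig(nTrials = 250, seed = 42))
})

fxNeurons <- function() fixture("neurons", function() {
  makeArchetypes(taskConfig(nTrials = 250, seed = 42), nPerArchetype = 1,
                 seed = 42)
})

fxSpikes <- function() fixture("spikes", function() {
  simulatePopulation(fxSession(), fxNeurons(), seed = 42)
})

fxDesign <- function() fixture("design", function() {
  buildDesignMatrix(fxSession())
})

# fitted preChoiceRewardHistory unit (index 3) and rewardLocked unit (index 5)
fxFit3 <- function() fixture("fit3", function() {
  fitGLM(fxSpikes()[[3]], fxDesign(), xi = 1)
})

fxFit5 <- function() fixture("fit5", function() {
  fitGLM(fxSpikes()[[5]], fxDesign(), xi = 1)
})

# population for clustering tests: 8 units per archetype
fxClusterPop <- function() fixture("clusterPop", function() {
  session <- generateSession(taskConfig(nTrials = 200, seed = 11))
  neurons <- makeArchetypes(taskConfig(nTrials = 200, seed = 11),
                            nPerArchetype = 8, seed = 11)
  spikes <- simulatePopulation(session, neurons, seed = 11)
  list(session = session, spikes = spikes,
       truth = rep(seq_along(archetypeNamesForTest()), each = 8))
})

archetypeNamesForTest <- function() {
  c("trialStartBurst", "cuePersistent", "preChoiceRewardHistory",
    "choiceLocked", "rewardLocked")
}

fxPsthFS <- function() fixture("psthFS", function() {
  pop <- fxClusterPop()
  buildPsthFeatureSpace(psthMatrix(pop$spikes, pop$session))
})

# true kernel of a ground-truth neuron on the lag grid, one column per
# planted variable
trueKernels <- function(neuron, basis = buildBasis()) {
  vapply(names(neuron@weights), function(v)
    as.numeric(basis@evaluation %*% neuron@weights[[v]]),
    numeric(nrow(basis@evaluation)))
}

# correlation between planted and recovered kernels, concatenated over the
# planted task variables
kernelRecovery <- function(fit, neuron, basis = buildBasis()) {
  kt <- trueKernels(neuron, basis)
  k <- kernels(fit)[, colnames(kt), drop = FALSE]
  cor(as.numeric(k), as.numeric(kt))
}

# independent O(N^2) silhouette, straight from the defining sums
bruteSilhouette <- function(x, lab) {
  D <- as.matrix(dist(x))
  n <- nrow(x)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(lab == lab[i])
    a <- sum(D[i, setdiff(own, i)]) / (length(own) - 1)
    b <- min(vapply(setdiff(unique(lab), lab[i]), function(k)
      mean(D[i, lab == k]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# independent elementwise Mahalanobis separation (double loop over clusters
# and points)
bruteMahalanobis <- function(x, lab) {
  K <- max(lab)
  out <- matrix(NA_real_, K, K)
  for (B in seq_len(K)) {
    xb <- x[lab == B, , drop = FALSE]
    mu <- colMeans(xb)
    Sinv <- solve(stats::cov(xb))
    for (A in seq_len(K)) {
      xa <- x[lab == A, , drop = FALSE]
      out[A, B] <- mean(apply(xa, 1, function(p)
        sqrt(drop(t(p - mu) %*% Sinv %*% (p - mu)))))
    }
  }
  out
}

# Gaussian blob data: K clusters of n points in d dims, centres `sep` apart
blobs <- function(K, n, d, sep, seed = 1, sd = 1) {
  withr::with_seed(seed, {
    centers <- matrix(rnorm(K * d), K, d)
    centers <- centers / sqrt(rowSums(centers^2)) * sep
    x <- do.call(rbind, lapply(seq_len(K), function(k)
      matrix(rnorm(n * d, sd = sd), n, d) + rep(centers[k, ], each = n)))
    list(x = x, labels = rep(seq_len(K), each = n))
  })
}
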