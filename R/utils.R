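# Internal helpers shared across modules.

# Derive a deterministic sub-seed from a master seed and a stream name, so one
# user-facing seed fans out to independent named substreams (session, neurons,
# spikes, shuffles, ...). Kept below 2^31 - 1.
subSeed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483629 + 1)
}

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Centred moving average matching Matlab's smooth.m: full 250 ms (5-bin)
# window in the interior, symmetric shrinking windows at the edges.
boxcarSmooth <- function(x, nbins = 5L) {
  n <- length(x)
  if (n == 0) return(x)
  half <- nbins %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    h <- min(half, i - 1L, n - i)
    out[i] <- mean(x[(i - h):(i + h)])
  }
  out
}

# Row-wise boxcar smoothing of a trials x bins matrix.
smoothRows <- function(m, nbins = 5L) {
  t(apply(m, 1L, boxcarSmooth, nbins = nbins))
}

# Inclusive 50 ms grid of bin centres from a to b (121 bins for [-2, 4]).
binGrid <- function(window, dt = 0.05) {
  seq(window[1], window[2], by = dt)
}

# Count spikes into bins centred on `centers` (width dt).
binSpikes <- function(times, centers, dt = 0.05) {
  edges <- c(centers - dt / 2, centers[length(centers)] + dt / 2)
  counts <- hist(times[times >= edges[1] & times < edges[length(edges)]],
                 breaks = edges, plot = FALSE)$counts
  as.integer(counts)
}

# The 15 task variables of the default encoding model, in canonical order.
taskVariables <- function() {
  c("leftClick", "rightClick", "leftFlash", "rightFlash",
    "leftChoice", "rightChoice", "safeChoice", "riskyChoice",
    "win", "loss", "prevWin", "prevLoss", "prevOptOut",
    "prevRewardRate", "sessionProgress")
}

# Per-variable event anchor used for metric alignment and reporting.
variableAnchor <- function(v) {
  switch(v,
    leftClick = , rightClick = , leftFlash = , rightFlash = ,
    prevWin = , prevLoss = , prevOptOut = ,
    prevRewardRate = , sessionProgress = "start",
    leftChoice = , rightChoice = , safeChoice = , riskyChoice = "exitCenter",
    win = , loss = , outcome = , currentVolume = , previousVolume = "choice",
    stop("unknown variable: ", v))
}

# Sample from N(mu, Sigma) via Cholesky with a tiny ridge for safety.
rmvn <- function(n, mu, Sigma) {
  p <- length(mu)
  R <- tryCatch(chol(Sigma), error = function(e) chol(Sigma + diag(1e-8, p)))
  matrix(rnorm(n * p), n, p) %*% R + rep(mu, each = n)
}
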