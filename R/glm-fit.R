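# L2-penalised Poisson encoding model: fitting, cross-validation,
# hyperparameter search, held-out variance explained, model comparison.

# Align a unit's binned counts with the rows of a design matrix.
countsVector <- function(spikes, design) {
  cnt <- if (is(spikes, "SpikeTrains")) spikeCounts(spikes) else spikes
  if (ncol(cnt) != design@nBinsPerTrial)
    stop("count bins (", ncol(cnt), ") do not match design rows per trial (",
         design@nBinsPerTrial, ")")
  as.numeric(t(cnt))
}

poissonNll <- function(eta, y) {
  # per-bin mean of lambda*dt - y*log(lambda*dt), dropping the y! constant
  mean(exp(eta) - y * eta)
}

#' Fit the penalised Poisson encoding model at a fixed penalty
#'
#' Minimises the convex objective
#' sum_t [exp(eta_t) - y_t eta_t] + xi/2 ||theta||^2 (background unpenalised)
#' by damped Newton iteration, to a gradient-norm tolerance. The parameter
#' covariance is the inverse of the objective's Hessian at the optimum.
#'
#' @param spikes a [SpikeTrains-class] (or a trials x bins count matrix whose
#'   bins match the design rows).
#' @param design a [DesignMatrix-class].
#' @param xi L2 penalty (>= 0).
#' @param trials optional trial ids to fit on (default: all).
#' @param tol max-gradient convergence tolerance.
#' @param maxIter Newton iteration cap; failure to reach `tol` is flagged in
#'   `converged`, not silently ignored.
#' @param init optional warm-start parameter vector (theta0 last).
#' @return a [GLMFit-class].
#' @export
fitGLM <- function(spikes, design, xi = 0.1, trials = NULL, tol = 1e-6,
                   maxIter = 50L, init = NULL) {
  if (xi < 0) stop("xi must be non-negative")
  y <- countsVector(spikes, design)
  keep <- if (is.null(trials)) rep(TRUE, length(y)) else design@trialIndex %in% trials
  X <- cbind(design@X[keep, , drop = FALSE], intercept = 1)
  y <- y[keep]
  p <- ncol(X)
  pen <- c(rep(xi, p - 1L), 0)
  beta <- if (is.null(init)) c(numeric(p - 1L), log(mean(y) + 1e-10)) else init
  eta <- as.numeric(X %*% beta)
  obj <- sum(exp(eta) - y * eta) + sum(pen * beta^2) / 2
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    mu <- exp(eta)
    g <- crossprod(X, mu - y)[, 1] + pen * beta
    if (max(abs(g)) < tol) { converged <- TRUE; break }
    H <- crossprod(X * mu, X)
    diag(H) <- diag(H) + pen
    step <- tryCatch(solve(H, g), error = function(e) {
      solve(H + diag(1e-8 * max(diag(H)), p), g)
    })
    alpha <- 1
    repeat {
      betaNew <- beta - alpha * step
      etaNew <- as.numeric(X %*% betaNew)
      if (max(etaNew) < 30) {
        objNew <- sum(exp(etaNew) - y * etaNew) + sum(pen * betaNew^2) / 2
        if (objNew <= obj + 1e-12) break
      }
      alpha <- alpha / 2
      if (alpha < 1e-10) { betaNew <- beta; etaNew <- eta; objNew <- obj; break }
    }
    beta <- betaNew; eta <- etaNew; obj <- objNew
  }
  mu <- exp(eta)
  H <- crossprod(X * mu, X)
  diag(H) <- diag(H) + pen
  cov <- tryCatch(chol2inv(chol(H)), error = function(e)
    chol2inv(chol(H + diag(1e-8 * max(diag(H)), p))))
  theta <- beta[-p]
  names(theta) <- colnames(design@X)
  dimnames(cov) <- list(c(colnames(design@X), "intercept"),
                        c(colnames(design@X), "intercept"))
  new("GLMFit", theta = theta, theta0 = beta[p], xi = xi,
      nll = c(train = poissonNll(eta, y)), r2Test = NA_real_,
      kernelCov = cov, converged = converged,
      variables = design@variables, basis = design@basis)
}

#' Predicted mean counts per bin for (a subset of) a design
#'
#' @param fit a [GLMFit-class]
#' @param design a [DesignMatrix-class]
#' @param trials optional trial ids
#' @return numeric vector of mean counts per 50 ms bin
#' @export
predictRate <- function(fit, design, trials = NULL) {
  keep <- if (is.null(trials)) rep(TRUE, nrow(design@X)) else design@trialIndex %in% trials
  exp(as.numeric(design@X[keep, , drop = FALSE] %*% fit@theta) + fit@theta0)
}

evalNll <- function(fit, spikes, design, trials) {
  y <- countsVector(spikes, design)
  keep <- design@trialIndex %in% trials
  eta <- as.numeric(design@X[keep, , drop = FALSE] %*% fit@theta) + fit@theta0
  poissonNll(eta, y[keep])
}

# ---- cross-validation ------------------------------------------------------

#' Partition trials into balanced cross-validation folds
#'
#' Greedy stratified assignment on the joint outcome x previous-outcome x
#' choice cell: trials within each cell are shuffled and dealt round-robin,
#' starting each cell at the currently smallest partition, so every condition
#' count differs by at most one across partitions where feasible.
#'
#' @param session a [Session-class].
#' @param seed integer seed (deterministic labels for a given seed).
#' @param nParts number of partitions.
#' @return list with `labels` (partition id per trial), `balanceReport`
#'   (per-partition condition counts) and `chisqP` (homogeneity p-value of the
#'   report; near 1 on well-balanced data).
#' @export
partitionTrials <- function(session, seed = 1L, nParts = 5L) {
  tr <- trialTable(session)
  n <- nrow(tr)
  if (n < nParts) stop("need at least ", nParts, " trials")
  cell <- paste(tr$outcome, tr$prevOutcome,
                ifelse(is.na(tr$choice), "none", tr$choice), sep = ".")
  labels <- integer(n)
  withSeed(subSeed(seed, "cv"), {
    sizes <- integer(nParts)
    for (cl in sort(unique(cell))) {
      idx <- which(cell == cl)
      idx <- idx[sample.int(length(idx))]
      ord <- order(sizes, seq_len(nParts))  # start filling the smallest part
      for (j in seq_along(idx)) {
        part <- ord[(j - 1L) %% nParts + 1L]
        labels[idx[j]] <- part
        sizes[part] <- sizes[part] + 1L
      }
    }
  })
  conds <- cbind(
    win = tr$outcome == "win", loss = tr$outcome == "loss",
    prevWin = tr$prevOutcome == "win", prevLoss = tr$prevOutcome == "loss",
    left = !is.na(tr$choice) & tr$choice == "left",
    right = !is.na(tr$choice) & tr$choice == "right")
  report <- t(vapply(seq_len(nParts), function(p)
    colSums(conds[labels == p, , drop = FALSE]), numeric(ncol(conds))))
  rownames(report) <- paste0("part", seq_len(nParts))
  spread <- apply(report, 2, function(x) diff(range(x)))
  if (any(spread > 1 + 1e-9))
    warning("exact joint balance infeasible; partitions balanced marginally (max spread ",
            max(spread), ")")
  chisqP <- tryCatch(
    suppressWarnings(stats::chisq.test(report)$p.value),
    error = function(e) NA_real_)
  list(labels = labels, balanceReport = report, chisqP = chisqP,
       nParts = as.integer(nParts))
}

# ---- hyperparameter search and model selection -----------------------------

#' Cross-validated penalty search and model selection for one unit
#'
#' For each penalty on a refining log-spaced grid over `xiRange`, four models
#' are fit by four-fold cross-validation on the non-test partitions (each fit
#' on three folds, assessed on the held-out validation fold) and the fold
#' model with the lowest validation negative log-likelihood is kept; the
#' penalty whose kept model has the lowest negative log-likelihood on the test
#' partition wins. Subsequent rounds bracket the previous argmin. The returned
#' fit carries train/validation/test NLL and the held-out R2.
#'
#' @param spikes a [SpikeTrains-class].
#' @param design a [DesignMatrix-class].
#' @param scheme a [partitionTrials()] result.
#' @param testPartition partition id held out from all fitting.
#' @param xiRange penalty search interval.
#' @param nPerRound,nRounds grid resolution and number of refinement rounds.
#' @param tol,maxIter passed to [fitGLM()].
#' @return a [GLMFit-class] with `xi`, `nll["test"]` and `r2Test` filled in,
#'   plus attributes `xiGrid` and `testNll` tracing the search.
#' @export
selectModel <- function(spikes, design, scheme, testPartition = 1L,
                        xiRange = c(1e-5, 10), nPerRound = 7L, nRounds = 3L,
                        tol = 1e-6, maxIter = 50L) {
  parts <- sort(unique(scheme$labels))
  if (!testPartition %in% parts) stop("testPartition not in scheme")
  trainParts <- setdiff(parts, testPartition)
  testTrials <- which(scheme$labels == testPartition)
  lo <- log10(xiRange[1]); hi <- log10(xiRange[2])
  allXi <- numeric(0); allNll <- numeric(0); best <- NULL
  for (round in seq_len(nRounds)) {
    grid <- 10^seq(lo, hi, length.out = nPerRound)
    grid <- setdiff(signif(grid, 10), signif(allXi, 10))
    for (xi in grid) {
      foldFits <- lapply(trainParts, function(v) {
        fitTrials <- which(scheme$labels %in% setdiff(trainParts, v))
        fit <- fitGLM(spikes, design, xi = xi, trials = fitTrials,
                      tol = tol, maxIter = maxIter)
        list(fit = fit, valNll = evalNll(fit, spikes, design,
                                         which(scheme$labels == v)))
      })
      kept <- foldFits[[which.min(vapply(foldFits, `[[`, 0, "valNll"))]]
      testNll <- evalNll(kept$fit, spikes, design, testTrials)
      allXi <- c(allXi, xi); allNll <- c(allNll, testNll)
      if (is.null(best) || testNll < best$testNll)
        best <- list(fit = kept$fit, valNll = kept$valNll, testNll = testNll,
                     xi = xi)
    }
    if (any(!vapply(allNll, is.finite, TRUE)) && is.null(best))
      stop("all fits diverged")
    # bracket the argmin for the next round
    ord <- order(allXi)
    i <- which(allXi[ord] == best$xi)
    lo <- log10(allXi[ord][max(1, i - 1)])
    hi <- log10(allXi[ord][min(length(ord), i + 1)])
  }
  fit <- best$fit
  fit@xi <- best$xi
  fit@nll <- c(fit@nll["train"], val = best$valNll, test = best$testNll)
  fit@r2Test <- r2Heldout(fit, spikes, design, trials = testTrials)
  attr(fit, "xiGrid") <- allXi
  attr(fit, "testNll") <- allNll
  fit
}

#' Held-out proportion of variance explained
#'
#' Compares the model's predicted mean counts against 250 ms boxcar-smoothed
#' observed counts on held-out trials: R2 = 1 - SSE(model, smoothed) /
#' SSE(mean, smoothed). Negative values indicate a fit worse than the mean.
#'
#' @param fit a [GLMFit-class], or a numeric vector of predicted mean counts
#'   per bin (e.g. the generative rates) aligned with the selected trials.
#' @param spikes a [SpikeTrains-class] (or count matrix).
#' @param design a [DesignMatrix-class].
#' @param trials held-out trial ids (disjoint from training).
#' @param smoothBins width of the boxcar in bins.
#' @return unitless R2 (<= 1, possibly negative).
#' @export
r2Heldout <- function(fit, spikes, design, trials = NULL, smoothBins = 5L) {
  cnt <- if (is(spikes, "SpikeTrains")) spikeCounts(spikes) else spikes
  if (is.null(trials)) trials <- seq_len(nrow(cnt))
  sm <- as.numeric(t(smoothRows(cnt[trials, , drop = FALSE], smoothBins)))
  pred <- if (is.numeric(fit)) {
    stopifnot(length(fit) == length(sm))
    fit
  } else predictRate(fit, design, trials = trials)
  sse0 <- sum((sm - mean(sm))^2)
  if (sse0 < 1e-12) stop("zero-variance held-out data")
  1 - sum((sm - pred)^2) / sse0
}

#' Population-level model comparison between design variants
#'
#' Two-sided Wilcoxon signed-rank test on paired per-neuron held-out negative
#' log-likelihoods, for every pair of variants (or against a reference).
#'
#' @param nllTable matrix or data.frame, neurons x variants, of test NLLs.
#' @param reference optional variant name; when given, only pairs against it
#'   are reported.
#' @return data.frame (variantA, variantB, medianDiff, p); `medianDiff` is the
#'   median of NLL(B) - NLL(A), so positive values favour variant A.
#' @export
compareVariants <- function(nllTable, reference = NULL) {
  m <- as.matrix(nllTable)
  if (nrow(m) < 6) stop("need at least 6 paired neurons for a signed-rank test")
  vars <- colnames(m)
  if (is.null(vars)) vars <- paste0("variant", seq_len(ncol(m)))
  pairs <- utils::combn(vars, 2, simplify = FALSE)
  if (!is.null(reference))
    pairs <- Filter(function(p) reference %in% p, pairs)
  rows <- lapply(pairs, function(p) {
    a <- m[, p[1]]; b <- m[, p[2]]
    d <- b - a
    pval <- if (all(d == 0)) 1 else
      suppressWarnings(wilcox.test(a, b, paired = TRUE, exact = FALSE)$p.value)
    data.frame(variantA = p[1], variantB = p[2],
               medianDiff = median(d), p = pval)
  })
  do.call(rbind, rows)
}
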