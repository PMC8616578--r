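# Per-neuron encoding metrics: coefficient of partial determination with
# shuffle nulls, sampling-based mutual information, and shuffle-corrected
# discriminability, plus cluster averaging.

#' Covariate groups for encoding metrics
#'
#' The five groups whose joint omission defines the reduced models: current
#' reward (win/loss), reward history (previous win/loss/opt-out), choice
#' (left/right), clicks and flashes (left/right). Each group carries the task
#' event its metrics are aligned to.
#'
#' @return named list with `members` and `align` per group.
#' @export
covariateGroups <- function() {
  list(
    reward = list(members = c("win", "loss"), align = "choice"),
    rewardHistory = list(members = c("prevWin", "prevLoss", "prevOptOut"),
                         align = "start"),
    choice = list(members = c("leftChoice", "rightChoice"),
                  align = "exitCenter"),
    clicks = list(members = c("leftClick", "rightClick"), align = "start"),
    flashes = list(members = c("leftFlash", "rightFlash"), align = "start"))
}

#' Reduced design: erase a covariate group's condition identity
#'
#' Replaces the member streams by their arithmetic mean stream (each member
#' carries every member's events at amplitude 1/m), preserving event timing
#' while erasing which condition occurred. No refitting is done; all other
#' covariates are untouched.
#'
#' @param design a [DesignMatrix-class].
#' @param group a group name from [covariateGroups()].
#' @return a [DesignMatrix-class].
#' @export
reducedDesign <- function(design, group) {
  g <- covariateGroups()[[group]]
  if (is.null(g)) stop("unknown covariate group: ", group)
  members <- intersect(g$members, design@variables)
  ev <- design@events
  sel <- ev$variable %in% members
  pooled <- ev[sel, , drop = FALSE]
  if (nrow(pooled) && length(members) > 1) {
    rep_ev <- do.call(rbind, lapply(members, function(v) {
      e <- pooled
      e$variable <- v
      e$amp <- e$amp / length(members)
      e
    }))
    ev <- rbind(ev[!sel, , drop = FALSE], rep_ev)
  }
  rebuildDesign(design, ev)
}

# ---- internal machinery ----------------------------------------------------

# Trial-level condition labels for the permutation groups; NA = ineligible.
groupConditions <- function(trials, group) {
  switch(group,
    reward = ifelse(trials$outcome %in% c("win", "loss"), trials$outcome, NA),
    rewardHistory = ifelse(trials$prevOutcome %in% c("win", "loss", "opt_out"),
                           trials$prevOutcome, NA),
    choice = ifelse(trials$outcome != "opt_out", trials$choice, NA),
    clicks = , flashes = rep("orig", nrow(trials)),
    stop("no trial-level conditions for group: ", group))
}

# Condition-specific log-rate contribution of a group, per trial and bin:
# array trials x conditions x bins. For reward/history/choice the conditions
# are the member labels (the trial's event time under each member's kernel);
# for clicks/flashes they are the original and left/right-swapped streams.
groupContributions <- function(fit, design, group) {
  g <- covariateGroups()[[group]]
  members <- intersect(g$members, design@variables)
  kern <- kernels(fit)
  nb <- design@nBinsPerTrial
  n <- nrow(design@trials)
  nLag <- nrow(kern)
  ev <- design@events
  addKernel <- function(vec, bin, k, amp = 1) {
    span <- bin:min(bin + nLag - 1L, nb)
    vec[span] <- vec[span] + amp * k[seq_along(span)]
    vec
  }
  if (group %in% c("clicks", "flashes")) {
    vl <- members[1]; vr <- members[2]
    conds <- c("orig", "swap")
    out <- array(0, c(n, 2, nb), dimnames = list(NULL, conds, NULL))
    for (i in seq_len(n)) {
      for (m in c(vl, vr)) {
        e <- ev[ev$variable == m & ev$trial == i, , drop = FALSE]
        other <- if (m == vl) vr else vl
        for (j in seq_len(nrow(e))) {
          out[i, 1, ] <- addKernel(out[i, 1, ], e$bin[j], kern[, m], e$amp[j])
          out[i, 2, ] <- addKernel(out[i, 2, ], e$bin[j], kern[, other], e$amp[j])
        }
      }
    }
    return(out)
  }
  condMap <- switch(group,
    reward = c(win = "win", loss = "loss"),
    rewardHistory = c(win = "prevWin", loss = "prevLoss", opt_out = "prevOptOut"),
    choice = c(left = "leftChoice", right = "rightChoice"))
  conds <- names(condMap)
  out <- array(0, c(n, length(conds), nb), dimnames = list(NULL, conds, NULL))
  for (i in seq_len(n)) {
    # the trial's own event bin for this group (one event per eligible trial)
    e <- ev[ev$trial == i & ev$variable %in% members, , drop = FALSE]
    if (!nrow(e)) next
    for (ci in seq_along(conds)) {
      v <- condMap[[ci]]
      if (!v %in% members) next
      out[i, ci, ] <- addKernel(out[i, ci, ], e$bin[1], kern[, v], 1)
    }
  }
  out
}

# trials x tau matrix of absolute per-trial bin indices for an aligned grid
alignedIndex <- function(design, align, alignWindow) {
  dt <- design@basis@dt
  tau <- binGrid(alignWindow, dt)
  at <- switch(align, start = rep(0, nrow(design@trials)),
               exitCenter = design@trials$tExitCenter,
               choice = design@trials$tChoice)
  nb <- design@nBinsPerTrial
  idx <- outer(at, tau, function(a, tt)
    floor((a + tt - design@window[1]) / dt) + 1)
  idx[idx < 1 | idx > nb] <- NA
  storage.mode(idx) <- "integer"
  list(idx = idx, tau = tau)
}

# pick aligned entries out of a trials x bins matrix
alignedValues <- function(m, idx) {
  out <- matrix(NA_real_, nrow(idx), ncol(idx))
  for (j in seq_len(ncol(idx))) {
    ok <- !is.na(idx[, j])
    out[ok, j] <- m[cbind(which(ok), idx[ok, j])]
  }
  out
}

defaultAlignWindow <- function(align) if (align == "start") c(-2, 4) else c(-2, 2)

# condition-balancing weights: each condition contributes equally
conditionWeights <- function(cond) {
  w <- rep(0, length(cond))
  lev <- unique(cond[!is.na(cond)])
  for (l in lev) w[!is.na(cond) & cond == l] <- 1 / (length(lev) * sum(cond == l, na.rm = TRUE))
  w
}

newMetricSeries <- function(metric, unit, group, align, tau, raw, corrected,
                            nullMean, ciHi, significant, extra = list()) {
  structure(c(list(metric = metric, unit = unit, group = group, align = align,
                   time = tau, raw = raw, corrected = corrected,
                   nullMean = nullMean, ciHi = ciHi,
                   significant = significant), extra),
            class = "metricSeries")
}

#' @export
print.metricSeries <- function(x, ...) {
  cat(sprintf("metricSeries '%s' (%s), group %s, aligned to %s: %d bins, %d significant\n",
              x$metric, x$unit, x$group, x$align, length(x$time),
              sum(x$significant)))
  invisible(x)
}

# ---- CPD --------------------------------------------------------------------

#' Coefficient of partial determination for a covariate group
#'
#' Per aligned time bin, compares the trial-summed squared error between
#' observed counts and model predictions under the full design against the
#' reduced design in which the group's condition identity is erased:
#' CPD_t = 100 (SSE_reduced - SSE_full) / SSE_reduced. For the reward,
#' reward-history and choice groups, trial types are weighted so each
#' condition contributes equally. Significance comes from a null of
#' `nShuffles` CPD values in which the group's condition labels are shuffled
#' across trials (event timing and all other covariates fixed): the null mean
#' is subtracted and bins inside the one-sided 95% band are set to 0.
#' Computed on the full dataset (train, validation and test trials).
#'
#' @param fit a [GLMFit-class].
#' @param spikes the unit's [SpikeTrains-class].
#' @param design the full [DesignMatrix-class] the fit used.
#' @param group a group name from [covariateGroups()].
#' @param nShuffles label shuffles for the null (default 500).
#' @param seed integer seed.
#' @param alignWindow aligned window (s) around the group's anchor event.
#' @param weighting balance trial types (ignored for clicks/flashes).
#' @param outlierThreshold raw CPD (%) above which the unit is flagged as an
#'   outlier for cluster averaging.
#' @return a `metricSeries` (see [clusterAverage()]) with `corrected` the
#'   null-mean-subtracted, significance-masked CPD in percent.
#' @export
cpd <- function(fit, spikes, design, group, nShuffles = 500L, seed = 1L,
                alignWindow = NULL, weighting = TRUE, outlierThreshold = 50) {
  g <- covariateGroups()[[group]]
  if (is.null(g)) stop("unknown covariate group: ", group)
  if (is.null(alignWindow)) alignWindow <- defaultAlignWindow(g$align)
  nb <- design@nBinsPerTrial
  n <- nrow(design@trials)
  y <- matrix(countsVector(spikes, design), n, nb, byrow = TRUE)
  etaFull <- matrix(log(predictRate(fit, design)), n, nb, byrow = TRUE)
  red <- reducedDesign(design, group)
  etaRed <- matrix(log(predictRate(fit, red)), n, nb, byrow = TRUE)

  al <- alignedIndex(design, g$align, alignWindow)
  yA <- alignedValues(y, al$idx)
  predFullA <- exp(alignedValues(etaFull, al$idx))
  predRedA <- exp(alignedValues(etaRed, al$idx))

  cond <- groupConditions(design@trials, group)
  permGroup <- !group %in% c("clicks", "flashes")
  w <- if (weighting && permGroup) conditionWeights(cond) else {
    ok <- if (permGroup) !is.na(cond) else rep(TRUE, n)
    ifelse(ok, 1 / sum(ok), 0)
  }
  sse <- function(predA) {
    e2 <- w * (yA - predA)^2
    colSums(e2, na.rm = TRUE)
  }
  sseRed <- sse(predRedA)
  if (any(sseRed < 1e-12)) stop("degenerate reduced-model SSE")
  sseFull <- sse(predFullA)
  raw <- 100 * (sseRed - sseFull) / sseRed

  # null: permute condition labels (or left/right swap for stimulus groups)
  contrib <- groupContributions(fit, design, group)
  condLevels <- dimnames(contrib)[[2]]
  contribA <- lapply(seq_along(condLevels), function(ci)
    alignedValues(contrib[, ci, ], al$idx))
  etaOtherA <- alignedValues(etaFull, al$idx) -
    if (permGroup) {
      base <- matrix(0, n, length(al$tau))
      for (ci in seq_along(condLevels)) {
        rows <- which(!is.na(cond) & cond == condLevels[ci])
        base[rows, ] <- contribA[[ci]][rows, , drop = FALSE]
      }
      base
    } else contribA[[1]]
  eligible <- which(!is.na(cond))
  nullMat <- withSeed(subSeed(seed, paste0("cpd.", group)), {
    vapply(seq_len(nShuffles), function(s) {
      etaS <- etaOtherA
      if (permGroup) {
        perm <- cond
        perm[eligible] <- cond[sample(eligible)]
        for (ci in seq_along(condLevels)) {
          rows <- which(!is.na(perm) & perm == condLevels[ci])
          etaS[rows, ] <- etaS[rows, , drop = FALSE] +
            contribA[[ci]][rows, , drop = FALSE]
        }
      } else {
        swap <- sample(c(TRUE, FALSE), n, replace = TRUE)
        etaS[!swap, ] <- etaS[!swap, , drop = FALSE] + contribA[[1]][!swap, , drop = FALSE]
        etaS[swap, ] <- etaS[swap, , drop = FALSE] + contribA[[2]][swap, , drop = FALSE]
      }
      100 * (sseRed - sse(exp(etaS))) / sseRed
    }, numeric(length(al$tau)))
  })
  nullMean <- rowMeans(nullMat)
  ciHi <- apply(nullMat, 1, quantile, 0.95, names = FALSE)
  significant <- raw > ciHi
  corrected <- ifelse(significant, raw - nullMean, 0)
  newMetricSeries("cpd", "percent", group, g$align, al$tau, raw, corrected,
                  nullMean, ciHi, significant,
                  extra = list(outlier = any(raw > outlierThreshold,
                                             na.rm = TRUE),
                               nShuffles = as.integer(nShuffles)))
}

# ---- mutual information -----------------------------------------------------

entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Mutual information between spike counts and a covariate group
#'
#' Models the conditional spiking distribution by a doubly stochastic
#' process: parameter vectors are sampled from the fit's normal distribution
#' (covariance = inverse Hessian), passed through the exponential link, and
#' the resulting Poisson count distributions (truncated at `yMax` spikes per
#' 50 ms bin, a 200 Hz cutoff) are averaged over the trials of each
#' condition. MI_t = H(Y_t) - H(Y_t | X) with H(X) from the empirical
#' condition frequencies is reported in bits, with a label-shuffle null and
#' 95% significance mask as for [cpd()]. Restricted to the trial-level groups
#' (reward, reward history, choice).
#'
#' @param fit a [GLMFit-class].
#' @param design the full [DesignMatrix-class].
#' @param group "reward", "rewardHistory" or "choice".
#' @param nSamples parameter samples (default 500).
#' @param nShuffles label shuffles for the null.
#' @param seed integer seed.
#' @param alignWindow aligned window (s).
#' @param yMax count truncation per bin (excess mass pooled into the top bin).
#' @return a `metricSeries` in bits; `extra$HX` is the stimulus entropy
#'   (bits), an upper bound on the raw MI.
#' @export
mutualInformation <- function(fit, design, group, nSamples = 500L,
                              nShuffles = 500L, seed = 1L, alignWindow = NULL,
                              yMax = 10L) {
  if (!group %in% c("reward", "rewardHistory", "choice"))
    stop("MI is defined for the trial-level groups (reward, rewardHistory, choice)")
  g <- covariateGroups()[[group]]
  if (is.null(alignWindow)) alignWindow <- defaultAlignWindow(g$align)
  cond <- groupConditions(design@trials, group)
  eligible <- which(!is.na(cond))
  if (!length(eligible)) stop("no eligible trials for group ", group)
  lev <- sort(unique(cond[eligible]))
  if (any(tabulate(factor(cond[eligible], lev)) == 0))
    stop("condition with zero trials")
  pX <- as.numeric(table(factor(cond[eligible], lev))) / length(eligible)
  HX <- entropy(pX)

  al <- alignedIndex(design, g$align, alignWindow)
  nTau <- length(al$tau)
  n <- nrow(design@trials)
  theta <- c(fit@theta, fit@theta0)
  samples <- withSeed(subSeed(seed, paste0("mi.", group)),
                      rmvn(nSamples, theta, fit@kernelCov))
  Xd <- cbind(design@X, 1)
  nb <- design@nBinsPerTrial

  miFromP <- function(pcond, labels) {
    # pcond: trials x (yMax+1) conditional count distribution
    lab <- factor(labels[eligible], lev)
    pk <- rowsum(pcond[eligible, , drop = FALSE], lab) /
      as.numeric(table(lab))
    HcondY <- sum(pX * apply(pk, 1, entropy))
    pY <- colSums(pX * pk)
    entropy(pY) - HcondY
  }

  raw <- numeric(nTau)
  nullMat <- matrix(NA_real_, nTau, nShuffles)
  perms <- withSeed(subSeed(seed, paste0("mi.null.", group)), {
    lapply(seq_len(nShuffles), function(s) {
      p <- cond; p[eligible] <- cond[sample(eligible)]; p
    })
  })
  for (j in seq_len(nTau)) {
    ok <- which(!is.na(al$idx[, j]))
    rows <- (ok - 1L) * nb + al$idx[ok, j]
    lam <- exp(Xd[rows, , drop = FALSE] %*% t(samples))  # trials x samples
    pcond <- matrix(0, n, yMax + 1L)
    py <- exp(-lam)
    acc <- py
    pcond[ok, 1] <- rowMeans(py)
    for (yv in seq_len(yMax - 1L)) {
      py <- py * lam / yv
      acc <- acc + py
      pcond[ok, yv + 1L] <- rowMeans(py)
    }
    pcond[ok, yMax + 1L] <- pmax(rowMeans(1 - acc), 0)  # pooled tail mass
    # trials without coverage at this lag: drop from the conditional average
    okCond <- cond
    okCond[setdiff(seq_len(n), ok)] <- NA
    covered <- !is.na(okCond)
    if (sum(covered) < length(lev) + 1 ||
        any(tabulate(factor(okCond[covered], lev)) == 0)) {
      raw[j] <- NA
      next
    }
    eligibleJ <- which(covered)
    miJ <- function(labels) {
      lab <- factor(labels[eligibleJ], lev)
      pk <- rowsum(pcond[eligibleJ, , drop = FALSE], lab) / as.numeric(table(lab))
      pY <- colSums(pX * pk)
      entropy(pY) - sum(pX * apply(pk, 1, entropy))
    }
    raw[j] <- miJ(cond)
    for (s in seq_len(nShuffles)) nullMat[j, s] <- miJ(perms[[s]])
  }
  toBits <- 1 / log(2)
  raw <- raw * toBits
  nullMat <- nullMat * toBits
  nullMean <- rowMeans(nullMat)
  ciHi <- apply(nullMat, 1, function(v)
    if (all(is.na(v))) NA_real_ else quantile(v, 0.95, na.rm = TRUE, names = FALSE))
  significant <- !is.na(raw) & raw > ciHi
  corrected <- ifelse(significant, raw - nullMean, 0)
  newMetricSeries("mi", "bits", group, g$align, al$tau, raw, corrected,
                  nullMean, ciHi, significant,
                  extra = list(HX = HX * toBits, base = "bits",
                               nSamples = as.integer(nSamples)))
}

# ---- discriminability -------------------------------------------------------

# unsigned per-column d' between two samples (rows = trials, cols = bins):
# |mu_A - mu_B| / sqrt((var_A + var_B) / 2); NA where the pooled variance
# vanishes
dprimeStat <- function(a, b) {
  muA <- colMeans(a, na.rm = TRUE); muB <- colMeans(b, na.rm = TRUE)
  vA <- apply(a, 2, var, na.rm = TRUE); vB <- apply(b, 2, var, na.rm = TRUE)
  pooled <- (vA + vB) / 2
  out <- abs(muA - muB) / sqrt(pooled)
  out[!is.finite(pooled) | pooled < 1e-12] <- NA
  out
}

#' Shuffle-corrected discriminability (d') between previous wins and losses
#'
#' Per aligned bin, the unsigned d' between the smoothed single-trial firing
#' rates of the two conditions, |mu_A - mu_B| / sqrt((sigma_A^2 +
#' sigma_B^2) / 2). Because the unsigned form inflates small effects, the
#' mean of a label-shuffled null (condition counts preserved) is subtracted;
#' bins outside the one-sided 95% band of the null are flagged significant.
#'
#' @param spikes a [SpikeTrains-class].
#' @param session the [Session-class].
#' @param conditionA,conditionB logical trial filters (defaults: previous win
#'   vs previous loss).
#' @param align,window alignment event and window (s).
#' @param nShuffles label shuffles (default 1000).
#' @param seed integer seed.
#' @return a `metricSeries` (unitless).
#' @export
dprime <- function(spikes, session, conditionA = NULL, conditionB = NULL,
                   align = "start", window = NULL, nShuffles = 1000L,
                   seed = 1L) {
  tr <- trialTable(session)
  if (is.null(conditionA)) conditionA <- tr$prevOutcome == "win"
  if (is.null(conditionB)) conditionB <- tr$prevOutcome == "loss"
  if (is.null(window)) window <- defaultWindow(align)
  if (!any(conditionA) || !any(conditionB)) stop("both conditions must be populated")
  rates <- computePSTH(spikes, session, align = align, window = window,
                       conditionFilter = conditionA | conditionB,
                       perTrial = TRUE)
  isA <- conditionA[conditionA | conditionB]
  dfun <- function(a) dprimeStat(rates[a, , drop = FALSE],
                                 rates[!a, , drop = FALSE])
  raw <- dfun(isA)
  nullMat <- withSeed(subSeed(seed, "dprime"), {
    vapply(seq_len(nShuffles), function(s) dfun(sample(isA)),
           numeric(ncol(rates)))
  })
  nullMean <- rowMeans(nullMat, na.rm = TRUE)
  ciHi <- apply(nullMat, 1, function(v)
    if (all(is.na(v))) NA_real_ else quantile(v, 0.95, na.rm = TRUE, names = FALSE))
  significant <- !is.na(raw) & raw > ciHi
  corrected <- raw - nullMean
  tau <- binGrid(window, 0.05)
  newMetricSeries("dprime", "unitless", "rewardHistory", align, tau, raw,
                  corrected, nullMean, ciHi, significant,
                  extra = list(nShuffles = as.integer(nShuffles)))
}

# ---- cluster averages -------------------------------------------------------

#' Average a metric over the neurons of each cluster
#'
#' Mean and SEM of the corrected metric per cluster and time bin, after
#' exclusion rules (CPD outlier units are dropped when flagged).
#'
#' @param metricList named list of `metricSeries`, one per neuron, on a
#'   common time grid.
#' @param labels cluster labels (or [ClusterResult-class]) covering the
#'   metric neurons.
#' @param excludeOutliers drop units flagged `outlier` (CPD only).
#' @return data.frame (cluster, time, mean, sem, n); SEM is NA for
#'   single-neuron clusters.
#' @export
clusterAverage <- function(metricList, labels, excludeOutliers = TRUE) {
  lab <- asLabels(labels)
  if (!is.null(names(lab)) && !is.null(names(metricList)))
    lab <- lab[names(metricList)]
  if (length(lab) != length(metricList) || any(is.na(lab)))
    stop("labels must cover every metric neuron")
  keep <- rep(TRUE, length(metricList))
  if (excludeOutliers)
    keep <- !vapply(metricList, function(m) isTRUE(m$outlier), TRUE)
  tau <- metricList[[1]]$time
  vals <- do.call(rbind, lapply(metricList, `[[`, "corrected"))
  rows <- list()
  for (cl in sort(unique(lab))) {
    sel <- keep & lab == cl
    if (!any(sel)) stop("empty cluster after exclusions: ", cl)
    v <- vals[sel, , drop = FALSE]
    rows[[length(rows) + 1L]] <- data.frame(
      cluster = cl, time = tau,
      mean = colMeans(v, na.rm = TRUE),
      sem = if (sum(sel) > 1) apply(v, 2, sd, na.rm = TRUE) / sqrt(sum(sel))
            else NA_real_,
      n = sum(sel))
  }
  do.call(rbind, rows)
}
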