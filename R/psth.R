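# Peristimulus time histograms and the two clustering feature spaces.

alignmentTimes <- function(session, align) {
  tr <- trialTable(session)
  switch(align,
    start = rep(0, nrow(tr)),
    exitCenter = tr$tExitCenter,
    choice = tr$tChoice,
    stop("unknown alignment: ", align))
}

defaultWindow <- function(align) {
  if (align == "start") c(-2, 4) else c(-4, 4)
}

#' Trial-averaged (or per-trial) smoothed firing rates
#'
#' Bins spikes at 50 ms on an event-aligned grid ([-2, 4] s for trial-start
#' alignment, [-4, 4] s for exit/choice alignments; inclusive of both
#' endpoints, so the default trial-start grid has 121 bins), converts to Hz,
#' averages over trials and smooths with a centred 250 ms moving average.
#' Bins outside a trial's observed spike window are treated as missing.
#'
#' @param spikes a [SpikeTrains-class].
#' @param session the matching [Session-class].
#' @param align "start", "exitCenter" or "choice".
#' @param window alignment window (s); default depends on `align`.
#' @param conditionFilter optional logical vector over trials (or a function
#'   of the trial table returning one).
#' @param dt bin width (s).
#' @param smoothBins boxcar width in bins (5 = 250 ms).
#' @param perTrial if TRUE return the trials x bins matrix of smoothed rates
#'   instead of the trial average.
#' @return numeric vector (or matrix) of rates in Hz, with the bin centres as
#'   names (or column names); NA where no trial covers a bin.
#' @export
computePSTH <- function(spikes, session, align = "start", window = NULL,
                        conditionFilter = NULL, dt = 0.05, smoothBins = 5L,
                        perTrial = FALSE) {
  if (is.null(window)) window <- defaultWindow(align)
  centers <- binGrid(window, dt)
  at <- alignmentTimes(session, align)
  keep <- rep(TRUE, nTrials(session))
  if (!is.null(conditionFilter)) {
    keep <- if (is.function(conditionFilter)) conditionFilter(trialTable(session))
            else conditionFilter
    keep[is.na(keep)] <- FALSE
  }
  idx <- which(keep)
  if (!length(idx)) stop("empty condition: no trials selected")
  cov <- spikes@coverage
  st <- spikeTimes(spikes)
  rates <- matrix(NA_real_, length(idx), length(centers))
  for (r in seq_along(idx)) {
    i <- idx[r]
    rel <- st[[i]] - at[i]
    covered <- centers - dt / 2 >= cov[1] - at[i] - 1e-9 &
               centers + dt / 2 <= cov[2] - at[i] + 1e-9
    cnt <- binSpikes(rel, centers, dt)
    row <- cnt / dt
    row[!covered] <- NA_real_
    rates[r, ] <- row
  }
  sm <- t(apply(rates, 1, function(x) {
    ok <- !is.na(x)
    if (!any(ok)) return(x)
    x[ok] <- boxcarSmooth(x[ok], smoothBins)
    x
  }))
  colnames(sm) <- signif(centers, 10)
  if (perTrial) return(sm)
  out <- colMeans(sm, na.rm = TRUE)
  out[colSums(!is.na(sm)) == 0] <- NA_real_
  out
}

#' Population PSTH matrix
#'
#' @param spikesList named list of [SpikeTrains-class].
#' @param session the [Session-class].
#' @param ... passed to [computePSTH()].
#' @return matrix, neurons x bins, in Hz.
#' @export
psthMatrix <- function(spikesList, session, ...) {
  rows <- lapply(spikesList, function(s) computePSTH(s, session, ...))
  out <- do.call(rbind, rows)
  rownames(out) <- names(spikesList)
  out
}

zscoreRows <- function(m) {
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  (m - mu) / s
}

pcaReduce <- function(Z, varThreshold) {
  pc <- prcomp(Z, center = TRUE, scale. = FALSE)
  tot <- sum(pc$sdev^2)
  if (tot < 1e-24) {
    # degenerate: all rows identical after centring
    return(list(scores = matrix(0, nrow(Z), 1), 
                loadings = matrix(pc$rotation[, 1], ncol = 1),
                varExplained = c(1, rep(0, length(pc$sdev) - 1)),
                k = 1L, center = pc$center))
  }
  ve <- pc$sdev^2 / tot
  k <- which(cumsum(ve) > varThreshold)[1]
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       loadings = pc$rotation[, seq_len(k), drop = FALSE],
       varExplained = ve, k = as.integer(k), center = pc$center)
}

#' PSTH feature space: z-scored PSTHs projected onto leading PCs
#'
#' Rows are z-scored (constant rows are dropped with a warning), PCA is
#' applied, and the minimal number of components whose cumulative variance
#' exceeds `varThreshold` is retained.
#'
#' @param psths neurons x bins PSTH matrix (see [psthMatrix()]).
#' @param varThreshold cumulative-variance cut (default 0.95).
#' @return a [FeatureSpace-class] with `source = "psth"`.
#' @export
buildPsthFeatureSpace <- function(psths, varThreshold = 0.95) {
  if (nrow(psths) < 2) stop("need at least two neurons")
  keep <- !is.na(colSums(psths))
  psths <- psths[, keep, drop = FALSE]
  sds <- apply(psths, 1, sd)
  flat <- sds < 1e-12
  if (any(flat)) {
    warning("dropping ", sum(flat), " constant (zero-variance) neuron(s): ",
            paste(rownames(psths)[flat], collapse = ", "))
    psths <- psths[!flat, , drop = FALSE]
  }
  Z <- zscoreRows(psths)
  p <- pcaReduce(Z, varThreshold)
  fn <- colnames(Z)
  if (is.null(fn)) fn <- paste0("bin", seq_len(ncol(Z)))
  new("FeatureSpace", scores = p$scores, loadings = p$loadings,
      varExplained = p$varExplained, k = p$k, source = "psth", raw = Z,
      center = p$center, featureNames = fn)
}

conditionalFeatureNames <- function() {
  c("win", "loss", "rv0", "rv6", "rv12", "rv24", "rv48",
    "prevWin", "prevLoss", "left", "right",
    "evl1", "evl2", "evl3", "evl4", "evr1", "evr2", "evr3", "evr4")
}

evBin <- function(ev) findInterval(ev, c(0, 6, 12, 24), rightmost.closed = FALSE)

# window-averaged, marginally z-scored conditional response of one neuron
conditionalFeatures <- function(spikes, session, dt = 0.05) {
  tr <- trialTable(session)
  marg <- computePSTH(spikes, session, align = "start", perTrial = TRUE, dt = dt)
  m <- mean(marg, na.rm = TRUE)
  s <- sd(as.numeric(marg), na.rm = TRUE)
  if (!is.finite(s) || s < 1e-12) s <- 1
  avgZ <- function(align, window, filter) {
    psth <- computePSTH(spikes, session, align = align, window = window,
                        conditionFilter = filter, dt = dt)
    mean((psth - m) / s, na.rm = TRUE)
  }
  done <- tr$outcome != "opt_out"
  f <- setNames(rep(NA_real_, 19), conditionalFeatureNames())
  safeAvg <- function(name, align, window, filter) {
    if (any(filter, na.rm = TRUE))
      f[name] <<- avgZ(align, window, filter)
  }
  safeAvg("win", "choice", c(0, 3), done & tr$outcome == "win")
  safeAvg("loss", "choice", c(0, 3), done & tr$outcome == "loss")
  for (v in c(0, 6, 12, 24, 48))
    safeAvg(paste0("rv", v), "choice", c(0, 3), done & tr$VRewarded == v)
  safeAvg("prevWin", "start", c(-1, 2), tr$prevOutcome == "win")
  safeAvg("prevLoss", "start", c(-1, 2), tr$prevOutcome == "loss")
  safeAvg("left", "exitCenter", c(0, 1.5), done & tr$choice == "left")
  safeAvg("right", "exitCenter", c(0, 1.5), done & tr$choice == "right")
  for (b in 1:4) {
    safeAvg(paste0("evl", b), "choice", c(-1, 0), done & evBin(tr$EVLeft) == b)
    safeAvg(paste0("evr", b), "choice", c(-1, 0), done & evBin(tr$EVRight) == b)
  }
  f
}

#' Conditional feature space: 19 condition-averaged responses per neuron
#'
#' For each neuron, the marginally z-scored conditional PSTH is averaged in
#' the epoch where each variable is most strongly encoded: current outcome
#' (win/loss) and rewarded volume (0/6/12/24/48 ul) over [0, 3] s after reward
#' delivery; previous outcome over [-1, 2] s after trial start; left/right
#' choice over [0, 1.5] s after centre-port exit; and left/right offer
#' expected value, binned on a log-2 scale ([0,6), [6,12), [12,24), [24,48]),
#' over [-1, 0] s before side-port entry. Empty condition cells are imputed
#' with the neuron's marginal mean (zero after z-scoring) and logged. The 19
#' features are then PCA-reduced like the PSTH space.
#'
#' @param spikesList named list of [SpikeTrains-class].
#' @param session the [Session-class].
#' @param varThreshold cumulative-variance cut.
#' @return a [FeatureSpace-class] with `source = "conditional"`.
#' @export
buildConditionalFeatureSpace <- function(spikesList, session,
                                         varThreshold = 0.95) {
  feats <- t(vapply(spikesList, conditionalFeatures, numeric(19),
                    session = session))
  rownames(feats) <- names(spikesList)
  nMiss <- sum(is.na(feats))
  if (nMiss > 0) {
    message("imputing ", nMiss, " empty condition cell(s) with the marginal mean")
    feats[is.na(feats)] <- 0  # marginal mean is 0 on the z-scored scale
  }
  p <- pcaReduce(feats, varThreshold)
  new("FeatureSpace", scores = p$scores, loadings = p$loadings,
      varExplained = p$varExplained, k = p$k, source = "conditional",
      raw = feats, center = p$center,
      featureNames = conditionalFeatureNames())
}
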