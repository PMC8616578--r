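# Impulse streams and basis-convolved design matrices.

designVariants <- function() {
  c("default", "volume", "noExtras", "noHistory", "symmetric")
}

# bin index of time t (s, relative to trial start) on the per-trial grid
timeToBin <- function(t, window, dt) {
  b <- floor((t - window[1]) / dt) + 1L
  as.integer(b)
}

# Build the long event table (variable, trial, bin, amp) for a variant.
# Event variables are binary impulses; prevRewardRate and sessionProgress are
# scalar-amplitude impulses at the trial-start bin.
buildEventTable <- function(session, variant, window, dt) {
  tr <- trialTable(session)
  ev <- eventTimes(session)
  nb <- as.integer(round(diff(window) / dt))
  n <- nrow(tr)
  rows <- list()
  addEvents <- function(variable, trial, time, amp = 1) {
    bin <- timeToBin(time, window, dt)
    ok <- bin >= 1L & bin <= nb & amp != 0
    if (!any(ok)) return()
    rows[[length(rows) + 1L]] <<- data.frame(
      variable = variable, trial = trial[ok], bin = bin[ok], amp = amp[ok])
  }

  stimMap <- c(clickL = "leftClick", clickR = "rightClick",
               flashL = "leftFlash", flashR = "rightFlash")
  for (e in names(stimMap)) {
    sel <- ev$event == e
    if (any(sel)) {
      # binarize: at most one impulse per bin per variable
      key <- unique(data.frame(trial = ev$trial[sel],
                               bin = timeToBin(ev$time[sel], window, dt)))
      addEvents(stimMap[[e]], key$trial, window[1] + (key$bin - 0.5) * dt,
                amp = rep(1, nrow(key)))
    }
  }

  done <- tr$outcome != "opt_out"
  startT <- rep(0, n)
  if (variant == "symmetric") {
    addEvents("choice", tr$index[done] + 1L, tr$tExitCenter[done],
              ifelse(tr$choice[done] == "left", 1, -1))
    addEvents("safety", tr$index[done] + 1L, tr$tExitCenter[done],
              ifelse(tr$choseSafe[done] == "safe", 1, -1))
    addEvents("outcome", tr$index[done] + 1L, tr$tChoice[done],
              ifelse(tr$outcome[done] == "win", 1, -1))
    hw <- tr$prevOutcome %in% c("win", "loss")
    addEvents("prevOutcome", tr$index[hw] + 1L, startT[hw],
              ifelse(tr$prevOutcome[hw] == "win", 1, -1))
    sel <- tr$prevOutcome == "opt_out"
    addEvents("prevOptOut", tr$index[sel] + 1L, startT[sel], rep(1, sum(sel)))
  } else {
    for (side in c("left", "right")) {
      sel <- done & tr$choice == side
      addEvents(paste0(side, "Choice"), tr$index[sel] + 1L,
                tr$tExitCenter[sel], rep(1, sum(sel)))
    }
    for (s in c("safe", "risky")) {
      sel <- done & tr$choseSafe == s
      addEvents(paste0(s, "Choice"), tr$index[sel] + 1L,
                tr$tExitCenter[sel], rep(1, sum(sel)))
    }
    for (o in c("win", "loss")) {
      sel <- tr$outcome == o
      addEvents(o, tr$index[sel] + 1L, tr$tChoice[sel], rep(1, sum(sel)))
    }
    if (variant != "noHistory") {
      prevMap <- c(win = "prevWin", loss = "prevLoss", opt_out = "prevOptOut")
      for (o in names(prevMap)) {
        if (variant == "noExtras" && o == "opt_out") next
        sel <- tr$prevOutcome == o
        addEvents(prevMap[[o]], tr$index[sel] + 1L, startT[sel], rep(1, sum(sel)))
      }
    }
  }
  if (variant != "noExtras") {
    addEvents("prevRewardRate", tr$index + 1L, startT, tr$prevRewardRate)
    addEvents("sessionProgress", tr$index + 1L, startT, tr$sessionProgress)
  }
  if (variant == "volume") {
    addEvents("currentVolume", tr$index + 1L, tr$tChoice, tr$VRewarded)
    prevVol <- c(0, tr$VRewarded[-n])
    addEvents("previousVolume", tr$index + 1L, startT, prevVol)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

variantVariables <- function(variant) {
  base <- taskVariables()
  switch(variant,
    default = base,
    volume = c(base, "currentVolume", "previousVolume"),
    noExtras = setdiff(base, c("prevOptOut", "prevRewardRate", "sessionProgress")),
    noHistory = setdiff(base, c("prevWin", "prevLoss", "prevOptOut")),
    symmetric = c("leftClick", "rightClick", "leftFlash", "rightFlash",
                  "choice", "safety", "outcome", "prevOutcome", "prevOptOut",
                  "prevRewardRate", "sessionProgress"),
    stop("unknown design variant: ", variant))
}

# Convolve event impulses with the basis, trial by trial (causal in lag,
# no leakage across trial windows).
convolveEvents <- function(events, variables, basis, n, nb) {
  Phi <- basis@evaluation
  M <- ncol(Phi)
  nLag <- nrow(Phi)
  X <- matrix(0, n * nb, length(variables) * M)
  colnames(X) <- paste(rep(variables, each = M), colnames(Phi), sep = ".")
  for (vi in seq_along(variables)) {
    sel <- events$variable == variables[vi]
    if (!any(sel)) next
    e <- events[sel, , drop = FALSE]
    cols <- ((vi - 1) * M + 1):(vi * M)
    for (tr in unique(e$trial)) {
      et <- e[e$trial == tr, , drop = FALSE]
      s <- numeric(nb)
      s[et$bin] <- et$amp
      lagged <- embed(c(numeric(nLag - 1), s), nLag)  # nb x nLag, col j = s[t-j+1]
      off <- (tr - 1) * nb
      X[(off + 1):(off + nb), cols] <- lagged %*% Phi
    }
  }
  X
}

#' Build the basis-convolved design matrix for a session
#'
#' Emits one impulse stream per task variable on the concatenated per-trial
#' 50 ms grid (stimuli at their own event times; choice variables at
#' centre-port exit; win/loss at side-port entry; history, reward-rate and
#' session-progress impulses at trial start), then convolves each stream
#' causally with every basis function over 4 s of lag. The default variant has
#' the 15 task variables; `volume` adds current/previous rewarded volume,
#' `noExtras` drops previous-opt-out, previous-reward-rate and
#' session-progress, `noHistory` drops the previous-outcome variables, and
#' `symmetric` collapses each condition pair to a single +1/-1 stream.
#'
#' @param session a [Session-class].
#' @param variant one of `designVariants()`.
#' @param window per-trial window (s, relative to trial start).
#' @param basis a [buildBasis()] basis.
#' @return a [DesignMatrix-class].
#' @export
buildDesignMatrix <- function(session, variant = "default",
                              window = c(-2, 6), basis = buildBasis()) {
  if (!variant %in% designVariants())
    stop("unknown design variant: ", variant)
  dt <- basis@dt
  nb <- as.integer(round(diff(window) / dt))
  n <- nTrials(session)
  variables <- variantVariables(variant)
  events <- buildEventTable(session, variant, window, dt)
  X <- convolveEvents(events, variables, basis, n, nb)
  new("DesignMatrix", X = X, variables = variables, basis = basis,
      events = events, trialIndex = rep(seq_len(n), each = nb),
      binTime = rep(window[1] + (seq_len(nb) - 0.5) * dt, times = n),
      window = window, nBinsPerTrial = nb, variant = variant,
      trials = trialTable(session))
}

# Rebuild a DesignMatrix from a modified event table (reduced designs and
# label shuffles reuse this).
rebuildDesign <- function(design, events) {
  n <- length(unique(design@trialIndex))
  X <- convolveEvents(events, design@variables, design@basis, n,
                      design@nBinsPerTrial)
  initialize(design, X = X, events = events)
}
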