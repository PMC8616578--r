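# Synthetic cued-gamble sessions and ground-truth Poisson-GLM units.

#' Task configuration for the synthetic cued-gamble session generator
#'
#' Defaults reproduce the task structure: a centre poke starts the trial,
#' Poisson click trains from both speakers convey the water volume baited at
#' each side port, and after a 0-350 ms pre-flash interval 20 ms light
#' flashes on a 250 ms grid convey reward probability, until a go cue ~2.5-3 s
#' after trial start (minus a 0-500 ms post-flash delay). One side is always
#' safe (p = 1), the other risky (p < 1). The click-rate/volume map and the
#' choice policy are configurable conveniences, not models of the animal.
#'
#' @param nTrials number of trials.
#' @param volumes water volumes (ul) offered on each side.
#' @param probLevels reward-probability levels; the risky side draws from the
#'   levels below 1, the safe side has p = 1.
#' @param pOptOut probability that a trial ends in an opt-out.
#' @param preFlashRange,postFlashRange uniform ranges (s) for the pre-flash
#'   interval and post-flash delay.
#' @param cuePeriodRange uniform range (s) of the trial-start-to-go interval.
#' @param flashSpacing,flashDuration flash grid spacing and duration (s).
#' @param clickRateMap named numeric, click rate (Hz) per volume (ul). The
#'   default is linear in volume with 40 Hz at 48 ul.
#' @param reactionRange uniform range (s) from go cue to centre-port exit.
#' @param movementTimeRange uniform range (s) from centre-port exit to
#'   side-port entry.
#' @param itiRange uniform inter-trial interval range (s).
#' @param choiceBeta slope (1/ul) of the logistic choice rule on the
#'   left-right expected-value difference.
#' @param seed default seed used by [generateSession()] when none is given.
#' @return a validated list of class `taskConfig`.
#' @export
taskConfig <- function(nTrials = 400L,
                       volumes = c(6, 12, 24, 48),
                       probLevels = c(0, 0.25, 0.5, 0.75, 1),
                       pOptOut = 0.1,
                       preFlashRange = c(0, 0.35),
                       postFlashRange = c(0, 0.5),
                       cuePeriodRange = c(2.5, 3),
                       flashSpacing = 0.25,
                       flashDuration = 0.02,
                       clickRateMap = NULL,
                       reactionRange = c(0.1, 0.3),
                       movementTimeRange = c(0.2, 0.5),
                       itiRange = c(2, 4),
                       choiceBeta = 0.15,
                       seed = 1L) {
  if (nTrials < 1) stop("nTrials must be positive")
  if (any(probLevels < 0 | probLevels > 1)) stop("probability levels must lie in [0, 1]")
  if (pOptOut < 0 || pOptOut > 1) stop("pOptOut must lie in [0, 1]")
  if (is.null(clickRateMap)) {
    clickRateMap <- setNames(40 * volumes / max(volumes), as.character(volumes))
  }
  stopifnot(all(as.character(volumes) %in% names(clickRateMap)),
            flashSpacing > 0, flashDuration > 0,
            diff(cuePeriodRange) >= 0, cuePeriodRange[1] > 0)
  structure(list(nTrials = as.integer(nTrials), volumes = volumes,
                 probLevels = probLevels, pOptOut = pOptOut,
                 preFlashRange = preFlashRange, postFlashRange = postFlashRange,
                 cuePeriodRange = cuePeriodRange, flashSpacing = flashSpacing,
                 flashDuration = flashDuration, clickRateMap = clickRateMap,
                 reactionRange = reactionRange,
                 movementTimeRange = movementTimeRange, itiRange = itiRange,
                 choiceBeta = choiceBeta, seed = as.integer(seed)),
            class = "taskConfig")
}

runifRange <- function(n, range) runif(n, range[1], range[2])

#' Generate a synthetic session
#'
#' Draws trial timelines, stimuli, choices and outcomes. Click trains are
#' Poisson processes whose rate maps the offered volume; flashes occupy a
#' 250 ms grid, each slot emitting with probability equal to the side's
#' reward probability. Outcomes are independent across trials with
#' P(win | chosen side) equal to that side's probability. History fields are
#' computed strictly from earlier trials.
#'
#' @param config a [taskConfig()].
#' @param seed integer seed (defaults to `config$seed`).
#' @return a [Session-class].
#' @export
generateSession <- function(config = taskConfig(), seed = config$seed) {
  stopifnot(inherits(config, "taskConfig"))
  n <- config$nTrials
  withSeed(subSeed(seed, "session"), {
    iti <- runifRange(n, config$itiRange)
    cueLen <- runifRange(n, config$cuePeriodRange)
    preFlash <- runifRange(n, config$preFlashRange)
    postFlash <- runifRange(n, config$postFlashRange)
    reaction <- runifRange(n, config$reactionRange)
    movement <- runifRange(n, config$movementTimeRange)
    drawFrom <- function(vals) vals[sample.int(length(vals), n, replace = TRUE)]
    VLeft <- drawFrom(config$volumes)
    VRight <- drawFrom(config$volumes)
    risky <- drawFrom(c("left", "right"))
    riskyLevels <- config$probLevels[config$probLevels < 1]
    pRisky <- if (length(riskyLevels)) drawFrom(riskyLevels) else rep(1, n)
    pLeft <- ifelse(risky == "left", pRisky, 1)
    pRight <- ifelse(risky == "right", pRisky, 1)
    EVLeft <- pLeft * VLeft
    EVRight <- pRight * VRight
    pChooseLeft <- 1 / (1 + exp(-config$choiceBeta * (EVLeft - EVRight)))
    choice <- ifelse(runif(n) < pChooseLeft, "left", "right")
    optOut <- runif(n) < config$pOptOut
    pChosen <- ifelse(choice == "left", pLeft, pRight)
    win <- runif(n) < pChosen
    outcome <- ifelse(optOut, "opt_out", ifelse(win, "win", "loss"))
    choiceLab <- ifelse(optOut, NA_character_, choice)
    choseSafe <- ifelse(optOut, NA_character_,
                        ifelse(choice == risky, "risky", "safe"))
    VChosen <- ifelse(choice == "left", VLeft, VRight)
    VRewarded <- ifelse(outcome == "win", VChosen, 0)

    tStart <- cumsum(iti)
    tGo <- cueLen
    tExit <- tGo + reaction
    tChoice <- tExit + movement

    prevOutcome <- c("none", outcome[-n])
    prevRewardRate <- c(0, cumsum(VRewarded)[-n] / seq_len(n - 1))
    sessionProgress <- if (n > 1) (seq_len(n) - 1) / (n - 1) else 0

    events <- vector("list", n)
    for (i in seq_len(n)) {
      ev <- list()
      for (side in c("left", "right")) {
        rate <- config$clickRateMap[[as.character(if (side == "left") VLeft[i] else VRight[i])]]
        nClicks <- rpois(1, rate * cueLen[i])
        if (nClicks > 0)
          ev[[paste0("click", toupper(substr(side, 1, 1)))]] <-
            sort(runif(nClicks, 0, cueLen[i]))
        slots <- seq(preFlash[i], max(preFlash[i], cueLen[i] - postFlash[i]),
                     by = config$flashSpacing)
        p <- if (side == "left") pLeft[i] else pRight[i]
        lit <- slots[runif(length(slots)) < p]
        if (length(lit))
          ev[[paste0("flash", toupper(substr(side, 1, 1)))]] <- lit
      }
      if (length(ev)) {
        events[[i]] <- data.frame(
          trial = i,
          event = rep(names(ev), lengths(ev)),
          time = unlist(ev, use.names = FALSE))
      }
    }
    events <- do.call(rbind, events[!vapply(events, is.null, TRUE)])
    rownames(events) <- NULL

    trials <- data.frame(
      index = seq_len(n) - 1L, tStart = tStart, tGo = tGo,
      tExitCenter = tExit, tChoice = tChoice, choice = choiceLab,
      choseSafe = choseSafe, outcome = outcome,
      VLeft = VLeft, VRight = VRight, pLeft = pLeft, pRight = pRight,
      EVLeft = EVLeft, EVRight = EVRight, VRewarded = VRewarded,
      prevOutcome = prevOutcome, prevRewardRate = prevRewardRate,
      sessionProgress = sessionProgress, stringsAsFactors = FALSE)

    new("Session", trials = trials, events = events,
        config = unclass(config), seed = as.integer(seed))
  })
}

# ---- ground-truth neurons --------------------------------------------------

# Weight vector placing mass `amp` (kernel peak height, log-rate units) on a
# single basis function. Columns peak at 1, so the weight equals the peak.
pointWeight <- function(basis, j, amp) {
  w <- numeric(ncol(basis@evaluation))
  w[j] <- amp
  w
}

# Weight for variables whose impulse stream is sustained (clicks): scale so
# that a saturated stream contributes ~ampEta to the log rate.
sustainedWeight <- function(basis, j, ampEta) {
  s <- sum(basis@evaluation[, j])
  pointWeight(basis, j, ampEta / s)
}

archetypeNames <- function() {
  c("trialStartBurst", "cuePersistent", "preChoiceRewardHistory",
    "choiceLocked", "rewardLocked")
}

archetypeWeights <- function(basis, archetype) {
  # Basis columns 1:2 are the exponentials (25/50 ms), 3:9 the cosines with
  # peak lags log-spaced from 25 ms to 2 s (columns 3..9 peak near
  # 0.025, 0.08, 0.17, 0.35, 0.7, 1.3, 2 s).
  # Kernels use the broader mid-lag cosines (peaks ~0.1-0.5 s, spanning
  # several bins) so the planted responses have the few-hundred-ms widths of
  # real PSTH transients; only choiceLocked adds a fast exponential edge.
  burst <- function(amp) pointWeight(basis, 5, amp) + pointWeight(basis, 6, 0.8 * amp)
  w <- list()
  switch(archetype,
    trialStartBurst = {
      # bursts after the centre poke irrespective of history: equal weight on
      # every reward-history condition, short latency
      for (v in c("prevWin", "prevLoss", "prevOptOut")) w[[v]] <- burst(1.1)
      w$win <- pointWeight(basis, 7, 0.3)
      w$loss <- pointWeight(basis, 7, 0.3)
      w$leftChoice <- pointWeight(basis, 5, 0.25)
      w$rightChoice <- pointWeight(basis, 5, 0.25)
    },
    cuePersistent = {
      # sustained cue-period activity driven by the click trains
      w$leftClick <- sustainedWeight(basis, 8, 1.1)
      w$rightClick <- sustainedWeight(basis, 8, 1.1)
      w$win <- pointWeight(basis, 7, 0.35)
      w$loss <- pointWeight(basis, 7, 0.2)
      w$leftChoice <- pointWeight(basis, 5, 0.3)
      w$rightChoice <- pointWeight(basis, 5, 0.3)
    },
    preChoiceRewardHistory = {
      # early post-start history response plus a prevWin-specific late
      # component (~2 s lag) that re-emerges just before the choice
      w$prevWin <- burst(0.7) + pointWeight(basis, 9, 1.0)
      w$prevLoss <- burst(0.7)
      w$win <- pointWeight(basis, 7, 1.2)
      w$loss <- pointWeight(basis, 7, 0.4)
      w$leftChoice <- burst(0.5)
      w$rightChoice <- burst(0.5)
    },
    choiceLocked = {
      # sharp transient at centre-port exit, stronger for the preferred side
      w$leftChoice <- pointWeight(basis, 1, 1.2) + burst(0.9)
      w$rightChoice <- pointWeight(basis, 1, 0.6) + burst(0.45)
      w$win <- pointWeight(basis, 7, 0.3)
      w$loss <- pointWeight(basis, 7, 0.3)
    },
    rewardLocked = {
      # slow post-outcome response, much larger after wins
      w$win <- pointWeight(basis, 7, 1.5)
      w$loss <- pointWeight(basis, 7, 0.5)
      w$leftChoice <- pointWeight(basis, 5, 0.25)
      w$rightChoice <- pointWeight(basis, 5, 0.25)
    },
    stop("unknown archetype: ", archetype))
  w
}

#' Create ground-truth neurons from five planted response archetypes
#'
#' Archetypes mimic canonical profiles: a trial-start burst, persistent
#' cue-period activity, a pre-choice unit whose previous-win response
#' re-emerges late in the trial (the planted positive for the reward-history
#' analyses), a choice-locked unit, and a reward-locked unit. Every archetype
#' carries win/loss and choice kernels; only `preChoiceRewardHistory` has a
#' reward-history kernel that differs between previous wins and losses.
#'
#' @param config a [taskConfig()] (kept for signature symmetry; rates do not
#'   depend on it).
#' @param nPerArchetype neurons per archetype (>= 1).
#' @param seed integer seed for per-neuron jitter.
#' @param jitter SD of the multiplicative log-normal weight jitter that
#'   individuates neurons within an archetype.
#' @param basis the [buildBasis()] the weights are expressed in.
#' @param baseRateRange uniform range (Hz) of background rates.
#' @return list of [GroundTruthNeuron-class] objects.
#' @export
makeArchetypes <- function(config = taskConfig(), nPerArchetype = 1L,
                           seed = 1L, jitter = 0.15, basis = buildBasis(),
                           baseRateRange = c(3, 8)) {
  if (nPerArchetype < 1) stop("need at least one neuron per archetype")
  dt <- basis@dt
  withSeed(subSeed(seed, "neurons"), {
    out <- list()
    for (arch in archetypeNames()) {
      for (i in seq_len(nPerArchetype)) {
        w <- archetypeWeights(basis, arch)
        w <- lapply(w, function(x) x * exp(rnorm(1, 0, jitter)))
        rate <- runifRange(1, baseRateRange)
        out[[length(out) + 1L]] <- new("GroundTruthNeuron",
          unitId = sprintf("%s_%02d", arch, i), archetype = arch,
          weights = w, background = log(rate * dt))
      }
    }
    out
  })
}

#' Constant-rate Poisson unit (all kernels zero)
#'
#' @param rateHz firing rate in Hz.
#' @param unitId identifier.
#' @param dt bin width (s).
#' @return a [GroundTruthNeuron-class].
#' @export
constantNeuron <- function(rateHz = 5, unitId = "constant", dt = 0.05) {
  new("GroundTruthNeuron", unitId = unitId, archetype = "constant",
      weights = list(), background = log(rateHz * dt))
}

#' Simulate spikes from a ground-truth neuron
#'
#' Applies the generative encoding model: the session's design matrix is
#' combined with the neuron's kernel weights and background, exponentiated to
#' a rate, and counts are drawn from a Poisson distribution per 50 ms bin
#' (spike times uniform within their bin). The simulation window extends past
#' the model window so that choice-aligned analyses have coverage.
#'
#' @param session a [Session-class].
#' @param neuron a [GroundTruthNeuron-class].
#' @param seed integer seed.
#' @param window simulation window (s, relative to trial start).
#' @param countWindow window of the stored binned counts (the model window).
#' @param basis kernel basis; must match the one the weights are expressed in.
#' @param maxCountPerBin guard against run-away rates: a mean above this many
#'   counts per bin aborts with an error rather than clipping silently.
#' @param design optional precomputed generative [DesignMatrix-class] on
#'   `window` (avoids rebuilding it per unit when simulating populations).
#' @return a [SpikeTrains-class].
#' @export
simulateSpikes <- function(session, neuron, seed = 1L, window = c(-2.05, 8.05),
                           countWindow = c(-2, 6), basis = buildBasis(),
                           maxCountPerBin = 50, design = NULL) {
  if (is.null(design))
    design <- buildDesignMatrix(session, variant = "default", window = window,
                                basis = basis)
  stopifnot(all(abs(design@window - window) < 1e-9))
  M <- ncol(basis@evaluation)
  theta <- numeric(ncol(design@X))
  for (v in names(neuron@weights)) {
    i <- match(v, design@variables)
    if (is.na(i)) stop("kernel for unknown variable: ", v)
    theta[((i - 1) * M + 1):(i * M)] <- neuron@weights[[v]]
  }
  eta <- as.numeric(design@X %*% theta) + neuron@background
  if (max(eta) > log(maxCountPerBin))
    stop("rate overflow: peak mean count per bin ", signif(exp(max(eta)), 3),
         " exceeds ", maxCountPerBin, "; kernel weights too large")
  dt <- basis@dt
  nb <- design@nBinsPerTrial
  n <- nTrials(session)
  withSeed(subSeed(seed, paste0("spikes.", neuron@unitId)), {
    counts <- matrix(rpois(length(eta), exp(eta)), nrow = n, ncol = nb,
                     byrow = TRUE)
    centers <- window[1] + dt / 2 + (seq_len(nb) - 1) * dt
    st <- lapply(seq_len(n), function(i) {
      k <- counts[i, ]
      if (sum(k) == 0) return(numeric(0))
      sort(rep(centers, k) + (runif(sum(k)) - 0.5) * dt)
    })
    keep <- centers > countWindow[1] & centers < countWindow[2]
    new("SpikeTrains", unitId = neuron@unitId, spikeTimes = st,
        counts = counts[, keep, drop = FALSE], binCenters = centers[keep],
        window = countWindow, coverage = window, truth = neuron)
  })
}

#' Simulate a population of ground-truth neurons
#'
#' @param session a [Session-class].
#' @param neurons list of [GroundTruthNeuron-class].
#' @param seed integer seed; each unit gets its own substream.
#' @param ... passed to [simulateSpikes()].
#' @return named list of [SpikeTrains-class].
#' @export
simulatePopulation <- function(session, neurons, seed = 1L,
                               window = c(-2.05, 8.05), basis = buildBasis(), ...) {
  design <- buildDesignMatrix(session, variant = "default", window = window,
                              basis = basis)
  out <- lapply(neurons, function(nr)
    simulateSpikes(session, nr, seed = seed, window = window, basis = basis,
                   design = design, ...))
  names(out) <- vapply(neurons, function(nr) nr@unitId, "")
  out
}
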