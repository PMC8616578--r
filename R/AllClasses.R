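#' @import methods
#' @importFrom stats rnorm rpois runif rbinom quantile sd var median mahalanobis
#'   dist kmeans prcomp dpois lm anova pf pt wilcox.test binom.test t.test
#'   qnorm pnorm ks.test setNames aggregate complete.cases coef optim rexp
#' @importFrom utils head tail read.csv write.csv
#' @importFrom grDevices pdf dev.off
NULL

# ---- central S4 containers -------------------------------------------------

#' Session: behavioural truth for one synthetic (or loaded) session
#'
#' Ordered trials with event times, stimuli, choices and outcomes. All times
#' are in seconds. Within-trial event times (`go`, `exitCenter`, `choice`,
#' click and flash times) are stored relative to trial start; `tStart` is the
#' absolute session time of the centre poke.
#'
#' @slot trials data.frame with one row per trial (index, tStart, tGo,
#'   tExitCenter, tChoice, choice, choseSafe, outcome, VLeft, VRight, pLeft,
#'   pRight, EVLeft, EVRight, VRewarded, prevOutcome, prevRewardRate,
#'   sessionProgress).
#' @slot events long data.frame (trial, event, time) holding click and flash
#'   times per side, relative to trial start.
#' @slot config the [taskConfig()] list used to generate the session.
#' @slot seed integer seed the session was generated from.
#' @export
setClass("Session",
  representation(trials = "data.frame", events = "data.frame",
                 config = "list", seed = "integer"))

setValidity("Session", function(object) {
  tr <- object@trials
  need <- c("index", "tStart", "tGo", "tExitCenter", "tChoice", "choice",
            "outcome", "VLeft", "VRight", "pLeft", "pRight", "EVLeft",
            "EVRight", "VRewarded", "prevOutcome", "prevRewardRate",
            "sessionProgress", "choseSafe")
  miss <- setdiff(need, names(tr))
  if (length(miss)) return(paste("missing trial columns:", paste(miss, collapse = ", ")))
  bad <- with(tr, !(0 < tGo & tGo < tExitCenter & tExitCenter < tChoice))
  if (any(bad)) return("event times must satisfy start < go < exitCenter < choice")
  if (any(abs(tr$EVLeft - tr$pLeft * tr$VLeft) > 1e-9)) return("EVLeft != pLeft * VLeft")
  if (any(abs(tr$EVRight - tr$pRight * tr$VRight) > 1e-9)) return("EVRight != pRight * VRight")
  TRUE
})

#' SpikeTrains: spikes of a single unit over the trials of a session
#'
#' @slot unitId character identifier.
#' @slot spikeTimes list (one element per trial) of spike times relative to
#'   trial start, covering at least the binning window.
#' @slot counts integer matrix, trials x bins, of 50 ms spike counts on the
#'   model window around trial start.
#' @slot binCenters bin centre times (s, relative to trial start).
#' @slot window length-2 numeric, the count window (default c(-2, 6)).
#' @slot coverage length-2 numeric, the window over which spike times are
#'   observed (at least `window`; realigned analyses treat bins outside it
#'   as missing rather than silent).
#' @slot truth the [GroundTruthNeuron-class] that generated the unit, or NULL.
#' @export
setClass("SpikeTrains",
  representation(unitId = "character", spikeTimes = "list", counts = "matrix",
                 binCenters = "numeric", window = "numeric",
                 coverage = "numeric", truth = "ANY"))

setValidity("SpikeTrains", function(object) {
  if (nrow(object@counts) != length(object@spikeTimes))
    return("counts rows must match spikeTimes length")
  if (any(object@counts < 0) || any(object@counts != round(object@counts)))
    return("counts must be non-negative integers")
  if (ncol(object@counts) != length(object@binCenters))
    return("counts columns must match binCenters")
  TRUE
})

#' GroundTruthNeuron: a planted Poisson-GLM unit
#'
#' @slot unitId character identifier.
#' @slot archetype one of the five planted response archetypes.
#' @slot weights named list mapping task-variable name to a basis-weight
#'   vector (length = number of basis functions).
#' @slot background log mean count per 50 ms bin (theta0).
#' @export
setClass("GroundTruthNeuron",
  representation(unitId = "character", archetype = "character",
                 weights = "list", background = "numeric"))

setValidity("GroundTruthNeuron", function(object) {
  if (!all(vapply(object@weights, function(w) all(is.finite(w)), TRUE)))
    return("kernel weights must be finite")
  unknown <- setdiff(names(object@weights), taskVariables())
  if (length(unknown)) return(paste("unknown task variables:", paste(unknown, collapse = ", ")))
  TRUE
})

#' BasisSet: temporal basis for GLM kernels
#'
#' Seven log-raised-cosine bumps spread log-linearly over 4 s of lag, plus two
#' decaying exponentials peaking in the first two 50 ms lag bins.
#'
#' @slot dt bin width (s).
#' @slot support kernel support (s).
#' @slot evaluation matrix, lag bins x basis functions, each column peaking at 1.
#' @slot params list with the log-stretch `a`, centres `b`, peak lags, and
#'   exponential decay constants.
#' @export
setClass("BasisSet",
  representation(dt = "numeric", support = "numeric", evaluation = "matrix",
                 params = "list"))

setValidity("BasisSet", function(object) {
  ev <- object@evaluation
  if (nrow(ev) != round(object@support / object@dt))
    return("evaluation rows must equal support/dt lag bins")
  if (any(ev < -1e-12) || any(ev > 1 + 1e-12))
    return("basis functions must lie in [0, 1]")
  TRUE
})

#' DesignMatrix: basis-convolved task-variable regressors
#'
#' Rows run over the concatenated per-trial 50 ms grid; columns are the
#' task variables convolved with each basis function.
#'
#' @slot X numeric matrix, time x (variables * basis functions).
#' @slot variables character vector of task-variable names.
#' @slot basis the [BasisSet-class] used for convolution.
#' @slot events data.frame (variable, trial, bin, amp) of the impulse streams
#'   before convolution; `bin` indexes the per-trial grid.
#' @slot trialIndex integer trial id per row.
#' @slot binTime time (s, relative to trial start) per row.
#' @slot window per-trial window (s).
#' @slot nBinsPerTrial bins per trial.
#' @slot variant design variant identifier.
#' @slot trials copy of the session trial table (condition labels for
#'   reduced/shuffled designs).
#' @export
setClass("DesignMatrix",
  representation(X = "matrix", variables = "character", basis = "BasisSet",
                 events = "data.frame", trialIndex = "integer",
                 binTime = "numeric", window = "numeric",
                 nBinsPerTrial = "integer", variant = "character",
                 trials = "data.frame"))

setValidity("DesignMatrix", function(object) {
  if (ncol(object@X) != length(object@variables) * ncol(object@basis@evaluation))
    return("X columns must equal variables x basis functions")
  if (nrow(object@X) != length(object@trialIndex))
    return("trialIndex must have one entry per design row")
  TRUE
})

#' GLMFit: fitted L2-penalised Poisson encoding model
#'
#' @slot theta kernel weights, named `variable.b<j>`.
#' @slot theta0 background log mean count per bin.
#' @slot xi L2 penalty.
#' @slot nll named numeric: per-bin mean negative log-likelihood on the data
#'   splits that were evaluated (train, and where applicable val / test).
#' @slot r2Test held-out proportion of variance explained (may be negative,
#'   NA when no test partition was evaluated).
#' @slot kernelCov parameter covariance (inverse Hessian at the optimum).
#' @slot converged logical.
#' @slot variables task-variable names of the design the model was fit to.
#' @slot basis the kernel basis.
#' @export
setClass("GLMFit",
  representation(theta = "numeric", theta0 = "numeric", xi = "numeric",
                 nll = "numeric", r2Test = "numeric", kernelCov = "matrix",
                 converged = "logical", variables = "character",
                 basis = "BasisSet"))

setValidity("GLMFit", function(object) {
  if (!all(is.finite(object@theta)) || !is.finite(object@theta0))
    return("theta must be finite")
  if (object@xi < 0) return("xi must be non-negative")
  TRUE
})

#' FeatureSpace: per-neuron feature vectors with PCA metadata
#'
#' @slot scores matrix, neurons x retained components.
#' @slot loadings PCA loadings (features x retained components).
#' @slot varExplained per-component variance fractions (all components).
#' @slot k number of retained components (cumulative variance > threshold).
#' @slot source "psth" or "conditional".
#' @slot raw the pre-PCA feature matrix (z-scored).
#' @slot center PCA column centres.
#' @slot featureNames names of the pre-PCA features.
#' @export
setClass("FeatureSpace",
  representation(scores = "matrix", loadings = "matrix",
                 varExplained = "numeric", k = "integer", source = "character",
                 raw = "matrix", center = "numeric", featureNames = "character"))

#' ClusterResult: a k-means partition of a feature space
#'
#' @slot labels integer cluster label per neuron.
#' @slot centroids K x feature matrix.
#' @slot K number of clusters.
#' @slot inertia total within-cluster sum of squares.
#' @slot seed RNG seed used.
#' @slot replicates number of random restarts.
#' @export
setClass("ClusterResult",
  representation(labels = "integer", centroids = "matrix", K = "integer",
                 inertia = "numeric", seed = "integer", replicates = "integer"))

setValidity("ClusterResult", function(object) {
  if (any(is.na(object@labels))) return("every neuron must be labelled")
  if (max(object@labels) > object@K) return("labels exceed K")
  TRUE
})

# ---- show methods ----------------------------------------------------------

setMethod("show", "Session", function(object) {
  tr <- object@trials
  cat(sprintf("Session: %d trials (%d win, %d loss, %d opt-out)\n",
              nrow(tr), sum(tr$outcome == "win"), sum(tr$outcome == "loss"),
              sum(tr$outcome == "opt_out")))
  cat(sprintf("  volumes %s ul, opt-out rate %.2f, seed %d\n",
              paste(sort(unique(c(tr$VLeft, tr$VRight))), collapse = "/"),
              mean(tr$outcome == "opt_out"), object@seed))
})

setMethod("show", "SpikeTrains", function(object) {
  cat(sprintf("SpikeTrains '%s': %d trials, mean rate %.2f Hz on [%g, %g] s\n",
              object@unitId, nrow(object@counts),
              mean(object@counts) / diff(object@binCenters[1:2]),
              object@window[1], object@window[2]))
})

setMethod("show", "BasisSet", function(object) {
  cat(sprintf("BasisSet: %d functions (%d raised cosines + %d exponentials), dt %g s, support %g s\n",
              ncol(object@evaluation), length(object@params$peaks),
              length(object@params$taus), object@dt, object@support))
})

setMethod("show", "DesignMatrix", function(object) {
  cat(sprintf("DesignMatrix ('%s'): %d variables x %d basis = %d regressors, %d bins (%d trials x %d)\n",
              object@variant, length(object@variables),
              ncol(object@basis@evaluation), ncol(object@X), nrow(object@X),
              length(unique(object@trialIndex)), object@nBinsPerTrial))
})

setMethod("show", "GLMFit", function(object) {
  cat(sprintf("GLMFit: %d kernel weights + background %.3f, xi %.3g, converged %s\n",
              length(object@theta), object@theta0, object@xi, object@converged))
  if (!is.na(object@r2Test)) cat(sprintf("  held-out R2 %.3f\n", object@r2Test))
})

setMethod("show", "FeatureSpace", function(object) {
  cat(sprintf("FeatureSpace (%s): %d neurons, %d features -> %d PCs (%.1f%% variance)\n",
              object@source, nrow(object@scores), length(object@featureNames),
              object@k, 100 * sum(object@varExplained[seq_len(object@k)])))
})

setMethod("show", "ClusterResult", function(object) {
  cat(sprintf("ClusterResult: K = %d over %d points, sizes %s\n", object@K,
              length(object@labels),
              paste(tabulate(object@labels, object@K), collapse = "/")))
})

# ---- accessors -------------------------------------------------------------

#' @rdname Session-class
#' @param object,x a Session
#' @export
setGeneric("trialTable", function(object) standardGeneric("trialTable"))

#' @rdname Session-class
#' @export
setMethod("trialTable", "Session", function(object) object@trials)

#' @rdname Session-class
#' @export
setGeneric("eventTimes", function(object) standardGeneric("eventTimes"))

#' @rdname Session-class
#' @export
setMethod("eventTimes", "Session", function(object) object@events)

#' @rdname Session-class
#' @export
setGeneric("nTrials", function(object) standardGeneric("nTrials"))

#' @rdname Session-class
#' @export
setMethod("nTrials", "Session", function(object) nrow(object@trials))

#' @rdname SpikeTrains-class
#' @param object a SpikeTrains
#' @export
setGeneric("spikeCounts", function(object) standardGeneric("spikeCounts"))

#' @rdname SpikeTrains-class
#' @export
setMethod("spikeCounts", "SpikeTrains", function(object) object@counts)

#' @rdname SpikeTrains-class
#' @export
setGeneric("spikeTimes", function(object) standardGeneric("spikeTimes"))

#' @rdname SpikeTrains-class
#' @export
setMethod("spikeTimes", "SpikeTrains", function(object) object@spikeTimes)

#' @rdname SpikeTrains-class
#' @export
setGeneric("unitId", function(object) standardGeneric("unitId"))

#' @rdname SpikeTrains-class
#' @export
setMethod("unitId", "SpikeTrains", function(object) object@unitId)

#' @rdname DesignMatrix-class
#' @param object a DesignMatrix or GLMFit
#' @export
setGeneric("designMatrix", function(object) standardGeneric("designMatrix"))

#' @rdname DesignMatrix-class
#' @export
setMethod("designMatrix", "DesignMatrix", function(object) object@X)

#' @rdname DesignMatrix-class
#' @export
setGeneric("taskVariableNames", function(object) standardGeneric("taskVariableNames"))

#' @rdname DesignMatrix-class
#' @export
setMethod("taskVariableNames", "DesignMatrix", function(object) object@variables)

#' Reconstruct fitted kernels on the lag grid
#'
#' Linearly combines the basis functions with the fitted weights, one kernel
#' per task variable (k_s(tau) = sum_j theta_s^(j) phi_j(tau)).
#'
#' @param object a [GLMFit-class]
#' @return matrix, lag bins x task variables
#' @export
setGeneric("kernels", function(object) standardGeneric("kernels"))

#' @rdname kernels
#' @export
setMethod("kernels", "GLMFit", function(object) {
  Phi <- object@basis@evaluation
  M <- ncol(Phi)
  out <- vapply(seq_along(object@variables), function(i) {
    as.numeric(Phi %*% object@theta[((i - 1) * M + 1):(i * M)])
  }, numeric(nrow(Phi)))
  colnames(out) <- object@variables
  rownames(out) <- NULL
  out
})

#' @rdname ClusterResult-class
#' @param object a ClusterResult
#' @export
setGeneric("clusterLabels", function(object) standardGeneric("clusterLabels"))

#' @rdname ClusterResult-class
#' @export
setMethod("clusterLabels", "ClusterResult", function(object) object@labels)

#' @rdname FeatureSpace-class
#' @param object a FeatureSpace
#' @export
setGeneric("featureScores", function(object) standardGeneric("featureScores"))

#' @rdname FeatureSpace-class
#' @export
setMethod("featureScores", "FeatureSpace", function(object) object@scores)
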