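# Trial-history and adaptive-value-coding regressions on epoch-averaged
# firing rates, plus cluster enrichment of the resulting classifications.

#' Epoch-averaged firing rates per trial
#'
#' @param spikes a [SpikeTrains-class].
#' @param session the [Session-class].
#' @param epoch "postChoice" ([0, 1] s after reward onset, i.e. side-port
#'   entry) or "preChoice" (window before side-port entry).
#' @param window override window (s) relative to the epoch's anchor.
#' @return numeric vector, one rate (Hz) per trial (NA where uncovered).
#' @export
epochRates <- function(spikes, session, epoch = c("postChoice", "preChoice"),
                       window = NULL) {
  epoch <- match.arg(epoch)
  if (is.null(window)) window <- if (epoch == "postChoice") c(0, 1) else c(-1, 0)
  rates <- computePSTH(spikes, session, align = "choice", window = window,
                       perTrial = TRUE, smoothBins = 1L)
  rowMeans(rates, na.rm = TRUE)
}

outcomeCode <- function(outcome) {
  ifelse(outcome == "win", 1, ifelse(outcome == "loss", -1, 0))
}

fitEpochModel <- function(df, formula, targets, classify = TRUE) {
  df <- df[complete.cases(df), , drop = FALSE]
  if (nrow(df) < 20) stop("fewer than 20 usable trials")
  X <- df[, setdiff(names(df), "r"), drop = FALSE]
  if (any(vapply(X, function(col) var(col) < 1e-12, TRUE)))
    stop("degenerate (constant) regressor; model not identifiable")
  fit <- lm(formula, data = df)
  if (any(is.na(coef(fit)))) stop("collinear design; coefficients not identifiable")
  s <- summary(fit)
  co <- s$coefficients
  base <- lm(r ~ 1, data = df)
  modelP <- anova(base, fit)$`Pr(>F)`[2]
  res <- data.frame(term = rownames(co), estimate = co[, 1],
                    p = co[, 4], row.names = NULL)
  classification <- NA_character_
  if (classify) {
    pt <- co[targets, 4]
    et <- co[targets, 1]
    classification <- if (all(pt < 0.05)) {
      if (prod(sign(et)) < 0) "adaptive" else "modulated-non-adaptive"
    } else "not-significant"
  }
  structure(list(coefficients = res, modelP = modelP,
                 classification = classification, n = nrow(df), fit = fit),
            class = "regressionResult")
}

#' @export
print.regressionResult <- function(x, ...) {
  cat(sprintf("regressionResult: n = %d trials, model p = %.3g%s\n", x$n,
              x$modelP,
              if (!is.na(x$classification)) paste0(", ", x$classification) else ""))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Five-trials-back outcome history regression
#'
#' Regresses epoch-averaged rates on the win(+1)/loss(-1) outcomes of the
#' previous five trials, the left(+1)/right(-1) choice, and an intercept.
#' Coefficients get t-tests; the model gets an F-test against the
#' intercept-only baseline. Opt-out current trials are excluded; opt-outs in
#' the history are coded 0.
#'
#' @param rates per-trial rates (see [epochRates()]).
#' @param session the [Session-class].
#' @return a `regressionResult` (no adaptive classification for this model).
#' @export
historyRegression <- function(rates, session) {
  tr <- trialTable(session)
  n <- nrow(tr)
  if (n < 26) stop("need at least 6 trials of history per included trial")
  oc <- outcomeCode(tr$outcome)
  df <- data.frame(r = rates,
                   choice = ifelse(tr$choice == "left", 1, -1))
  for (i in 1:5) df[[paste0("h", i)]] <- c(rep(NA, i), oc[seq_len(n - i)])
  df <- df[tr$outcome != "opt_out" & seq_len(n) > 5, ]
  fitEpochModel(df, r ~ choice + h1 + h2 + h3 + h4 + h5, targets = NULL,
                classify = FALSE)
}

#' Outcome-adaptation regression (current vs previous win/loss)
#'
#' r_n ~ c_winloss x_winloss(n) + c_rewhist x_winloss(n-1) + c_choice
#' x_choice(n) + c0 on post-choice epoch rates. Units with both reward
#' coefficients significant (p < 0.05) are classified `adaptive` when the
#' signs are opposite (reward response scaled down after a win) and
#' `modulated-non-adaptive` when they agree; otherwise `not-significant`.
#'
#' @inheritParams historyRegression
#' @return a `regressionResult` with `classification`.
#' @export
outcomeAdaptationRegression <- function(rates, session) {
  tr <- trialTable(session)
  df <- data.frame(r = rates,
                   winloss = outcomeCode(tr$outcome),
                   rewhist = outcomeCode(tr$prevOutcome),
                   choice = ifelse(tr$choice == "left", 1, -1))
  df <- df[tr$outcome != "opt_out" & tr$prevOutcome %in% c("win", "loss"), ]
  fitEpochModel(df, r ~ winloss + rewhist + choice,
                targets = c("winloss", "rewhist"))
}

#' Volume-adaptation regression (rewarded volume vs previous outcome)
#'
#' r_n ~ c_vol x_vol(n) + c_loss x_loss(n) + c_rewhist x_winloss(n-1) +
#' c_choice x_choice(n) + c0, with x_vol the rewarded volume (ul) and x_loss
#' a 1/0 loss indicator. `adaptive` when c_vol and c_rewhist are both
#' significant with opposite signs.
#'
#' @inheritParams historyRegression
#' @return a `regressionResult` with `classification`.
#' @export
volumeAdaptationRegression <- function(rates, session) {
  tr <- trialTable(session)
  df <- data.frame(r = rates,
                   vol = tr$VRewarded,
                   loss = as.numeric(tr$outcome == "loss"),
                   rewhist = outcomeCode(tr$prevOutcome),
                   choice = ifelse(tr$choice == "left", 1, -1))
  df <- df[tr$outcome != "opt_out" & tr$prevOutcome %in% c("win", "loss"), ]
  fitEpochModel(df, r ~ vol + loss + rewhist + choice,
                targets = c("vol", "rewhist"))
}

#' Reward-prediction-error regression
#'
#' r_n ~ c_rpe x_rpe(n) + c_choice x_choice(n) + c0, with
#' x_rpe = V_rewarded - p_chosen * V_chosen (received minus expected volume
#' of the chosen option).
#'
#' @inheritParams historyRegression
#' @return a `regressionResult`.
#' @export
rpeRegression <- function(rates, session) {
  tr <- trialTable(session)
  pCh <- ifelse(tr$choice == "left", tr$pLeft, tr$pRight)
  vCh <- ifelse(tr$choice == "left", tr$VLeft, tr$VRight)
  rpe <- tr$VRewarded - pCh * vCh
  df <- data.frame(r = rates, rpe = rpe,
                   choice = ifelse(tr$choice == "left", 1, -1))
  df <- df[tr$outcome != "opt_out", ]
  if (var(df$rpe, na.rm = TRUE) < 1e-12)
    stop("zero-variance RPE (all-safe outcomes); model not identifiable")
  fitEpochModel(df, r ~ rpe + choice, targets = "rpe", classify = FALSE)
}

#' Cluster enrichment of a per-neuron classification
#'
#' Per-cluster probability of a classification (e.g. "adaptive") with an
#' exact (Clopper-Pearson) binomial 95% confidence interval; enrichment is
#' read off by comparing intervals across clusters.
#'
#' @param classifications character vector per neuron (or list of
#'   `regressionResult`).
#' @param labels cluster labels.
#' @param positive the classification counted as a success.
#' @return data.frame (cluster, n, k, prob, lo, hi).
#' @export
clusterEnrichment <- function(classifications, labels,
                              positive = "adaptive") {
  if (is.list(classifications) && !is.character(classifications))
    classifications <- vapply(classifications, `[[`, "", "classification")
  lab <- asLabels(labels)
  if (length(lab) != length(classifications))
    stop("labels must cover every classified neuron")
  rows <- lapply(sort(unique(lab)), function(cl) {
    sel <- lab == cl
    n <- sum(sel)
    if (n == 0) stop("empty cluster: ", cl)
    k <- sum(classifications[sel] == positive)
    ci <- binom.test(k, n)$conf.int
    data.frame(cluster = cl, n = n, k = k, prob = k / n, lo = ci[1], hi = ci[2])
  })
  do.call(rbind, rows)
}
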