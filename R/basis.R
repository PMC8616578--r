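# Temporal basis for the encoding-model kernels.

#' Build the kernel basis
#'
#' Seven raised cosines on a log-time axis,
#' phi_j(tau) = (cos(a log tau - b_j) + 1) / 2 for |a log tau - b_j| <= pi and
#' 0 otherwise, with peak lags spread log-linearly between `peakRange[1]` and
#' `peakRange[2]` and the stretch `a` chosen so adjacent cosines cross at 0.5;
#' plus two decaying exponentials (25 and 50 ms time constants) peaking in the
#' first two lag bins to capture impulse-like responses at event onset. All
#' columns are scaled to peak at 1. This gives M = 9 functions per kernel over
#' 4 s (80 lag bins) of causal support.
#'
#' @param dt lag bin width (s).
#' @param support kernel support (s).
#' @param nCosine number of raised cosines.
#' @param peakRange lags (s) of the first and last cosine peak.
#' @param expTaus decay constants (s) of the exponential pair.
#' @return a [BasisSet-class]; `evaluation` has the exponentials in columns
#'   1-2 and the cosines, ordered by peak lag, in columns 3 onwards.
#' @export
buildBasis <- function(dt = 0.05, support = 4, nCosine = 7L,
                       peakRange = c(0.025, 2), expTaus = c(0.025, 0.05)) {
  nLag <- round(support / dt)
  tau <- (seq_len(nLag) - 0.5) * dt
  logPeaks <- seq(log(peakRange[1]), log(peakRange[2]), length.out = nCosine)
  # adjacent cosines cross at phi = 0.5 when their centres are pi/1 apart in
  # a*log(tau): a = pi / spacing
  a <- pi / diff(logPeaks[1:2])
  b <- a * logPeaks
  cosines <- vapply(seq_len(nCosine), function(j) {
    arg <- a * log(tau) - b[j]
    phi <- ifelse(abs(arg) <= pi, (cos(arg) + 1) / 2, 0)
    phi / max(phi)
  }, numeric(nLag))
  expo <- vapply(seq_along(expTaus), function(j) {
    # peak in lag bin j, zero before it
    e <- ifelse(tau >= tau[j], exp(-(tau - tau[j]) / expTaus[j]), 0)
    e / max(e)
  }, numeric(nLag))
  ev <- cbind(expo, cosines)
  colnames(ev) <- c(paste0("exp", seq_along(expTaus)),
                    paste0("cos", seq_len(nCosine)))
  new("BasisSet", dt = dt, support = support, evaluation = ev,
      params = list(a = a, b = b, peaks = exp(logPeaks), taus = expTaus))
}

#' @rdname buildBasis
#' @param object a BasisSet
#' @export
setGeneric("nBasis", function(object) standardGeneric("nBasis"))

#' @rdname buildBasis
#' @export
setMethod("nBasis", "BasisSet", function(object) ncol(object@evaluation))
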