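# Plain-text persistence: trial tables, long event tables, spike times.

#' Write / read a session as CSV
#'
#' `writeSession` emits `trials.csv` (one row per trial) and `events.csv`
#' (long format: trial, event, time_s). `readSession` inverts it.
#'
#' @param session a [Session-class].
#' @param dir output directory (created if needed).
#' @return `writeSession`: the directory, invisibly. `readSession`: a
#'   [Session-class].
#' @export
writeSession <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(trialTable(session), file.path(dir, "trials.csv"), row.names = FALSE)
  ev <- eventTimes(session)
  names(ev) <- c("trial", "event", "time_s")
  write.csv(ev, file.path(dir, "events.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname writeSession
#' @export
readSession <- function(dir) {
  tf <- file.path(dir, "trials.csv"); ef <- file.path(dir, "events.csv")
  for (f in c(tf, ef)) if (!file.exists(f)) stop("missing session file: ", f)
  trials <- read.csv(tf, stringsAsFactors = FALSE)
  events <- read.csv(ef, stringsAsFactors = FALSE)
  names(events) <- c("trial", "event", "time")
  new("Session", trials = trials, events = events, config = list(),
      seed = NA_integer_)
}

#' Write / read unit spike times as CSV
#'
#' Long format `spikes.csv` (unit, trial, time_s; times relative to trial
#' start) plus `spike_meta.csv` describing the count window and coverage.
#'
#' @param spikesList named list of [SpikeTrains-class].
#' @param dir output directory.
#' @param nTrialsSession trial count of the session (needed on read to
#'   restore empty trials).
#' @return `writeSpikes`: the directory, invisibly. `readSpikes`: a named
#'   list of [SpikeTrains-class].
#' @export
writeSpikes <- function(spikesList, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  long <- do.call(rbind, lapply(spikesList, function(s) {
    st <- spikeTimes(s)
    data.frame(unit = unitId(s), trial = rep(seq_along(st), lengths(st)),
               time_s = unlist(st, use.names = FALSE))
  }))
  write.csv(long, file.path(dir, "spikes.csv"), row.names = FALSE)
  meta <- do.call(rbind, lapply(spikesList, function(s)
    data.frame(unit = unitId(s), nTrials = length(spikeTimes(s)),
               window_lo = s@window[1], window_hi = s@window[2],
               coverage_lo = s@coverage[1], coverage_hi = s@coverage[2])))
  write.csv(meta, file.path(dir, "spike_meta.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname writeSpikes
#' @export
readSpikes <- function(dir, nTrialsSession = NULL) {
  sf <- file.path(dir, "spikes.csv"); mf <- file.path(dir, "spike_meta.csv")
  for (f in c(sf, mf)) if (!file.exists(f)) stop("missing spike file: ", f)
  long <- read.csv(sf, stringsAsFactors = FALSE)
  meta <- read.csv(mf, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(meta)), function(i) {
    m <- meta[i, ]
    n <- if (is.null(nTrialsSession)) m$nTrials else nTrialsSession
    sub <- long[long$unit == m$unit, , drop = FALSE]
    st <- split(sub$time_s, factor(sub$trial, levels = seq_len(n)))
    st <- lapply(st, as.numeric)
    window <- c(m$window_lo, m$window_hi)
    dt <- 0.05
    nb <- round(diff(window) / dt)
    centers <- window[1] + dt / 2 + (seq_len(nb) - 1) * dt
    counts <- t(vapply(st, binSpikes, integer(nb), centers = centers, dt = dt))
    new("SpikeTrains", unitId = m$unit, spikeTimes = st, counts = counts,
        binCenters = centers, window = window,
        coverage = c(m$coverage_lo, m$coverage_hi), truth = NULL)
  })
  names(out) <- meta$unit
  out
}

#' Persist a list of metric series as tidy CSV
#'
#' @param metricList named list (per neuron) of `metricSeries`.
#' @param path output CSV path.
#' @return the tidy data.frame, invisibly.
#' @export
writeMetricSeries <- function(metricList, path) {
  tidy <- do.call(rbind, lapply(names(metricList), function(u) {
    m <- metricList[[u]]
    data.frame(neuron = u, metric = m$metric, group = m$group,
               alignment = m$align, time_s = m$time, value = m$corrected,
               raw = m$raw, null_mean = m$nullMean, ci_hi = m$ciHi,
               significant = m$significant)
  }))
  write.csv(tidy, path, row.names = FALSE)
  invisible(tidy)
}
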