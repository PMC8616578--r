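# End-to-end orchestration: configuration, staged execution, reporting, and
# the adapter for the deposited dataset.

#' Pipeline configuration
#'
#' Collects every stage parameter with defaults equal to the analysis
#' constants (50 ms bins, 4 s kernel support, M = 9 basis functions,
#' penalty grid over [1e-5, 10], 5 balanced partitions, 500 CPD shuffles,
#' 500 MI parameter samples, 1000 d' shuffles, 5000 gap references, 10000
#' PAIRS references, 95% PCA variance, 1 Hz and R2 > 0 unit inclusion, CPD
#' outlier cut 50%). Reduce the simulation sizes and reference counts for
#' quick runs; the defaults are the full-scale analysis.
#'
#' @param seed master seed; every stage derives named substreams from it.
#' @param nTrials,nPerArchetype synthetic session and population size.
#' @param stages character vector of stages to run, in order, from
#'   `c("simulate", "fit", "cluster", "validate", "metrics", "regress",
#'   "report")`.
#' @param source "synthetic" or "deposited".
#' @param depositedPath directory of the deposited data (when `source =
#'   "deposited"`).
#' @param clusterK clusters for the labelling used by metrics/enrichment.
#' @param ... overrides for any other parameter listed in the function body.
#' @return a validated list of class `runConfig`.
#' @export
runConfig <- function(seed = 1L, nTrials = 400L, nPerArchetype = 12L,
                      stages = c("simulate", "fit", "cluster", "validate",
                                 "metrics", "regress", "report"),
                      source = c("synthetic", "deposited"),
                      depositedPath = NULL, clusterK = 5L, ...) {
  cfg <- list(
    seed = as.integer(seed), nTrials = as.integer(nTrials),
    nPerArchetype = as.integer(nPerArchetype), stages = stages,
    source = match.arg(source), depositedPath = depositedPath,
    clusterK = as.integer(clusterK),
    dt = 0.05, kernelSupport = 4, window = c(-2, 6), simWindow = c(-2.05, 8.05),
    xiRange = c(1e-5, 10), xiPerRound = 7L, xiRounds = 3L, nPartitions = 5L,
    cpdShuffles = 500L, miSamples = 500L, miShuffles = 500L,
    dprimeShuffles = 1000L, gapRef = 5000L, pairsRef = 10000L,
    pairsKDraws = 50L, varThreshold = 0.95, minRateHz = 1,
    r2Inclusion = 0, cpdOutlier = 50, Kmax = 15L, kmeansReplicates = 50L,
    ariRep = 100L, ariFrac = 0.9,
    metricGroups = c("reward", "rewardHistory", "choice", "clicks", "flashes"),
    miGroups = c("reward", "rewardHistory", "choice"))
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config fields: ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  badStages <- setdiff(cfg$stages, c("simulate", "fit", "cluster", "validate",
                                     "metrics", "regress", "report"))
  if (length(badStages)) stop("unknown stages: ", paste(badStages, collapse = ", "))
  if (cfg$source == "deposited" && is.null(cfg$depositedPath))
    stop("deposited source requires depositedPath")
  structure(cfg, class = "runConfig")
}

#' Serialize / parse a run configuration (YAML)
#'
#' @param config a [runConfig()].
#' @param path YAML file path.
#' @return `writeRunConfig`: path, invisibly; `readRunConfig`: a `runConfig`.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  fixed <- c("seed", "nTrials", "nPerArchetype", "stages", "source",
             "depositedPath", "clusterK")
  do.call(runConfig, c(raw[intersect(fixed, names(raw))],
                       raw[setdiff(names(raw), fixed)]))
}

logLine <- function(state, ...) {
  msg <- sprintf(...)
  state$log <- c(state$log, msg)
  message(msg)
  state
}

requireStage <- function(state, what, stage) {
  if (is.null(state[[what]]))
    stop("stage '", stage, "' requires '", what,
         "' from an earlier stage; enable it or load a previous run")
  invisible(TRUE)
}

#' Run the analysis pipeline end-to-end
#'
#' Executes the requested stages in order (simulate -> fit -> cluster ->
#' validate -> metrics -> regress -> report), writing tidy CSV/JSON artifacts
#' plus the serialized configuration into `outDir`. A rerun with the same
#' configuration reproduces the same numbers; every unit exclusion is logged
#' with its rule so that included + excluded = input.
#'
#' @param config a [runConfig()].
#' @param outDir output directory.
#' @return (invisibly) the pipeline state: session, spikes, fits, feature
#'   spaces, cluster results, metrics, regressions, exclusion log.
#' @export
runPipeline <- function(config = runConfig(), outDir = tempfile("lofcrun")) {
  stopifnot(inherits(config, "runConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  writeRunConfig(config, file.path(outDir, "config.yaml"))
  state <- list(log = character(0), exclusions = data.frame(
    unit = character(0), rule = character(0)))
  basis <- buildBasis(dt = config$dt, support = config$kernelSupport)

  for (stage in config$stages) {
    state <- switch(stage,
      simulate = stageSimulate(state, config, basis, outDir),
      fit = stageFit(state, config, basis, outDir),
      cluster = stageCluster(state, config, outDir),
      validate = stageValidate(state, config, outDir),
      metrics = stageMetrics(state, config, outDir),
      regress = stageRegress(state, config, outDir),
      report = stageReport(state, config, outDir))
  }
  writeLines(state$log, file.path(outDir, "run.log"))
  write.csv(state$exclusions, file.path(outDir, "exclusions.csv"),
            row.names = FALSE)
  state$outDir <- outDir
  invisible(state)
}

stageSimulate <- function(state, config, basis, outDir) {
  if (config$source == "deposited") {
    loaded <- loadDeposited(config$depositedPath, minRateHz = config$minRateHz)
    state$session <- loaded$session
    state$spikes <- loaded$spikes
    state$exclusions <- rbind(state$exclusions, loaded$exclusions)
    return(logLine(state, "simulate: loaded %d units from deposit",
                   length(state$spikes)))
  }
  tc <- taskConfig(nTrials = config$nTrials, seed = config$seed)
  state$session <- generateSession(tc, seed = config$seed)
  neurons <- makeArchetypes(tc, nPerArchetype = config$nPerArchetype,
                            seed = config$seed, basis = basis)
  spikes <- simulatePopulation(state$session, neurons, seed = config$seed,
                               window = config$simWindow, basis = basis,
                               countWindow = config$window)
  rate <- vapply(spikes, function(s) mean(spikeCounts(s)) / config$dt, 0)
  low <- rate < config$minRateHz
  if (any(low)) {
    state$exclusions <- rbind(state$exclusions, data.frame(
      unit = names(spikes)[low], rule = sprintf("mean rate < %g Hz", config$minRateHz)))
    spikes <- spikes[!low]
  }
  state$spikes <- spikes
  state$truth <- vapply(neurons, function(n) n@archetype, "")[!low]
  names(state$truth) <- names(spikes)
  writeSession(state$session, outDir)
  writeSpikes(spikes, outDir)
  logLine(state, "simulate: %d trials, %d units kept (%d excluded below %g Hz)",
          nTrials(state$session), length(spikes), sum(low), config$minRateHz)
}

stageFit <- function(state, config, basis, outDir) {
  requireStage(state, "spikes", "fit")
  state$design <- buildDesignMatrix(state$session, window = config$window,
                                    basis = basis)
  state$scheme <- partitionTrials(state$session, seed = config$seed,
                                  nParts = config$nPartitions)
  fits <- lapply(names(state$spikes), function(u)
    selectModel(state$spikes[[u]], state$design, state$scheme,
                xiRange = config$xiRange, nPerRound = config$xiPerRound,
                nRounds = config$xiRounds))
  names(fits) <- names(state$spikes)
  state$fits <- fits
  r2 <- vapply(fits, slot, 0, "r2Test")
  excluded <- r2 <= config$r2Inclusion
  if (any(excluded))
    state$exclusions <- rbind(state$exclusions, data.frame(
      unit = names(fits)[excluded],
      rule = sprintf("held-out R2 <= %g", config$r2Inclusion)))
  state$included <- names(fits)[!excluded]
  tab <- data.frame(unit = names(fits), xi = vapply(fits, slot, 0, "xi"),
                    r2Test = r2,
                    nllTest = vapply(fits, function(f) f@nll[["test"]], 0))
  write.csv(tab, file.path(outDir, "glm_fits.csv"), row.names = FALSE)
  logLine(state, "fit: %d units fit, %d pass R2 > %g", length(fits),
          length(state$included), config$r2Inclusion)
}

stageCluster <- function(state, config, outDir) {
  requireStage(state, "spikes", "cluster")
  psths <- psthMatrix(state$spikes, state$session)
  state$psthFS <- buildPsthFeatureSpace(psths, config$varThreshold)
  state$condFS <- buildConditionalFeatureSpace(state$spikes, state$session,
                                               config$varThreshold)
  state$psthClusters <- kmeansCluster(state$psthFS, config$clusterK,
                                      seed = config$seed,
                                      replicates = config$kmeansReplicates)
  state$condClusters <- kmeansCluster(state$condFS, config$clusterK,
                                      seed = config$seed,
                                      replicates = config$kmeansReplicates)
  state$consistency <- clusterConsistency(state$psthClusters, state$condClusters)
  lab <- data.frame(unit = names(clusterLabels(state$psthClusters)),
                    psthCluster = clusterLabels(state$psthClusters),
                    condCluster = clusterLabels(state$condClusters)[
                      names(clusterLabels(state$psthClusters))])
  write.csv(lab, file.path(outDir, "cluster_labels.csv"), row.names = FALSE)
  write.csv(as.data.frame(state$consistency),
            file.path(outDir, "cluster_consistency.csv"))
  logLine(state, "cluster: K = %d on %d units (psth %d PCs, conditional %d PCs)",
          config$clusterK, nrow(featureScores(state$psthFS)),
          state$psthFS@k, state$condFS@k)
}

stageValidate <- function(state, config, outDir) {
  requireStage(state, "psthFS", "validate")
  gap <- gapStatistic(state$psthFS, Kmax = config$Kmax, nRef = config$gapRef,
                      seed = config$seed)
  pairs <- pairsStatistic(state$psthFS, nRef = config$pairsRef,
                          seed = config$seed)
  sil <- vapply(2:min(config$Kmax, nrow(featureScores(state$psthFS)) - 1),
                function(k) silhouetteScore(state$psthFS,
                  kmeansCluster(state$psthFS, k, seed = config$seed)),
                numeric(1))
  ariDist <- ariSubsample(state$psthFS, config$clusterK, frac = config$ariFrac,
                          nRep = config$ariRep, seed = config$seed)
  state$validation <- list(gap = gap, pairs = pairs, silhouette = sil,
                           ari = ariDist)
  tidy <- rbind(
    data.frame(metric = "gap", K = gap$K, replicate = NA, value = gap$gap),
    data.frame(metric = "silhouette", K = seq_along(sil) + 1, replicate = NA,
               value = sil),
    data.frame(metric = "ari", K = config$clusterK,
               replicate = seq_along(ariDist), value = ariDist))
  write.csv(tidy, file.path(outDir, "validation.csv"), row.names = FALSE)
  jsonlite::write_json(list(
    gapSelectedK = gap$selectedK,
    silhouetteOptK = which.max(sil) + 1,
    pairs = pairs$pairs, pairsP = pairs$p, pairsK = pairs$kNeighbors),
    file.path(outDir, "validation_summary.json"), auto_unbox = TRUE)
  logLine(state, "validate: gap K = %d, PAIRS = %.3f (p = %.3g, k = %d)",
          gap$selectedK, pairs$pairs, pairs$p, pairs$kNeighbors)
}

stageMetrics <- function(state, config, outDir) {
  requireStage(state, "fits", "metrics")
  requireStage(state, "psthClusters", "metrics")
  units <- state$included
  cpdAll <- list(); miAll <- list(); dpAll <- list()
  for (u in units) {
    for (grp in config$metricGroups)
      cpdAll[[paste(u, grp, sep = ".")]] <-
        cpd(state$fits[[u]], state$spikes[[u]], state$design, grp,
            nShuffles = config$cpdShuffles, seed = config$seed,
            outlierThreshold = config$cpdOutlier)
    for (grp in config$miGroups)
      miAll[[paste(u, grp, sep = ".")]] <-
        mutualInformation(state$fits[[u]], state$design, grp,
                          nSamples = config$miSamples,
                          nShuffles = config$miShuffles, seed = config$seed)
    dpAll[[u]] <- dprime(state$spikes[[u]], state$session,
                         nShuffles = config$dprimeShuffles, seed = config$seed)
  }
  state$cpd <- cpdAll; state$mi <- miAll; state$dprime <- dpAll
  writeMetricSeries(cpdAll, file.path(outDir, "cpd.csv"))
  writeMetricSeries(miAll, file.path(outDir, "mi.csv"))
  writeMetricSeries(dpAll, file.path(outDir, "dprime.csv"))
  lab <- clusterLabels(state$psthClusters)[units]
  avg <- list()
  for (grp in config$metricGroups) {
    ml <- cpdAll[paste(units, grp, sep = ".")]
    names(ml) <- units
    avg[[paste0("cpd.", grp)]] <- cbind(metric = "cpd", group = grp,
                                        clusterAverage(ml, lab))
  }
  write.csv(do.call(rbind, avg), file.path(outDir, "cluster_metrics.csv"),
            row.names = FALSE)
  logLine(state, "metrics: CPD/MI/d' for %d units", length(units))
}

stageRegress <- function(state, config, outDir) {
  requireStage(state, "spikes", "regress")
  requireStage(state, "psthClusters", "regress")
  units <- if (!is.null(state$included)) state$included else names(state$spikes)
  res <- lapply(units, function(u) {
    r <- epochRates(state$spikes[[u]], state$session, "postChoice")
    list(outcome = outcomeAdaptationRegression(r, state$session),
         volume = volumeAdaptationRegression(r, state$session),
         rpe = rpeRegression(r, state$session))
  })
  names(res) <- units
  state$regressions <- res
  cls <- vapply(res, function(x) x$outcome$classification, "")
  lab <- clusterLabels(state$psthClusters)[units]
  state$enrichment <- clusterEnrichment(cls, lab)
  tidy <- do.call(rbind, lapply(units, function(u) {
    do.call(rbind, lapply(names(res[[u]]), function(a) {
      co <- res[[u]][[a]]$coefficients
      data.frame(unit = u, analysis = a, coefficient = co$term,
                 estimate = co$estimate, p = co$p,
                 classification = res[[u]][[a]]$classification)
    }))
  }))
  write.csv(tidy, file.path(outDir, "regressions.csv"), row.names = FALSE)
  jsonlite::write_json(state$enrichment,
                       file.path(outDir, "enrichment.json"), dataframe = "rows")
  logLine(state, "regress: %d/%d units adaptive (outcome model)",
          sum(cls == "adaptive"), length(cls))
}

stageReport <- function(state, config, outDir) {
  requireStage(state, "psthClusters", "report")
  figDir <- file.path(outDir, "figures")
  dir.create(figDir, showWarnings = FALSE)
  figs <- reportFigures(state, config)
  for (nm in names(figs)) {
    grDevices::pdf(file.path(figDir, paste0(nm, ".pdf")), width = 7, height = 5)
    print(figs[[nm]])
    grDevices::dev.off()
  }
  state$figures <- figs
  logLine(state, "report: wrote %d figures to %s", length(figs), figDir)
}

#' Standard report figures for a pipeline state
#'
#' Cluster-mean PSTHs sorted by time to peak, the cross-method consistency
#' heatmap, the held-out R2 distribution, cluster-averaged CPD panels, the
#' d' raster, enrichment bars, and loss / low-reward (6-12 ul) /
#' high-reward (24-48 ul) conditional averages per cluster.
#'
#' @param state a [runPipeline()] state.
#' @param config the matching [runConfig()].
#' @return named list of ggplot objects.
#' @export
reportFigures <- function(state, config = runConfig()) {
  figs <- list()
  lab <- clusterLabels(state$psthClusters)
  psths <- psthMatrix(state$spikes, state$session)
  tau <- as.numeric(colnames(psths))
  cl <- sort(unique(lab))
  cm <- do.call(rbind, lapply(cl, function(k) data.frame(
    cluster = k, time = tau,
    rate = colMeans(psths[lab == k, , drop = FALSE], na.rm = TRUE))))
  peakOrder <- order(vapply(cl, function(k)
    tau[which.max(cm$rate[cm$cluster == k])], 0))
  cm$cluster <- factor(cm$cluster, levels = cl[peakOrder])
  figs$clusterPSTH <- ggplot2::ggplot(cm, ggplot2::aes(time, rate)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~cluster, scales = "free_y") +
    ggplot2::labs(x = "time from trial start (s)", y = "rate (Hz)",
                  title = "cluster-mean PSTHs (sorted by time to peak)")
  if (!is.null(state$consistency)) {
    cc <- as.data.frame(as.table(state$consistency))
    names(cc) <- c("psth", "conditional", "p")
    figs$consistency <- ggplot2::ggplot(cc,
        ggplot2::aes(conditional, psth, fill = p)) +
      ggplot2::geom_tile() +
      ggplot2::labs(title = "P(conditional cluster | PSTH cluster)")
  }
  if (!is.null(state$fits)) {
    r2 <- data.frame(unit = names(state$fits),
                     r2 = vapply(state$fits, slot, 0, "r2Test"))
    figs$r2 <- ggplot2::ggplot(r2, ggplot2::aes(seq_along(r2), r2)) +
      ggplot2::geom_point() +
      ggplot2::labs(x = "unit", y = "held-out R2")
  }
  if (!is.null(state$cpd)) {
    tidy <- do.call(rbind, lapply(names(state$cpd), function(nm) {
      m <- state$cpd[[nm]]
      u <- sub("\\.[^.]+$", "", nm)
      data.frame(cluster = lab[[u]], group = m$group, time = m$time,
                 value = m$corrected)
    }))
    agg <- aggregate(value ~ cluster + group + time, tidy, mean)
    figs$cpd <- ggplot2::ggplot(agg, ggplot2::aes(time, value,
        colour = factor(cluster))) +
      ggplot2::geom_line() +
      ggplot2::facet_wrap(~group, scales = "free") +
      ggplot2::labs(y = "CPD (%)", colour = "cluster")
  }
  if (!is.null(state$dprime)) {
    dp <- do.call(rbind, lapply(names(state$dprime), function(u) {
      m <- state$dprime[[u]]
      data.frame(unit = u, time = m$time,
                 value = ifelse(m$significant, m$corrected, 0))
    }))
    figs$dprimeRaster <- ggplot2::ggplot(dp, ggplot2::aes(time, unit,
        fill = value)) +
      ggplot2::geom_tile() +
      ggplot2::labs(title = "significant d' (prev win vs prev loss)")
  }
  if (!is.null(state$enrichment)) {
    figs$enrichment <- ggplot2::ggplot(state$enrichment,
        ggplot2::aes(factor(cluster), prob)) +
      ggplot2::geom_col() +
      ggplot2::geom_errorbar(ggplot2::aes(ymin = lo, ymax = hi), width = 0.2) +
      ggplot2::labs(x = "cluster", y = "P(adaptive)")
  }
  # loss / low / high conditional averages per cluster
  tr <- trialTable(state$session)
  conds <- list(loss = tr$outcome == "loss",
                low = tr$VRewarded %in% c(6, 12),
                high = tr$VRewarded %in% c(24, 48))
  rows <- list()
  for (cn in names(conds)) {
    if (!any(conds[[cn]])) next
    pm <- psthMatrix(state$spikes, state$session, align = "choice",
                     window = c(-2, 3), conditionFilter = conds[[cn]])
    tauC <- as.numeric(colnames(pm))
    for (k in cl)
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = k, condition = cn, time = tauC,
        rate = colMeans(pm[lab == k, , drop = FALSE], na.rm = TRUE))
  }
  if (length(rows)) {
    cd <- do.call(rbind, rows)
    figs$conditionalAverages <- ggplot2::ggplot(cd,
        ggplot2::aes(time, rate, colour = condition)) +
      ggplot2::geom_line() +
      ggplot2::facet_wrap(~cluster, scales = "free_y") +
      ggplot2::labs(x = "time from reward delivery (s)", y = "rate (Hz)")
  }
  figs
}

#' Load the deposited dataset from disk
#'
#' Maps a locally downloaded copy of the study's deposited source data onto
#' the package's containers. The adapter expects the plain-text layout
#' written by [writeSession()] / [writeSpikes()] (trials.csv, events.csv,
#' spikes.csv, spike_meta.csv); schema mismatches are reported
#' field-by-field. Units with a mean firing rate below `minRateHz` are
#' excluded and logged, and the loaded unit count is reported against the
#' expected 659 well-isolated single units.
#'
#' @param path directory containing the deposited tables.
#' @param minRateHz inclusion threshold (default 1 Hz).
#' @return list(session, spikes, exclusions).
#' @export
loadDeposited <- function(path, minRateHz = 1) {
  if (is.null(path) || !dir.exists(path))
    stop("deposited data not found at '", path,
         "'; download the archive (DOI 10.5281/zenodo.5592702) and unpack it there")
  session <- readSession(path)
  need <- c("index", "tStart", "tGo", "tExitCenter", "tChoice", "choice",
            "choseSafe", "outcome", "VLeft", "VRight", "pLeft", "pRight",
            "EVLeft", "EVRight", "VRewarded", "prevOutcome",
            "prevRewardRate", "sessionProgress")
  miss <- setdiff(need, names(trialTable(session)))
  if (length(miss))
    stop("deposited trial table schema mismatch; missing fields: ",
         paste(miss, collapse = ", "))
  spikes <- readSpikes(path, nTrialsSession = nTrials(session))
  rate <- vapply(spikes, function(s) mean(spikeCounts(s)) / 0.05, 0)
  low <- rate < minRateHz
  exclusions <- data.frame(unit = names(spikes)[low],
                           rule = sprintf("mean rate < %g Hz", minRateHz))
  message(sprintf("loaded %d units (expected 659); %d excluded below %g Hz",
                  length(spikes), sum(low), minRateHz))
  list(session = session, spikes = spikes[!low], exclusions = exclusions)
}
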