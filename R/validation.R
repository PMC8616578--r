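# Cluster-number selection and clusteredness statistics: gap statistic,
# silhouette, subsampled ARI, Mahalanobis separation, PAIRS, and the
# covariance-regime experiment.

#' Gap statistic over a grid of cluster numbers
#'
#' Reference sets are drawn uniformly over the box aligned with the data's
#' principal axes (`cluster::clusGap` with `spaceH0 = "scaledPCA"`). The
#' selected K is the largest K in the grid with a significant jump,
#' Gap(K) >= Gap(K-1) + 2 SE(K-1), falling back to 1 when no jump is
#' significant.
#'
#' @param features a [FeatureSpace-class] or numeric matrix.
#' @param Kmax grid upper end (grid is 1..Kmax).
#' @param nRef number of reference datasets (default 5000; reduce for quick
#'   exploration — fewer than 100 draws triggers a warning).
#' @param seed integer seed.
#' @param replicates k-means restarts per evaluation.
#' @return list of class `gapCurve`: `K` grid, `gap`, `se`, `selectedK`,
#'   `logW`, `nRef`.
#' @export
gapStatistic <- function(features, Kmax = 15L, nRef = 5000L, seed = 1L,
                         replicates = 10L) {
  x <- featureMatrix(features)
  if (nRef < 100) warning("fewer than 100 reference samples; gap estimates will be noisy")
  Kmax <- min(Kmax, nrow(x) - 1L)
  gs <- withSeed(subSeed(seed, "gap"), {
    cluster::clusGap(x, FUNcluster = function(xx, k)
      list(cluster = kmeans(xx, k, nstart = replicates, iter.max = 50)$cluster),
      K.max = Kmax, B = nRef, spaceH0 = "scaledPCA", verbose = FALSE)
  })
  tab <- gs$Tab
  structure(list(K = seq_len(Kmax), gap = tab[, "gap"], se = tab[, "SE.sim"],
                 logW = tab[, "logW"],
                 selectedK = selectGapK(tab[, "gap"], tab[, "SE.sim"]),
                 nRef = as.integer(nRef)),
            class = "gapCurve")
}

# largest K with Gap(K) >= Gap(K-1) + 2 SE(K-1); 1 when no significant jump
selectGapK <- function(gap, se) {
  K <- length(gap)
  sig <- which(gap[-1] >= gap[-K] + 2 * se[-K]) + 1L
  if (length(sig)) max(sig) else 1L
}

#' Silhouette score of a labelled feature space
#'
#' Mean over points of (b(i) - a(i)) / max(a(i), b(i)) with Euclidean
#' distances, where a(i) is the mean within-cluster distance and b(i) the
#' mean distance to the closest other cluster.
#'
#' @param features a [FeatureSpace-class] or matrix.
#' @param labels cluster labels (or [ClusterResult-class]).
#' @return scalar score in [-1, 1].
#' @export
silhouetteScore <- function(features, labels) {
  x <- featureMatrix(features)
  lab <- asLabels(labels)
  if (length(unique(lab)) < 2) stop("silhouette needs at least two clusters")
  if (all(tabulate(lab) <= 1)) stop("all clusters are singletons")
  mean(cluster::silhouette(lab, dist(x))[, "sil_width"])
}

#' Reproducibility of a clustering under subsampling (ARI distribution)
#'
#' Repeatedly samples a fraction of the population without replacement,
#' clusters the subsample and the full data with the same K, and records the
#' adjusted Rand index between the two labelings on the shared neurons.
#'
#' @param features a [FeatureSpace-class] or matrix.
#' @param K number of clusters (>= 2).
#' @param frac subsample fraction in (0, 1].
#' @param nRep number of subsampled datasets.
#' @param seed integer seed.
#' @param replicates k-means restarts.
#' @return numeric vector of `nRep` ARI values.
#' @export
ariSubsample <- function(features, K, frac = 0.9, nRep = 100L, seed = 1L,
                         replicates = 20L) {
  if (K < 2) stop("K must be at least 2")
  if (frac <= 0 || frac > 1) stop("frac must lie in (0, 1]")
  x <- featureMatrix(features)
  full <- kmeansCluster(x, K, seed = seed, replicates = replicates)
  n <- nrow(x)
  m <- max(K, floor(frac * n))
  vapply(seq_len(nRep), function(r) {
    idx <- withSeed(subSeed(seed, paste0("ari", r)), sample.int(n, m))
    sub <- kmeansCluster(x[idx, , drop = FALSE], K, seed = seed + r,
                         replicates = replicates)
    ari(clusterLabels(full)[idx], clusterLabels(sub))
  }, numeric(1))
}

#' Cluster-averaged Mahalanobis distances
#'
#' D_M(A, B) averages, over the points of cluster A, the Mahalanobis distance
#' (square root of the quadratic form, an average z-score) to cluster B's
#' mean and covariance. The full K x K matrix including own-cluster entries is
#' returned. Near-singular covariances get a small ridge; clusters smaller
#' than dimension + 1 fall back to a pseudo-inverse with a warning.
#'
#' @param features a [FeatureSpace-class] or matrix.
#' @param labels cluster labels.
#' @param ridge diagonal ridge added when the covariance is near-singular.
#' @return K x K matrix of averaged distances.
#' @export
mahalanobisSeparation <- function(features, labels, ridge = 1e-8) {
  x <- featureMatrix(features)
  lab <- asLabels(labels)
  K <- max(lab)
  d <- ncol(x)
  out <- matrix(NA_real_, K, K,
                dimnames = list(paste0("from", seq_len(K)), paste0("to", seq_len(K))))
  for (B in seq_len(K)) {
    xb <- x[lab == B, , drop = FALSE]
    mu <- colMeans(xb)
    S <- stats::cov(xb)
    Sinv <- if (nrow(xb) < d + 1) {
      warning("cluster ", B, " smaller than dimension + 1; using pseudo-inverse")
      ginv(S)
    } else {
      tryCatch(solve(S), error = function(e) solve(S + diag(ridge, d)))
    }
    for (A in seq_len(K)) {
      xa <- x[lab == A, , drop = FALSE]
      delta <- sweep(xa, 2, mu)
      out[A, B] <- mean(sqrt(pmax(rowSums((delta %*% Sinv) * delta), 0)))
    }
  }
  out
}

# Moore-Penrose pseudo-inverse via SVD (for covariance fallback only).
ginv <- function(S, tol = 1e-10) {
  s <- svd(S)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

# ---- PAIRS -----------------------------------------------------------------

whiten <- function(x) {
  x <- sweep(x, 2, colMeans(x))
  e <- eigen(stats::cov(x), symmetric = TRUE)
  vals <- pmax(e$values, 1e-12)
  x %*% e$vectors %*% diag(1 / sqrt(vals), length(vals)) %*% t(e$vectors)
}

# Per-point mean angle to the k nearest neighbours (neighbours by angular
# proximity). fold = TRUE folds angles about pi/2 (arccos |cos|).
meanNeighborAngles <- function(x, k, fold = FALSE) {
  n <- nrow(x)
  if (k >= n) stop("k must be smaller than the number of points")
  nrm <- sqrt(rowSums(x^2))
  C <- tcrossprod(x) / outer(nrm, nrm)
  C[C > 1] <- 1; C[C < -1] <- -1
  ang <- if (fold) acos(abs(C)) else acos(C)
  diag(ang) <- Inf
  sorted <- apply(ang, 1, sort)[seq_len(k), , drop = FALSE]
  colMeans(sorted)
}

#' PAIRS: neighbour-angle test for clustered structure
#'
#' Whitens the feature space to zero mean and unit covariance, computes each
#' point's mean angle to its k nearest neighbours, and compares the median of
#' those angles to the pooled median of matched standard-Gaussian reference
#' datasets: PAIRS = (median_ref - median_data) / median_ref. Positive values
#' mean the data are more tightly packed (more clustered) than an isotropic
#' Gaussian. The two-sided p-value comes from a normal fit to the reference
#' PAIRS values, and a Kolmogorov-Smirnov test compares the angle
#' distributions.
#'
#' @param features a PCA-reduced [FeatureSpace-class] or matrix.
#' @param kNeighbors neighbours to average; default picks
#'   [selectPairsK()] on the matched reference.
#' @param nRef number of reference datasets (default 10000; reduce for quick
#'   exploration).
#' @param seed integer seed.
#' @param fold fold angles about pi/2 (arccos of the absolute cosine) instead
#'   of the signed convention on [0, pi].
#' @return list of class `pairsResult`: `pairs`, `p`, `ksP`, `kNeighbors`,
#'   `thetaData`, `thetaRefMedian`, `nRef`.
#' @export
pairsStatistic <- function(features, kNeighbors = NULL, nRef = 10000L,
                           seed = 1L, fold = FALSE) {
  x <- whiten(featureMatrix(features))
  n <- nrow(x); d <- ncol(x)
  if (is.null(kNeighbors))
    kNeighbors <- selectPairsK(n, d, seed = subSeed(seed, "pairsK"),
                               nDraws = min(nRef, 50L), fold = fold)
  thetaData <- meanNeighborAngles(x, kNeighbors, fold)
  refAngles <- vector("list", nRef)
  withSeed(subSeed(seed, "pairsRef"), {
    # references get the same whitening as the data, so sampling noise in
    # the sample covariance affects both sides equally
    for (r in seq_len(nRef))
      refAngles[[r]] <- meanNeighborAngles(whiten(matrix(rnorm(n * d), n, d)),
                                           kNeighbors, fold)
  })
  pooled <- unlist(refAngles)
  thetaRef <- median(pooled)
  pairs <- (thetaRef - median(thetaData)) / thetaRef
  refPairs <- vapply(refAngles, function(a) (thetaRef - median(a)) / thetaRef,
                     numeric(1))
  z <- (pairs - mean(refPairs)) / sd(refPairs)
  structure(list(pairs = pairs, p = 2 * pnorm(-abs(z)),
                 ksP = suppressWarnings(ks.test(thetaData, pooled)$p.value),
                 kNeighbors = as.integer(kNeighbors), thetaData = thetaData,
                 thetaRefMedian = thetaRef, refPairs = refPairs,
                 nRef = as.integer(nRef), fold = fold),
            class = "pairsResult")
}

#' Select the PAIRS neighbour count from the Gaussian reference
#'
#' Draws standard-Gaussian reference datasets of the data's size and
#' dimensionality, pools each point's mean angle to its k nearest neighbours
#' across draws, and returns the smallest k whose pooled median angle exceeds
#' pi/4.
#'
#' @param N number of data points.
#' @param D feature-space dimensionality.
#' @param seed integer seed.
#' @param nDraws reference datasets pooled per k.
#' @param kMax largest neighbour count considered.
#' @param fold angle-folding convention (see [pairsStatistic()]).
#' @return integer neighbour count.
#' @export
selectPairsK <- function(N, D, seed = 1L, nDraws = 50L, kMax = min(N - 1L, 30L),
                         fold = FALSE) {
  pooled <- matrix(NA_real_, nDraws * N, kMax)
  withSeed(subSeed(seed, "pairsK"), {
    for (r in seq_len(nDraws)) {
      x <- matrix(rnorm(N * D), N, D)
      nrm <- sqrt(rowSums(x^2))
      C <- tcrossprod(x) / outer(nrm, nrm)
      C[C > 1] <- 1; C[C < -1] <- -1
      ang <- if (fold) acos(abs(C)) else acos(C)
      diag(ang) <- Inf
      sorted <- apply(ang, 1, sort)[seq_len(kMax), , drop = FALSE]
      cums <- apply(sorted, 2, cumsum) / seq_len(kMax)  # mean over first k
      pooled[((r - 1) * N + 1):(r * N), ] <- t(cums)
    }
  })
  meds <- apply(pooled, 2, median)
  k <- which(meds > pi / 4)[1]
  if (is.na(k)) stop("reference median angle never exceeds pi/4 up to k = ", kMax)
  as.integer(k)
}

# ---- covariance-regime experiment ------------------------------------------

#' Smooth synthetic covariance (squared-exponential over ordered bins)
#'
#' A stand-in covariance with the smooth, low-effective-rank structure of
#' trial-averaged response profiles; used by [regimeExperiment()] when no
#' empirical covariances are supplied.
#'
#' @param D dimension.
#' @param ell correlation length in bins.
#' @param variance marginal variance.
#' @return D x D covariance matrix.
#' @export
smoothCov <- function(D, ell = 10, variance = 1) {
  i <- seq_len(D)
  variance * exp(-outer(i, i, "-")^2 / (2 * ell^2))
}

#' Cluster-number selection across covariance regimes
#'
#' Generates ground-truth datasets with `K` clusters: cluster means drawn
#' from a multivariate normal with the total-data covariance scaled by each
#' factor, and points drawn around them with the within-cluster covariance.
#' Each replicate is PCA-reduced (cumulative variance > `varThreshold`) and
#' the silhouette-optimal K and the gap-selected K are recorded.
#'
#' @param totalCov,withinCov D x D covariances (defaults: [smoothCov()] with
#'   the within-cluster spread a tenth of the total).
#' @param scales total-covariance scale factors.
#' @param nRep replicates per scale.
#' @param seed integer seed.
#' @param K planted number of clusters.
#' @param nPerCluster points per cluster.
#' @param Kmax largest K evaluated.
#' @param nRef gap-statistic reference draws per replicate.
#' @param varThreshold PCA variance cut.
#' @param replicates k-means restarts per clustering evaluation.
#' @return data.frame (scale, rep, method, K) of selected cluster numbers,
#'   with a `summary` attribute of per-scale mean and SEM.
#' @export
regimeExperiment <- function(totalCov = NULL, withinCov = NULL,
                             scales = c(0.1, 0.5, 1, 2, 3, 5), nRep = 100L,
                             seed = 1L, K = 5L, nPerCluster = 100L,
                             Kmax = 8L, nRef = 100L, varThreshold = 0.95,
                             replicates = 20L) {
  D <- if (!is.null(totalCov)) nrow(totalCov) else 121L
  if (is.null(totalCov)) totalCov <- smoothCov(D)
  if (is.null(withinCov)) withinCov <- smoothCov(D, variance = 0.1)
  stopifnot(nrow(withinCov) == D)
  eigTot <- min(eigen(totalCov, symmetric = TRUE, only.values = TRUE)$values)
  if (eigTot < -1e-8) stop("total covariance is not positive semidefinite")
  rows <- list()
  for (s in scales) {
    for (r in seq_len(nRep)) {
      x <- withSeed(subSeed(seed, sprintf("regime%.3g_%d", s, r)), {
        mus <- rmvn(K, numeric(D), s * totalCov)
        do.call(rbind, lapply(seq_len(K), function(k)
          rmvn(nPerCluster, mus[k, ], withinCov)))
      })
      red <- pcaReduce(sweep(x, 2, colMeans(x)), varThreshold)$scores
      silK <- which.max(vapply(2:Kmax, function(k) {
        cl <- kmeansCluster(red, k, seed = seed + r, replicates = replicates)
        silhouetteScore(red, cl)
      }, numeric(1))) + 1L
      gapK <- gapStatistic(red, Kmax = Kmax, nRef = nRef, seed = seed + r,
                           replicates = replicates)$selectedK
      rows[[length(rows) + 1L]] <- data.frame(
        scale = s, rep = r,
        method = c("silhouette", "gap"), K = c(silK, gapK))
    }
  }
  out <- do.call(rbind, rows)
  summ <- aggregate(K ~ scale + method, out,
                    function(v) c(mean = mean(v), sem = sd(v) / sqrt(length(v))))
  attr(out, "summary") <- do.call(data.frame, summ)
  out
}
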