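# k-means clustering of feature spaces and cross-method consistency.

featureMatrix <- function(features) {
  if (is(features, "FeatureSpace")) featureScores(features) else as.matrix(features)
}

#' k-means clustering with seeded restarts
#'
#' Best of `replicates` random restarts by total within-cluster sum of
#' squares. Rows are put in a canonical (sorted) order before clustering so
#' the result is invariant to neuron ordering, and clusters are relabelled by
#' decreasing size (ties broken by centroid order) for stability.
#'
#' @param features a [FeatureSpace-class] or numeric matrix (rows = neurons).
#' @param K number of clusters (1 <= K <= rows).
#' @param seed integer seed; the same seed reproduces the same labels.
#' @param replicates number of random restarts.
#' @return a [ClusterResult-class].
#' @export
kmeansCluster <- function(features, K, seed = 1L, replicates = 50L) {
  x <- featureMatrix(features)
  if (K < 1) stop("K must be at least 1")
  if (K > nrow(x)) stop("K exceeds the number of points")
  if (K == 1) {
    ctr <- matrix(colMeans(x), 1)
    return(new("ClusterResult", labels = setNames(rep(1L, nrow(x)), rownames(x)),
               centroids = ctr, K = 1L,
               inertia = sum(sweep(x, 2, ctr[1, ])^2), seed = as.integer(seed),
               replicates = as.integer(replicates)))
  }
  ord <- do.call(order, as.data.frame(x))
  fit <- withSeed(subSeed(seed, "kmeans"),
                  kmeans(x[ord, , drop = FALSE], centers = K,
                         nstart = replicates, iter.max = 100))
  labels <- integer(nrow(x))
  labels[ord] <- fit$cluster
  # canonical relabelling: by decreasing cluster size, ties by first centroid axis
  sizes <- tabulate(fit$cluster, K)
  relab <- order(-sizes, fit$centers[, 1])
  map <- integer(K); map[relab] <- seq_len(K)
  labels <- map[labels]
  new("ClusterResult", labels = setNames(labels, rownames(x)),
      centroids = fit$centers[relab, , drop = FALSE], K = as.integer(K),
      inertia = fit$tot.withinss, seed = as.integer(seed),
      replicates = as.integer(replicates))
}

asLabels <- function(x) {
  if (is(x, "ClusterResult")) clusterLabels(x) else as.integer(x)
}

#' Consistency between two clusterings of the same neurons
#'
#' Conditional probability P(B = j | A = i) with B's clusters matched to A's
#' by greedy maximal overlap before display, so corresponding clusters sit on
#' the diagonal.
#'
#' @param labelsA,labelsB [ClusterResult-class] objects or label vectors over
#'   the same neurons.
#' @return matrix of conditional probabilities (rows = A clusters, columns =
#'   matched B clusters; rows sum to 1), with the B-to-column mapping in
#'   `attr(, "matching")`.
#' @export
clusterConsistency <- function(labelsA, labelsB) {
  a <- asLabels(labelsA); b <- asLabels(labelsB)
  if (length(a) != length(b)) stop("label vectors must cover the same neurons")
  if (!is.null(names(a)) && !is.null(names(b))) {
    if (!setequal(names(a), names(b))) stop("disjoint neuron sets")
    b <- b[names(a)]
  }
  Ka <- max(a); Kb <- max(b)
  tab <- matrix(0, Ka, Kb)
  for (i in seq_along(a)) tab[a[i], b[i]] <- tab[a[i], b[i]] + 1
  # greedy maximal-overlap matching of B clusters onto A clusters
  matching <- integer(Kb)
  work <- tab
  for (step in seq_len(min(Ka, Kb))) {
    ij <- arrayInd(which.max(work), dim(work))
    matching[ij[2]] <- ij[1]
    work[ij[1], ] <- -1; work[, ij[2]] <- -1
  }
  unmatched <- which(matching == 0)
  matching[unmatched] <- setdiff(seq_len(max(Ka, Kb)), matching)[seq_along(unmatched)]
  perm <- order(matching[seq_len(Kb)])
  P <- tab / rowSums(tab)
  P <- P[, perm, drop = FALSE]
  colnames(P) <- paste0("B", perm)
  rownames(P) <- paste0("A", seq_len(Ka))
  attr(P, "matching") <- matching
  P
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement (wraps `mclust::adjustedRandIndex`).
#'
#' @param labelsA,labelsB label vectors or [ClusterResult-class] objects.
#' @return ARI in (-1, 1], 1 for identical partitions.
#' @export
ari <- function(labelsA, labelsB) {
  mclust::adjustedRandIndex(asLabels(labelsA), asLabels(labelsB))
}
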