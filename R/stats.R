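# Spatiotemporal cluster-based permutation testing.
#
# Dependent-samples t-maps are thresholded at the two-tailed parametric
# critical t (the conventional cluster-forming default; the design itself
# states none), suprathreshold cells are clustered by temporal adjacency
# (consecutive samples), spatial adjacency (electrodes within 5 cm) and
# common sign, the cluster statistic is the summed t, and the family-wise
# null distribution is the maximum |summed t| under random within-subject
# condition swaps (sign flips of the subject difference maps). With n
# subjects and 2^n <= nPermutations the sign assignments are enumerated
# exhaustively and the p-values are exact.

#' Build the spatial adjacency graph of a montage
#'
#' Electrodes whose Euclidean distance is at most \code{thresholdCm} are
#' neighbours.
#'
#' @param montage montage data.frame (label, x_cm, y_cm, z_cm).
#' @param thresholdCm neighbour distance threshold (cm).
#' @return an [AdjacencyGraph-class]
#' @export
buildAdjacency <- function(montage, thresholdCm = 5) {
  xyz <- as.matrix(montage[, c("x_cm", "y_cm", "z_cm")])
  if (any(!is.finite(xyz))) stop("missing electrode coordinate")
  d <- as.matrix(dist(xyz))
  ij <- which(upper.tri(d) & d <= thresholdCm, arr.ind = TRUE)
  colnames(ij) <- NULL
  new("AdjacencyGraph", labels = montage$label, coords = xyz,
      edges = ij, thresholdCm = thresholdCm)
}

#' Neighbour index lists of an adjacency graph
#' @param adjacency an [AdjacencyGraph-class].
#' @return list of integer neighbour indices per channel
#' @export
adjacencyNeighbors <- function(adjacency) {
  n <- length(adjacency@labels)
  nb <- vector("list", n)
  for (i in seq_len(n)) nb[[i]] <- integer(0)
  e <- adjacency@edges
  for (k in seq_len(nrow(e))) {
    nb[[e[k, 1]]] <- c(nb[[e[k, 1]]], e[k, 2])
    nb[[e[k, 2]]] <- c(nb[[e[k, 2]]], e[k, 1])
  }
  nb
}

# subject-wise difference matrix: subjects x (channels*samples),
# channel-fastest cell order
.diffMatrix <- function(condA, condB) {
  stopifnot(identical(dim(condA), dim(condB)), length(dim(condA)) == 3)
  n <- dim(condA)[1]
  D <- condA - condB
  dim(D) <- c(n, dim(condA)[2] * dim(condA)[3])
  D
}

# t statistics for rows of sign matrix S against difference matrix D;
# zero-variance cells with non-zero mean get a fixed +-1e6 sentinel (larger
# than any realistic finite t, and identical for observed and permuted maps
# so the max-statistic comparison stays consistent)
.tFromSigns <- function(S, D, sentinel = 1e6) {
  n <- ncol(S)
  M <- (S %*% D) / n
  ss <- rep(colSums(D^2), each = nrow(S))
  varp <- (ss - n * M^2) / (n - 1)
  varp[varp < 0] <- 0
  t <- M / sqrt(varp / n)
  bad <- varp == 0
  if (any(bad)) {
    t[bad] <- sign(M[bad]) * sentinel
    message(sum(bad), " zero-variance cells set to the max-magnitude sentinel")
  }
  t
}

#' Dependent-samples t-map between two conditions
#'
#' One-sample t statistics of the per-subject differences at every
#' channel x sample cell. Cells with zero difference variance and non-zero
#' mean are set to a max-magnitude sentinel (and logged); zero-mean
#' zero-variance cells give t = 0.
#'
#' @param condA,condB numeric arrays, subjects x channels x samples
#'   (subject-matched).
#' @return channels x samples t matrix
#' @export
pairedTMap <- function(condA, condB) {
  D <- .diffMatrix(condA, condB)
  n <- nrow(D)
  if (n < 2) stop("need at least 2 subjects")
  t <- .tFromSigns(matrix(1, 1, n), D)
  m <- matrix(t, dim(condA)[2], dim(condA)[3])
  if (!is.null(dimnames(condA)[[2]])) rownames(m) <- dimnames(condA)[[2]]
  m
}

#' Spatiotemporal cluster-based permutation test
#'
#' @param condA,condB subjects x channels x samples arrays (matched
#'   subjects; channel order must follow the adjacency graph's labels).
#' @param adjacency an [AdjacencyGraph-class].
#' @param nPermutations Monte-Carlo permutations; when 2^nSubjects is no
#'   larger, all sign assignments are enumerated instead and the p-values
#'   are exact. Fewer than 100 draws a warning.
#' @param alpha significance level for flagging clusters.
#' @param clusterAlpha alpha of the two-tailed parametric t threshold that
#'   forms clusters.
#' @param seed optional integer seed for the Monte-Carlo draws.
#' @param timesMs optional sample times (ms) stored in the result.
#' @return a [ClusterResult-class]
#' @export
clusterPermutationTest <- function(condA, condB, adjacency,
                                   nPermutations = 1000, alpha = 0.05,
                                   clusterAlpha = 0.05, seed = NULL,
                                   timesMs = NULL) {
  if (nPermutations < 100) warning("fewer than 100 permutations")
  if (!is.null(seed)) set.seed(seed)
  n <- dim(condA)[1]
  nch <- dim(condA)[2]
  ns <- dim(condA)[3]
  if (nch != length(adjacency@labels))
    stop("data channels do not match the adjacency graph")
  if (is.null(timesMs)) timesMs <- seq_len(ns) - 1
  D <- .diffMatrix(condA, condB)
  thr <- qt(1 - clusterAlpha / 2, df = n - 1)
  nb <- adjacencyNeighbors(adjacency)

  tObs <- matrix(.tFromSigns(matrix(1, 1, n), D), nch, ns)
  lab <- .clusterLabel(tObs, thr, nb)
  nClus <- length(lab$sums)
  clusters <- vector("list", nClus)
  if (nClus) {
    cellIdx <- which(lab$labels > 0)
    byLab <- split(cellIdx, lab$labels[cellIdx])
    for (k in seq_len(nClus)) {
      cells <- byLab[[as.character(k)]]
      clusters[[k]] <- data.frame(
        channel = as.integer((cells - 1) %% nch + 1),
        sample = as.integer((cells - 1) %/% nch + 1))
    }
  }
  summedT <- as.numeric(lab$sums)

  exhaustive <- 2^n <= nPermutations
  if (exhaustive) {
    S <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
    colnames(S) <- NULL
    nPerm <- nrow(S)
  } else {
    nPerm <- nPermutations
    S <- matrix(sample(c(1, -1), nPerm * n, replace = TRUE), nPerm, n)
  }
  tPerm <- .tFromSigns(S, D)
  maxNull <- .permMaxClusterSums(tPerm, nch, ns, thr, nb)

  pValues <- if (nClus) {
    vapply(summedT, function(st) {
      # tolerance: the identity permutation reproduces the observed summed
      # t only up to floating-point accumulation order
      tol <- 1e-8 * max(1, abs(st))
      hits <- sum(maxNull >= abs(st) - tol)
      if (exhaustive) hits / nPerm else (hits + 1) / (nPerm + 1)
    }, 0)
  } else numeric(0)

  new("ClusterResult", clusters = clusters, summedT = summedT,
      pValues = pValues, significant = pValues <= alpha, tMap = tObs,
      threshold = thr, alpha = alpha, nPermutations = as.integer(nPerm),
      exhaustive = exhaustive,
      channels = adjacency@labels, timesMs = as.numeric(timesMs))
}
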