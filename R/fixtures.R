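#' Synthetic clustered network + expression fixture
#'
#' Generates a planted-partition graph with a matched node-attribute matrix,
#' emulating a modular interaction network whose modules carry distinct
#' expression signatures (e.g. tissue-specific genes): edges are drawn
#' independently with probability `pWithin` inside a cluster and `pBetween`
#' between clusters; each cluster's profile is elevated by `effect` in its
#' own block of samples, plus Gaussian noise; cells are deleted
#' independently at `missingRate`. Fully deterministic for a given seed.
#'
#' @param nClusters number of planted clusters.
#' @param nodesPerCluster nodes in each cluster.
#' @param pWithin,pBetween within/between-cluster edge probabilities
#'   (`pWithin > pBetween`).
#' @param nSamples number of attribute columns; split as evenly as possible
#'   into one block per cluster.
#' @param effect mean shift of a cluster in its own sample block.
#' @param noiseSd standard deviation of the additive Gaussian noise (> 0).
#' @param missingRate independent cell-deletion probability in \[0, 1).
#' @param seed RNG seed.
#' @return list with `network` (igraph), `data` (numeric matrix, `NA` for
#'   missing) and `labels` (named integer cluster assignment).
#' @export
generateFixture <- function(nClusters = 3L, nodesPerCluster = 20L,
                            pWithin = 0.3, pBetween = 0.02,
                            nSamples = 12L, effect = 3.0, noiseSd = 1.0,
                            missingRate = 0, seed = 1L) {
  if (pWithin <= pBetween) stop("pWithin must exceed pBetween")
  if (noiseSd <= 0) stop("noiseSd must be positive")
  if (missingRate < 0 || missingRate >= 1) stop("missingRate must be in [0, 1)")
  n <- nClusters * nodesPerCluster
  if (n < 2L || nSamples < 1L) stop("parameters imply an empty fixture")
  ids <- sprintf("n%03d", seq_len(n))
  labels <- rep(seq_len(nClusters), each = nodesPerCluster)
  names(labels) <- ids
  # local RNG scope: restore the caller's RNG state afterwards
  oldSeed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(oldSeed)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", oldSeed, envir = globalenv())
  })
  set.seed(seed)
  from <- character(); to <- character()
  for (i in seq_len(n - 1L)) {
    p <- ifelse(labels[(i + 1L):n] == labels[i], pWithin, pBetween)
    hit <- which(stats::runif(n - i) < p)
    if (length(hit)) {
      from <- c(from, rep(ids[i], length(hit)))
      to <- c(to, ids[i + hit])
    }
  }
  network <- buildGraph(ids, from, to)
  blocks <- split(seq_len(nSamples),
                  sort(rep_len(seq_len(nClusters), nSamples)))
  mean <- matrix(0, n, nSamples)
  for (cl in seq_len(nClusters))
    mean[labels == cl, blocks[[cl]]] <- effect
  data <- mean + matrix(stats::rnorm(n * nSamples, sd = noiseSd), n, nSamples)
  dimnames(data) <- list(ids, sprintf("s%02d", seq_len(nSamples)))
  if (missingRate > 0) {
    drop <- matrix(stats::runif(n * nSamples) < missingRate, n, nSamples)
    # never blank out an entire row
    fullRow <- rowSums(!drop) == 0L
    drop[fullRow, 1] <- FALSE
    data[drop] <- NA_real_
  }
  list(network = network, data = data, labels = labels)
}

#' Generate a rigid pair of layouts
#'
#' Draws a random layout and returns it together with an exact rigid
#' transform of itself (rotation by `angle`, optional mirror, plus a fixed
#' translation); pairwise distances are identical between the two, which
#' makes the pair an exact-recovery oracle for [alignLayouts()].
#'
#' @param n number of nodes (at least 2).
#' @param angle rotation angle in radians.
#' @param mirrored whether to reflect the x axis before rotating.
#' @param seed RNG seed.
#' @return list with `source` and `reference` layouts.
#' @export
generateRigidPair <- function(n, angle = pi / 4, mirrored = FALSE, seed = 1L) {
  if (n < 2L) stop("need at least 2 nodes")
  oldSeed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(oldSeed)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", oldSeed, envir = globalenv())
  })
  set.seed(seed)
  src <- matrix(stats::rnorm(2 * n, sd = 5), n, 2,
                dimnames = list(sprintf("n%03d", seq_len(n)), c("x", "y")))
  tr <- new("AlignmentTransform", angle = angle, mirrored = mirrored,
            translation = c(3.5, -2.25))
  list(source = src, reference = applyTransform(tr, src))
}
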