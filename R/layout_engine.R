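#' Layout post-processing configuration
#'
#' Thresholds for the three post-processing steps applied to a raw
#' projection: overlap jitter, outlier pull-in, and placement of nodes
#' excluded for missing data. Length scales are fractions of the layout's
#' bounding-box diagonal so behaviour is invariant to layout scale.
#'
#' @param overlapEpsilon two nodes closer than this fraction of the
#'   diagonal count as overlapping.
#' @param jitterRadius displacement radius for overlap jitter, as a
#'   fraction of the diagonal.
#' @param outlierFactor a node is an outlier when its distance to the
#'   barycenter exceeds this multiple of the median distance.
#' @param seed RNG seed for the jitter directions.
#' @return a list of class `PostprocessConfig`.
#' @export
postprocessConfig <- function(overlapEpsilon = 1e-3, jitterRadius = 5e-3,
                              outlierFactor = 6.0, seed = 1L) {
  stopifnot(overlapEpsilon > 0, jitterRadius > 0, outlierFactor > 0)
  structure(list(overlapEpsilon = overlapEpsilon, jitterRadius = jitterRadius,
                 outlierFactor = outlierFactor, seed = as.integer(seed)),
            class = "PostprocessConfig")
}

boundingDiagonal <- function(layout) {
  rng <- apply(layout, 2, range)
  sqrt(sum((rng[2, ] - rng[1, ])^2))
}

#' Jitter overlapping nodes
#'
#' Nodes whose pairwise distance falls below `overlapEpsilon` times the
#' bounding-box diagonal are each displaced by `jitterRadius` times the
#' diagonal in a random direction (seeded), so coincident nodes — e.g.
#' nodes with identical data vectors — become distinguishable. No node
#' moves farther than the jitter radius.
#'
#' @param layout n x 2 coordinate matrix with node IDs as rownames.
#' @param config a [postprocessConfig()].
#' @return the jittered layout.
#' @export
jitterOverlaps <- function(layout, config = postprocessConfig()) {
  layout <- asLayout(layout)
  n <- nrow(layout)
  if (n < 2L) return(layout)
  diag0 <- boundingDiagonal(layout)
  if (diag0 == 0) diag0 <- 1 # all nodes coincident: use unit scale
  eps <- config$overlapEpsilon * diag0
  d <- as.matrix(stats::dist(layout))
  overlapping <- which(apply(d + diag(Inf, n), 1, min) < eps)
  if (length(overlapping) == 0L) return(layout)
  rng <- seededRng(config$seed)
  for (i in overlapping) {
    theta <- rng() * 2 * pi
    layout[i, ] <- layout[i, ] +
      config$jitterRadius * diag0 * c(cos(theta), sin(theta))
  }
  layout
}

#' Pull outliers toward the barycenter
#'
#' A node is an outlier when its distance from the barycenter of all
#' positions exceeds `outlierFactor` times the median distance-to-
#' barycenter. Outliers are moved along the ray toward the barycenter so
#' their distance equals that threshold; all other nodes are untouched, and
#' applying the operation twice equals applying it once.
#'
#' @param layout n x 2 coordinate matrix (at least 3 nodes).
#' @param config a [postprocessConfig()].
#' @return the adjusted layout.
#' @export
pullInOutliers <- function(layout, config = postprocessConfig()) {
  layout <- asLayout(layout)
  if (nrow(layout) < 3L) return(layout)
  ctr <- colMeans(layout)
  d <- sqrt(rowSums(sweep(layout, 2, ctr)^2))
  thr <- config$outlierFactor * stats::median(d)
  out <- which(d > thr)
  for (i in out) {
    layout[i, ] <- ctr + (layout[i, ] - ctr) * (thr / d[i])
  }
  layout
}

#' Place excluded nodes from their neighbours
#'
#' Nodes filtered out for missing data still belong on the picture: each
#' pass places every unplaced node that has at least one placed neighbour
#' at the mean position of those neighbours, using only positions from the
#' previous pass (Jacobi-style, so the result is independent of order
#' within a pass); passes repeat until no more nodes can be placed. Nodes
#' that remain unreachable (isolated, or in a component with no placed
#' node) fall back to the barycenter of all placed nodes.
#'
#' @param layout coordinates of the placed nodes.
#' @param network igraph network containing both placed and excluded nodes.
#' @param excluded character vector of node IDs to place.
#' @return layout covering the placed and excluded nodes.
#' @export
placeExcluded <- function(layout, network, excluded) {
  if (is.matrix(layout) && nrow(layout) == 0L)
    stop("no placed nodes to anchor the excluded ones")
  layout <- asLayout(layout)
  if (length(excluded) == 0L) return(layout)
  ids <- igraph::V(network)$name
  if (!all(excluded %in% ids)) stop("excluded nodes not in network: ",
    paste(setdiff(excluded, ids), collapse = ", "))
  if (nrow(layout) == 0L) stop("no placed nodes to anchor the excluded ones")
  excluded <- sort(excluded)
  unplaced <- setdiff(excluded, rownames(layout))
  pos <- layout
  repeat {
    placedThisPass <- character()
    newPos <- list()
    for (id in unplaced) {
      nbrs <- igraph::neighbors(network, id)$name
      anchored <- intersect(nbrs, rownames(pos))
      if (length(anchored)) {
        newPos[[id]] <- colMeans(pos[anchored, , drop = FALSE])
        placedThisPass <- c(placedThisPass, id)
      }
    }
    if (length(placedThisPass) == 0L) break
    add <- do.call(rbind, newPos[placedThisPass])
    rownames(add) <- placedThisPass
    pos <- rbind(pos, add)
    unplaced <- setdiff(unplaced, placedThisPass)
  }
  if (length(unplaced)) {
    ctr <- colMeans(layout)
    add <- matrix(ctr, length(unplaced), 2, byrow = TRUE,
                  dimnames = list(unplaced, c("x", "y")))
    pos <- rbind(pos, add)
  }
  pos
}

#' Build a layout from a projection
#'
#' Positions the network's nodes at their 2D projection coordinates and
#' applies the three post-processing steps in order: (1) jitter overlapping
#' nodes apart, (2) pull outliers toward the barycenter, (3) place nodes
#' excluded for missing data at the mean of their placed neighbours. With
#' no overlaps, no outliers and no exclusions the result equals the raw
#' projection. Deterministic for a fixed seed.
#'
#' @param projection a [ProjectionResult-class] (first two components are
#'   used) or an n x 2 coordinate matrix.
#' @param network igraph network to lay out.
#' @param excluded node IDs without projection coordinates, to be placed
#'   from neighbours.
#' @param config a [postprocessConfig()].
#' @return n x 2 layout covering every network node.
#' @export
buildLayout <- function(projection, network, excluded = character(),
                        config = postprocessConfig()) {
  coords <- if (is(projection, "ProjectionResult"))
    projCoordinates(projection)[, 1:2, drop = FALSE] else projection
  coords <- asLayout(coords, "projection")
  ids <- igraph::V(network)$name
  stray <- setdiff(rownames(coords), ids)
  if (length(stray))
    stop("projected nodes not in network: ", paste(stray, collapse = ", "))
  needed <- setdiff(ids, excluded)
  missingProj <- setdiff(needed, rownames(coords))
  if (length(missingProj))
    stop("nodes neither projected nor excluded: ",
         paste(missingProj, collapse = ", "))
  lay <- coords[intersect(rownames(coords), needed), , drop = FALSE]
  lay <- jitterOverlaps(lay, config)
  lay <- pullInOutliers(lay, config)
  lay <- placeExcluded(lay, network, setdiff(ids, rownames(lay)))
  lay[ids, , drop = FALSE]
}

# Small deterministic uniform(0,1) generator independent of R's global RNG
# state (keeps package functions from disturbing user RNG).
seededRng <- function(seed) {
  state <- as.double((as.double(seed) + 1) %% 2147483647)
  if (state <= 0) state <- 1
  function() {
    state <<- (state * 48271) %% 2147483647
    state / 2147483647
  }
}
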