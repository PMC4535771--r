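#' Select representative node pairs by farthest-point sampling
#'
#' A full pairwise distance matrix contains many mutually dependent
#' distances, so distance-preservation quality is judged on a representative
#' subset: the first two selected nodes are the globally most distant pair;
#' each subsequent node maximizes its minimum distance to the already
#' selected set (maximin / farthest-point sampling), and contributes the
#' pair (new node, nearest already-selected node). Ties are broken by
#' sorted node ID, making the selection deterministic.
#'
#' Distances between rows with missing values use the observed coordinates
#' only, rescaled by `sqrt(total dims / observed dims)`.
#'
#' @param vectors numeric matrix of node profiles (rownames = node IDs),
#'   `NA` allowed.
#' @param m number of nodes to select (at least 2, at most the node count).
#' @return character matrix with columns `a`, `b`: `m - 1` representative
#'   pairs in selection order.
#' @export
selectRepresentativePairs <- function(vectors, m = min(nrow(vectors), 100L)) {
  if (!is.matrix(vectors) || nrow(vectors) < 3L)
    stop("need at least 3 nodes")
  if (is.null(rownames(vectors))) stop("vectors must have node IDs as rownames")
  if (m < 2L) stop("m must be at least 2")
  m <- min(m, nrow(vectors))
  D <- missingAwareDist(vectors)
  ids <- rownames(vectors)
  if (max(D, na.rm = TRUE) == 0) stop("degenerate distances: all points identical")
  # most distant pair, ID-sorted tie-break
  best <- which(D == max(D), arr.ind = TRUE)
  cand <- t(apply(best, 1, function(ij) sort(ids[ij])))
  cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
  sel <- match(cand[1, ], ids)
  pairs <- matrix(c(ids[sel[1]], ids[sel[2]]), 1, 2)
  while (length(sel) < m) {
    minDist <- apply(D[, sel, drop = FALSE], 1, min)
    minDist[sel] <- -Inf
    top <- which(minDist == max(minDist))
    newNode <- top[order(ids[top])][1]
    nearSel <- sel[which.min(D[newNode, sel])]
    pairs <- rbind(pairs, c(ids[newNode], ids[nearSel]))
    sel <- c(sel, newNode)
  }
  colnames(pairs) <- c("a", "b")
  pairs
}

# Euclidean distance matrix tolerating missing entries: observed-coordinate
# distance scaled by sqrt(p / observed).
missingAwareDist <- function(vectors) {
  obs <- !is.na(vectors)
  if (all(obs)) return(as.matrix(stats::dist(vectors)))
  n <- nrow(vectors)
  p <- ncol(vectors)
  X <- vectors
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    o <- obs[i, ] & obs[j, ]
    if (!any(o)) stop("node pair with no commonly observed coordinates: ",
                      rownames(vectors)[i], ", ", rownames(vectors)[j])
    d2 <- sum((X[i, o] - X[j, o])^2) * p / sum(o)
    D[i, j] <- D[j, i] <- sqrt(d2)
  }
  dimnames(D) <- list(rownames(vectors), rownames(vectors))
  D
}

#' Quality of distance mapping (QDM) of a 2D layout
#'
#' Measures how well a 2D layout preserves the distances of the original
#' multidimensional node profiles: the Pearson correlation between
#' high-dimensional and layout Euclidean distances over the representative
#' pairs of [selectRepresentativePairs()], with a two-sided p-value from
#' the t distribution. A layout driven by the data scores higher than a
#' purely structure-driven one. The statistic is invariant under rigid
#' transforms (rotation, mirror, translation) of the layout.
#'
#' @param vectors numeric matrix of node profiles (rownames = node IDs).
#' @param layout n x 2 layout covering all profiled nodes.
#' @param m number of nodes for the farthest-point sample; defaults to
#'   `min(node count, 100)`.
#' @param allPairs if `TRUE`, correlate over all pairs among the selected
#'   nodes instead of the per-addition representative pairs.
#' @return list with `pairs`, `dHigh`, `d2d`, `pearsonR`, `pValue`.
#' @export
qdm <- function(vectors, layout, m = min(nrow(vectors), 100L),
                allPairs = FALSE) {
  layout <- asLayout(layout)
  missingIds <- setdiff(rownames(vectors), rownames(layout))
  if (length(missingIds))
    stop("layout lacks positions for: ", paste(missingIds, collapse = ", "))
  pairs <- selectRepresentativePairs(vectors, m)
  if (allPairs) {
    sel <- unique(as.vector(pairs))
    cmb <- utils::combn(sort(sel), 2)
    pairs <- cbind(a = cmb[1, ], b = cmb[2, ])
  }
  if (nrow(pairs) < 3L) stop("fewer than 3 representative pairs")
  D <- missingAwareDist(vectors)
  dHigh <- D[pairs]
  d2d <- sqrt(rowSums((layout[pairs[, 1], , drop = FALSE] -
                         layout[pairs[, 2], , drop = FALSE])^2))
  ct <- stats::cor.test(dHigh, d2d, method = "pearson",
                        alternative = "two.sided")
  list(pairs = pairs, dHigh = dHigh, d2d = d2d,
       pearsonR = unname(ct$estimate), pValue = ct$p.value)
}
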