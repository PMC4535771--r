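#' Morph between two layouts
#'
#' Node-wise linear interpolation: a node at \eqn{(x_{11}, x_{12})} in the
#' initial layout and \eqn{(x_{21}, x_{22})} in the target layout is placed
#' at \eqn{(p x_{21} + (1-p) x_{11},\; p x_{22} + (1-p) x_{12})}, so each
#' node moves along the straight line between its two positions. `p = 0`
#' reproduces the initial layout, `p = 1` the target. Morphing a
#' structure-driven layout into a data-driven one (typically after
#' [alignLayouts()]) gives intermediate layouts showing both network
#' structure and data trends.
#'
#' @param layoutA initial layout (n x 2 matrix, node IDs as rownames).
#' @param layoutB target layout over the same node set.
#' @param p morphing fraction in \[0, 1\].
#' @return the interpolated layout, in `layoutA`'s row order.
#' @export
morphLayouts <- function(layoutA, layoutB, p) {
  layoutA <- asLayout(layoutA, "layoutA")
  layoutB <- asLayout(layoutB, "layoutB")
  if (length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop("p must be a single number in [0, 1]")
  onlyA <- setdiff(rownames(layoutA), rownames(layoutB))
  onlyB <- setdiff(rownames(layoutB), rownames(layoutA))
  if (length(onlyA) || length(onlyB))
    stop("layouts cover different node sets; only in A: ",
         paste(onlyA, collapse = ", "), "; only in B: ",
         paste(onlyB, collapse = ", "))
  B <- layoutB[rownames(layoutA), , drop = FALSE]
  out <- p * B + (1 - p) * layoutA
  dimnames(out) <- dimnames(layoutA)
  out
}

#' Align one layout to another by rotation and mirroring
#'
#' Finds the rigid motion — rotation, optional mirror, and translation —
#' that minimizes the sum of squared Euclidean distances between matched
#' nodes of the source and reference layouts (2D orthogonal Procrustes in
#' closed form; both reflection branches are evaluated and the smaller
#' residual wins). No scaling is applied, so distances within the source
#' layout are preserved and subsequent morphing remains meaningful.
#' Centroids of the shared nodes are matched before rotation. The transform
#' is computed over the shared node set and applied to all source nodes.
#'
#' @param source layout to be moved (n x 2 matrix, node IDs as rownames).
#' @param reference layout to align to.
#' @return list with `transform` (an [AlignmentTransform-class]), `aligned`
#'   (the transformed source layout) and `residual` (sum of squared
#'   distances over shared nodes after alignment).
#' @export
alignLayouts <- function(source, reference) {
  source <- asLayout(source, "source")
  reference <- asLayout(reference, "reference")
  shared <- intersect(rownames(source), rownames(reference))
  if (length(shared) < 2L) stop("need at least 2 shared nodes to align")
  S <- source[shared, , drop = FALSE]
  R <- reference[shared, , drop = FALSE]
  sCtr <- colMeans(S)
  rCtr <- colMeans(R)
  Sc <- sweep(S, 2, sCtr)
  Rc <- sweep(R, 2, rCtr)
  if (max(abs(Sc)) == 0) {
    warning("all source points coincident; returning translation-only transform")
    tr <- new("AlignmentTransform", angle = 0, mirrored = FALSE,
              translation = rCtr - sCtr)
    return(list(transform = tr, aligned = applyTransform(tr, source),
                residual = sum(Rc^2)))
  }
  fitBranch <- function(mirror) {
    P <- Sc
    if (mirror) P[, 1] <- -P[, 1]
    # theta maximizing sum cos/sin cross terms
    num <- sum(P[, 1] * Rc[, 2] - P[, 2] * Rc[, 1])
    den <- sum(P[, 1] * Rc[, 1] + P[, 2] * Rc[, 2])
    theta <- atan2(num, den)
    Rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
    resid <- sum((P %*% t(Rot) - Rc)^2)
    list(theta = theta, resid = resid)
  }
  plain <- fitBranch(FALSE)
  flipped <- fitBranch(TRUE)
  mirrored <- flipped$resid < plain$resid
  best <- if (mirrored) flipped else plain
  # translation so that the shared-node centroid maps onto the reference's:
  # aligned = Rot(Mirror(x)) + t with t = rCtr - Rot(Mirror(sCtr))
  theta <- best$theta
  Rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  sCtrM <- if (mirrored) c(-sCtr[1], sCtr[2]) else sCtr
  translation <- rCtr - as.numeric(Rot %*% sCtrM)
  tr <- new("AlignmentTransform", angle = theta, mirrored = mirrored,
            translation = translation)
  list(transform = tr, aligned = applyTransform(tr, source),
       residual = best$resid)
}
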