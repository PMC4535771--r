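#' @import methods
NULL

#' SmoothingBasis: Laplacian eigenbasis of a network
#'
#' Holds the full eigendecomposition of the unnormalized graph Laplacian
#' \eqn{L = D - A} of a network, sorted by ascending eigenvalue. The first
#' `nc` eigenvalues are zero (one per connected component) and their
#' eigenspace is spanned by the component indicator vectors. Columns of
#' `vectors` are orthonormal eigenvectors over the nodes, in the node order
#' given by `nodeIds`.
#'
#' @slot values numeric vector of eigenvalues, ascending.
#' @slot vectors numeric matrix, one column per eigenvector, rows = nodes.
#' @slot nodeIds character vector of node identifiers (row order of `vectors`).
#' @slot nc integer, number of connected components of the graph.
#' @slot graphHash character, fingerprint of the graph the basis was
#'   computed from; used to refuse a cached basis for a different graph.
#'
#' @seealso [laplacianBasis()], [saveBasis()], [loadBasis()], [smoothMatrix()]
#' @export
setClass("SmoothingBasis",
  representation(
    values = "numeric",
    vectors = "matrix",
    nodeIds = "character",
    nc = "integer",
    graphHash = "character"
  )
)

setValidity("SmoothingBasis", function(object) {
  msgs <- character()
  N <- length(object@nodeIds)
  if (nrow(object@vectors) != N || ncol(object@vectors) != N)
    msgs <- c(msgs, sprintf("eigenvector matrix must be %d x %d", N, N))
  if (length(object@values) != N)
    msgs <- c(msgs, "one eigenvalue per node required")
  if (is.unsorted(object@values, strictly = FALSE))
    msgs <- c(msgs, "eigenvalues must be ascending")
  if (length(object@nc) != 1L || object@nc < 1L || object@nc > max(N, 1L))
    msgs <- c(msgs, "nc must be a single integer in [1, N]")
  if (length(msgs) == 0L) {
    tol <- 1e-8
    if (any(abs(object@values[seq_len(object@nc)]) > 1e-6))
      msgs <- c(msgs, "first nc eigenvalues must be zero")
    G <- crossprod(object@vectors)
    if (max(abs(G - diag(N))) > tol)
      msgs <- c(msgs, "eigenvectors must be orthonormal (tolerance 1e-8)")
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn SmoothingBasis-class compact display
#' @param object a `SmoothingBasis`
#' @export
setMethod("show", "SmoothingBasis", function(object) {
  cat(sprintf(
    "SmoothingBasis: %d nodes, %d connected component(s)\n",
    length(object@nodeIds), object@nc
  ))
  cat(sprintf(
    "  eigenvalues: %.4g .. %.4g\n",
    object@values[1], object@values[length(object@values)]
  ))
  invisible(object)
})

#' Accessors for SmoothingBasis
#'
#' @param x a [SmoothingBasis-class] object.
#' @return `basisValues`: eigenvalues (ascending); `basisVectors`: eigenvector
#'   matrix (columns orthonormal); `basisNodeIds`: node identifiers;
#'   `componentCount`: number of connected components.
#' @export
basisValues <- function(x) x@values

#' @rdname basisValues
#' @export
basisVectors <- function(x) x@vectors

#' @rdname basisValues
#' @export
basisNodeIds <- function(x) x@nodeIds

#' @rdname basisValues
#' @export
componentCount <- function(x) {
  if (is(x, "SmoothingBasis")) return(x@nc)
  if (inherits(x, "igraph")) return(igraph::count_components(x))
  stop("componentCount: expected a SmoothingBasis or an igraph object")
}

#' ProjectionResult: low-dimensional node coordinates
#'
#' Coordinates of network nodes after dimension reduction, together with the
#' fraction of data variance explained. For PCA the fractions are
#' per-component and non-increasing; for the elastic map a single fraction
#' (variance explained by the fitted 2D manifold) is reported.
#'
#' @slot coordinates numeric matrix, one row per retained node (rownames are
#'   node IDs), `d <= 10` columns.
#' @slot varianceExplained numeric vector of fractions in \[0, 1\].
#' @slot method character, `"pca"` or `"elmap"`.
#'
#' @seealso [pcaMissing()], [elasticMap()], [varianceReport()]
#' @export
setClass("ProjectionResult",
  representation(
    coordinates = "matrix",
    varianceExplained = "numeric",
    method = "character"
  )
)

setValidity("ProjectionResult", function(object) {
  msgs <- character()
  if (!object@method %in% c("pca", "elmap"))
    msgs <- c(msgs, "method must be 'pca' or 'elmap'")
  if (is.null(rownames(object@coordinates)))
    msgs <- c(msgs, "coordinates must have node IDs as rownames")
  if (ncol(object@coordinates) > 10L)
    msgs <- c(msgs, "at most 10 components supported")
  ve <- object@varianceExplained
  if (any(ve < -1e-8))
    msgs <- c(msgs, "variance fractions must be non-negative")
  if (sum(ve) > 1 + 1e-8)
    msgs <- c(msgs, "variance fractions must sum to at most 1")
  if (identical(object@method, "pca") && length(ve) > 1L &&
      any(diff(ve) > 1e-8))
    msgs <- c(msgs, "PCA variance fractions must be non-increasing")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn ProjectionResult-class compact display
#' @param object a `ProjectionResult`
#' @export
setMethod("show", "ProjectionResult", function(object) {
  cat(sprintf(
    "ProjectionResult (%s): %d nodes x %d component(s)\n",
    object@method, nrow(object@coordinates), ncol(object@coordinates)
  ))
  cat("  variance explained:",
      paste(sprintf("%.3f", object@varianceExplained), collapse = " "), "\n")
  invisible(object)
})

#' Accessors for ProjectionResult
#'
#' @param x a [ProjectionResult-class] object.
#' @return `projCoordinates`: the coordinate matrix; `varianceExplained`: the
#'   per-component variance fractions; `projMethod`: the method string.
#' @export
projCoordinates <- function(x) x@coordinates

#' @rdname projCoordinates
#' @export
varianceExplained <- function(x) x@varianceExplained

#' @rdname projCoordinates
#' @export
projMethod <- function(x) x@method

#' AlignmentTransform: rigid 2D motion aligning one layout to another
#'
#' A rotation by `angle`, an optional mirror (reflection of the x axis prior
#' to rotation), and a translation. Applying the transform preserves all
#' pairwise distances: no scaling is performed, so morphing distances remain
#' meaningful after alignment.
#'
#' @slot angle rotation angle in radians.
#' @slot mirrored logical, whether the source is reflected before rotation.
#' @slot translation numeric length-2 vector applied after rotation.
#'
#' @seealso [alignLayouts()], [applyTransform()]
#' @export
setClass("AlignmentTransform",
  representation(
    angle = "numeric",
    mirrored = "logical",
    translation = "numeric"
  )
)

setValidity("AlignmentTransform", function(object) {
  msgs <- character()
  if (length(object@angle) != 1L || !is.finite(object@angle))
    msgs <- c(msgs, "angle must be a single finite number")
  if (length(object@mirrored) != 1L || is.na(object@mirrored))
    msgs <- c(msgs, "mirrored must be TRUE or FALSE")
  if (length(object@translation) != 2L || any(!is.finite(object@translation)))
    msgs <- c(msgs, "translation must be a finite length-2 vector")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn AlignmentTransform-class compact display
#' @param object an `AlignmentTransform`
#' @export
setMethod("show", "AlignmentTransform", function(object) {
  cat(sprintf(
    "AlignmentTransform: angle %.4f rad, mirrored %s, translation (%.4g, %.4g)\n",
    object@angle, object@mirrored, object@translation[1], object@translation[2]
  ))
  invisible(object)
})

#' Apply a rigid alignment transform to a layout
#'
#' @param transform an [AlignmentTransform-class].
#' @param layout an n x 2 coordinate matrix with node IDs as rownames.
#' @return the transformed layout (same shape and rownames).
#' @export
applyTransform <- function(transform, layout) {
  stopifnot(is(transform, "AlignmentTransform"))
  layout <- asLayout(layout)
  P <- layout
  if (transform@mirrored) P[, 1] <- -P[, 1]
  th <- transform@angle
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  out <- P %*% t(R)
  out[, 1] <- out[, 1] + transform@translation[1]
  out[, 2] <- out[, 2] + transform@translation[2]
  dimnames(out) <- dimnames(layout)
  out
}

# Coerce/validate a layout: n x 2 numeric matrix, rownames = node IDs,
# finite coordinates.
asLayout <- function(x, what = "layout") {
  if (is.data.frame(x)) {
    ids <- if ("id" %in% names(x)) as.character(x$id) else rownames(x)
    x <- as.matrix(x[, setdiff(names(x), "id"), drop = FALSE])
    rownames(x) <- ids
  }
  if (!is.matrix(x) || !is.numeric(x) || ncol(x) != 2L)
    stop(what, " must be an n x 2 numeric matrix")
  if (is.null(rownames(x)))
    stop(what, " must have node IDs as rownames")
  if (any(!is.finite(x)))
    stop(what, " contains non-finite coordinates")
  colnames(x) <- c("x", "y")
  x
}
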