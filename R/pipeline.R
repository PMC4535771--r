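#' End-to-end data-driven layout
#'
#' Chains the full pipeline: restrict the data matrix to network nodes,
#' filter rows with too many missing values, optionally double-center,
#' optionally network-smooth (projection onto the first `k` Laplacian
#' eigenvectors, `k` derived from `pns`), reduce to 2D by PCA or elastic
#' map, and post-process the layout (overlap jitter, outlier pull-in,
#' neighbour-mean placement of filtered nodes).
#'
#' Double-centering is applied before smoothing: both are linear and the
#' order is a convention, but centering is a data-cleaning step and
#' smoothing a network-regularization step, so cleaning comes first.
#' Smoothing uses the Laplacian of the subgraph induced by the nodes that
#' retain data, since the projection needs one matrix row per graph node.
#'
#' @param network an igraph network.
#' @param data numeric node x attribute matrix (`NA` for missing).
#' @param method `"pca"` or `"elmap"`.
#' @param pns network-smoothing strength in \[0, 1\]; 0 disables smoothing.
#' @param doubleCenterData whether to double-center before reduction.
#' @param maxMissingFraction row filter threshold (see [filterMissing()]).
#' @param components which two components to use for the layout plane
#'   (PCA only), default `c(1, 2)`.
#' @param emConfig an [elasticMapConfig()] (elastic map only).
#' @param postConfig a [postprocessConfig()].
#' @param basis optional precomputed [SmoothingBasis-class] for the induced
#'   subgraph (e.g. from [loadBasis()]); computed fresh when `NULL`.
#' @return list with `layout` (n x 2 over all network nodes), `projection`
#'   (the [ProjectionResult-class]), `excluded` (node IDs placed from
#'   neighbours), and `k` (eigenvectors kept; `NA` without smoothing).
#' @examples
#' fx <- generateFixture(seed = 7)
#' res <- dataDrivenLayout(fx$network, fx$data, method = "pca", pns = 0.5)
#' head(res$layout)
#' @export
dataDrivenLayout <- function(network, data, method = c("pca", "elmap"),
                             pns = 0, doubleCenterData = FALSE,
                             maxMissingFraction = 0.20,
                             components = c(1L, 2L),
                             emConfig = elasticMapConfig(),
                             postConfig = postprocessConfig(),
                             basis = NULL) {
  method <- match.arg(method)
  data <- matchToNetwork(data, network)
  flt <- filterMissing(data, maxMissingFraction)
  mat <- flt$kept
  if (doubleCenterData) mat <- doubleCenter(mat)
  k <- NA_integer_
  if (pns > 0) {
    sub <- igraph::induced_subgraph(network, rownames(mat))
    if (is.null(basis)) basis <- laplacianBasis(sub)
    k <- kFromPns(pns, length(basisNodeIds(basis)), componentCount(basis))
    mat <- smoothMatrix(mat, basis, k = k)
  }
  if (method == "pca") {
    proj <- pcaMissing(mat)
    nc <- ncol(projCoordinates(proj))
    components <- as.integer(components)
    if (any(components < 1L) || any(components > nc))
      stop("requested components outside the computed range 1..", nc)
    plane <- projCoordinates(proj)[, components, drop = FALSE]
  } else {
    proj <- elasticMap(mat, emConfig)
    plane <- projCoordinates(proj)[, 1:2, drop = FALSE]
  }
  excluded <- setdiff(igraph::V(network)$name, rownames(plane))
  layout <- buildLayout(plane, network, excluded, postConfig)
  list(layout = layout, projection = proj, excluded = excluded, k = k)
}
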