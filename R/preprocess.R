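#' Filter rows with too many missing values
#'
#' A node's profile is excluded when strictly more than
#' `maxMissingFraction` of its entries are missing (the default keeps rows
#' with exactly 20 % missing and drops rows above it). Row order of the kept
#' matrix is preserved.
#'
#' @param mat numeric matrix with `NA` for missing entries.
#' @param maxMissingFraction threshold in \[0, 1).
#' @return list with `kept` (filtered matrix) and `excluded` (dropped IDs).
#' @export
filterMissing <- function(mat, maxMissingFraction = 0.20) {
  if (!is.matrix(mat)) stop("expected a matrix")
  if (maxMissingFraction < 0 || maxMissingFraction >= 1)
    stop("maxMissingFraction must be in [0, 1)")
  frac <- rowMeans(is.na(mat))
  drop <- frac > maxMissingFraction
  if (all(drop)) stop("no usable data points: every row exceeds the missing-value threshold")
  list(
    kept = mat[!drop, , drop = FALSE],
    excluded = rownames(mat)[drop]
  )
}

#' Double-center a data matrix
#'
#' Subtracts from each entry its row mean and its column mean and adds back
#' the global mean, removing additive row/column biases (e.g. probe
#' intensity offsets in microarray data). Means are computed over observed
#' cells only; missing cells stay missing. For a complete matrix every row
#' and column mean of the result is zero.
#'
#' @param mat numeric matrix, `NA` allowed.
#' @return the double-centered matrix.
#' @export
doubleCenter <- function(mat) {
  if (!is.matrix(mat) || nrow(mat) == 0L || ncol(mat) == 0L)
    stop("matrix is empty")
  obsRow <- rowSums(!is.na(mat))
  obsCol <- colSums(!is.na(mat))
  if (any(obsRow == 0L)) stop("row with zero observed cells: ",
                              paste(rownames(mat)[obsRow == 0L], collapse = ", "))
  if (any(obsCol == 0L)) stop("column with zero observed cells: ",
                              paste(colnames(mat)[obsCol == 0L], collapse = ", "))
  rm <- rowMeans(mat, na.rm = TRUE)
  cm <- colMeans(mat, na.rm = TRUE)
  gm <- mean(mat, na.rm = TRUE)
  sweep(sweep(mat, 1, rm), 2, cm) + gm
}

# FNV-1a hash over a canonical graph description (sorted node IDs + sorted
# undirected edge list); identifies the graph a cached basis belongs to.
graphHash <- function(network) {
  ids <- sort(igraph::V(network)$name)
  el <- igraph::as_edgelist(network, names = TRUE)
  edges <- character()
  if (nrow(el)) {
    a <- pmin(el[, 1], el[, 2])
    b <- pmax(el[, 1], el[, 2])
    edges <- sort(paste(a, b, sep = "|"))
  }
  bytes <- utf8ToInt(paste(c(ids, "#", edges), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    # xor the byte into the low 8 bits (h kept as a double in [0, 2^32))
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    # 32-bit multiply by the FNV prime 16777619 without losing precision:
    # split h into 16-bit halves so products stay below 2^53
    hi <- floor(h / 65536)
    lo <- h %% 65536
    h <- ((hi * 16777619) %% 65536) * 65536 + lo * 16777619
    h <- h %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Laplacian eigenbasis of a network
#'
#' Computes the full eigendecomposition of the unnormalized Laplacian
#' \eqn{L = D - A}, with eigenvalues sorted ascending. The graph has exactly
#' `nc` zero eigenvalues (one per connected component) whose eigenspace is
#' spanned by the component indicator vectors; the corresponding
#' eigenvectors are the smoothest functions on the graph and later
#' eigenvectors oscillate increasingly fast.
#'
#' @param network an igraph network (undirected, simple).
#' @return a [SmoothingBasis-class] object.
#' @export
laplacianBasis <- function(network) {
  N <- igraph::vcount(network)
  if (N == 0L) stop("network has an empty node set")
  L <- as.matrix(igraph::laplacian_matrix(network, normalization = "unnormalized"))
  eig <- eigen(L, symmetric = TRUE)
  ord <- order(eig$values) # eigen() returns descending; re-sort ascending
  values <- eig$values[ord]
  vectors <- eig$vectors[, ord, drop = FALSE]
  values[abs(values) < 1e-10] <- 0
  nc <- igraph::count_components(network)
  new("SmoothingBasis",
    values = values,
    vectors = vectors,
    nodeIds = igraph::V(network)$name,
    nc = as.integer(nc),
    graphHash = graphHash(network)
  )
}

#' Number of retained eigenvectors from the smoothing parameter
#'
#' The smoothing strength \eqn{p_{ns} \in [0,1]} maps to the number of
#' retained Laplacian eigenvectors by
#' \deqn{p_{ns} = 1 - \frac{k - (n_c + 2)}{N - (n_c + 2)}}
#' so \eqn{p_{ns} = 0} keeps all \eqn{N} eigenvectors (no smoothing) and
#' \eqn{p_{ns} = 1} keeps \eqn{k = n_c + 2}: the component indicators plus
#' the first two non-degenerate eigenvectors, making the data effectively
#' three-dimensional on a connected graph. Since the formula rarely yields
#' an integer, `k` is rounded half-up and clamped to `[nc + 2, N]`.
#'
#' @param pns smoothing strength in \[0, 1\].
#' @param N number of nodes.
#' @param nc number of connected components.
#' @return integer `k`, the number of eigenvectors to keep.
#' @export
kFromPns <- function(pns, N, nc) {
  if (length(pns) != 1L || is.na(pns) || pns < 0 || pns > 1)
    stop("pns must be a single number in [0, 1]")
  lo <- nc + 2
  if (N <= lo) {
    warning("graph too small for the smoothing parameterization (N <= nc + 2); using k = N")
    return(as.integer(N))
  }
  k <- floor(lo + (1 - pns) * (N - lo) + 0.5) # round half-up
  as.integer(min(max(k, lo), N))
}

#' Network-smooth a data matrix
#'
#' Projects each data column onto the span of the first `k` (smallest
#' eigenvalue) Laplacian eigenvectors, attenuating variation that changes
#' quickly across edges. The operator is an orthogonal projector: applying
#' it twice equals applying it once, and column norms never grow. Output
#' rank is at most `k`.
#'
#' Rows must be complete; missing entries in retained rows are filled with
#' the row's observed mean first (with a warning).
#'
#' @param mat numeric matrix, rows = nodes matching the basis node set.
#' @param basis a [SmoothingBasis-class] from [laplacianBasis()] or
#'   [loadBasis()].
#' @param pns smoothing strength in \[0, 1\]; ignored when `k` is given.
#' @param k number of eigenvectors to keep (overrides `pns`).
#' @return the smoothed matrix, same shape and dimnames, rows in basis node
#'   order.
#' @export
smoothMatrix <- function(mat, basis, pns = NULL, k = NULL) {
  stopifnot(is(basis, "SmoothingBasis"))
  ids <- basis@nodeIds
  if (!setequal(rownames(mat), ids) || nrow(mat) != length(ids))
    stop("matrix rows do not match the basis node set")
  mat <- mat[ids, , drop = FALSE]
  if (anyNA(mat)) {
    warning("missing entries imputed with the row's observed mean before smoothing")
    rm <- rowMeans(mat, na.rm = TRUE)
    if (anyNA(rm)) stop("row with zero observed cells cannot be imputed")
    idx <- which(is.na(mat), arr.ind = TRUE)
    mat[idx] <- rm[idx[, 1]]
  }
  if (is.null(k)) {
    if (is.null(pns)) stop("supply either pns or k")
    k <- kFromPns(pns, length(ids), basis@nc)
  }
  k <- as.integer(k)
  if (k < basis@nc || k > length(ids))
    stop("k out of range [nc, N]")
  V <- basis@vectors[, seq_len(k), drop = FALSE]
  out <- V %*% crossprod(V, mat)
  dimnames(out) <- dimnames(mat)
  out
}

#' Save / load a Laplacian eigenbasis
#'
#' The basis of a large network is expensive to compute (dense
#' eigendecomposition scales as the cube of the node count) but depends only
#' on the graph, so it can be computed once and reused. The cache is a
#' plain-text container holding node IDs, eigenvalues and eigenvectors at
#' full precision, plus a fingerprint of the graph; `loadBasis` validates
#' orthonormality and refuses a file whose fingerprint mismatches the graph
#' it is asked to serve.
#'
#' @param basis a [SmoothingBasis-class].
#' @param path file path for the cache.
#' @return `saveBasis`: the path, invisibly. `loadBasis`: the basis.
#' @export
saveBasis <- function(basis, path) {
  stopifnot(is(basis, "SmoothingBasis"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "ddlayout-basis\t1",
    paste("N", length(basis@nodeIds), sep = "\t"),
    paste("nc", basis@nc, sep = "\t"),
    paste("hash", basis@graphHash, sep = "\t"),
    paste(c("nodes", basis@nodeIds), collapse = "\t"),
    paste(c("values", sprintf("%.17g", basis@values)), collapse = "\t")
  ), con)
  for (i in seq_len(nrow(basis@vectors))) {
    writeLines(paste(c("vec", sprintf("%.17g", basis@vectors[i, ])),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' @param network optional igraph network; when given, the stored graph
#'   fingerprint must match it.
#' @rdname saveBasis
#' @export
loadBasis <- function(path, network = NULL) {
  if (!file.exists(path)) stop("basis cache not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 6L || !startsWith(lines[1], "ddlayout-basis"))
    stop("corrupt basis cache: bad header")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  getField <- function(key) {
    hit <- which(vapply(fields, function(f) f[1] == key, logical(1)))
    if (length(hit) == 0L) stop("corrupt basis cache: missing '", key, "'")
    fields[[hit[1]]][-1]
  }
  N <- as.integer(getField("N"))
  nc <- as.integer(getField("nc"))
  hash <- getField("hash")
  ids <- getField("nodes")
  values <- as.numeric(getField("values"))
  vecRows <- fields[vapply(fields, function(f) f[1] == "vec", logical(1))]
  if (length(ids) != N || length(values) != N || length(vecRows) != N)
    stop("corrupt basis cache: inconsistent dimensions")
  vectors <- t(vapply(vecRows, function(f) as.numeric(f[-1]), numeric(N)))
  if (anyNA(vectors) || anyNA(values))
    stop("corrupt basis cache: non-numeric entries")
  if (!is.null(network) && !identical(graphHash(network), hash))
    stop("basis cache was computed for a different graph (fingerprint mismatch)")
  basis <- new("SmoothingBasis", values = values, vectors = vectors,
               nodeIds = ids, nc = nc, graphHash = hash)
  validObject(basis) # enforces orthonormality on load
  basis
}
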