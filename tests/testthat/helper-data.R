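# shared builders for small in-code fixtures

namedMatrix <- function(values, nrow, ncol) {
  matrix(values, nrow, ncol,
         dimnames = list(sprintf("n%02d", seq_len(nrow)),
                         sprintf("s%02d", seq_len(ncol))))
}

# complete random matrix under a fixed seed, caller's RNG untouched
randomMatrix <- function(nrow, ncol, seed, sd = 1) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  namedMatrix(rnorm(nrow * ncol, sd = sd), nrow, ncol)
}

# small graph from an edge character vector like c("A","B", "B","C")
graphFromPairs <- function(pairs, isolated = character()) {
  m <- matrix(pairs, ncol = 2, byrow = TRUE)
  igraph::graph_from_data_frame(
    data.frame(from = m[, 1], to = m[, 2]),
    directed = FALSE,
    vertices = data.frame(name = unique(c(m[, 1], m[, 2], isolated))))
}

# random connected-ish graph on n nodes (Erdos-Renyi, fixed seed)
randomGraph <- function(n, p, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
  g
}

# classical SVD scores of the column-centered matrix (PCA oracle)
svdScores <- function(X, k) {
  Xc <- scale(X, center = TRUE, scale = FALSE)
  sv <- svd(Xc)
  (sv$u %*% diag(sv$d, length(sv$d)))[, seq_len(k), drop = FALSE]
}

# compare score matrices up to per-component sign
maxSignAdjustedDiff <- function(A, B) {
  max(vapply(seq_len(ncol(A)), function(l) {
    min(max(abs(A[, l] - B[, l])), max(abs(A[, l] + B[, l])))
  }, numeric(1)))
}

randomLayout <- function(n, seed, ids = sprintf("n%02d", seq_len(n))) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  matrix(rnorm(2 * n, sd = 3), n, 2, dimnames = list(ids, c("x", "y")))
}
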