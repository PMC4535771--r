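#' Principal components with missing values
#'
#' Computes principal components of the node x attribute matrix by
#' alternating least squares over observed cells only, so missing values
#' need no pre-imputation. The model is
#' \eqn{x_{ij} \approx m_j + \sum_l u_{il} v_{jl}} with column offsets
#' \eqn{m_j} estimated from observed entries; components are extracted
#' sequentially, each deflated from the residual before the next is fitted
#' (the NIPALS scheme). On complete data the scores coincide with classical
#' SVD scores up to per-component sign.
#'
#' By default 10 components are computed when there are more than 10 data
#' points, and `nrow - 1` otherwise. Each component is oriented so that its
#' largest-magnitude loading is positive, making layouts reproducible
#' across runs and eigensolvers.
#'
#' @param mat numeric matrix (rows = nodes, columns = samples), `NA` for
#'   missing entries; should already have passed [filterMissing()].
#' @param nComponents number of components, or `NULL` for the default rule.
#' @param tol convergence tolerance on the loading vector between
#'   iterations.
#' @param maxIter iteration cap per component.
#' @return a [ProjectionResult-class] with method `"pca"`; scores in
#'   `projCoordinates()`, per-component variance fractions in
#'   `varianceExplained()`.
#' @export
pcaMissing <- function(mat, nComponents = NULL, tol = 1e-9, maxIter = 20000L) {
  if (!is.matrix(mat) || nrow(mat) < 2L)
    stop("need at least 2 rows for PCA")
  if (is.null(rownames(mat))) stop("matrix must have node IDs as rownames")
  obs <- !is.na(mat)
  if (any(rowSums(obs) == 0L)) stop("row with no observed values")
  if (any(colSums(obs) == 0L)) stop("column with no observed values")
  n <- nrow(mat)
  if (is.null(nComponents)) nComponents <- if (n > 10L) 10L else n - 1L
  nComponents <- min(as.integer(nComponents), n - 1L, ncol(mat), 10L)
  if (nComponents < 1L) stop("no components requested")

  m <- colMeans(mat, na.rm = TRUE)
  X <- sweep(mat, 2, m)
  X[!obs] <- 0 # residual storage; observed mask carried separately
  tss <- sum(X[obs]^2)
  if (tss == 0) stop("matrix has no variance after centering")

  scores <- matrix(0, n, nComponents,
                   dimnames = list(rownames(mat), paste0("PC", seq_len(nComponents))))
  ve <- numeric(nComponents)
  rssPrev <- tss
  for (l in seq_len(nComponents)) {
    # start from the column with the largest residual sum of squares
    v <- numeric(ncol(X))
    j0 <- which.max(colSums(X^2))
    v[j0] <- 1
    u <- numeric(n)
    for (it in seq_len(maxIter)) {
      vOld <- v
      # u_i = sum_obs x_ij v_j / sum_obs v_j^2
      num <- X %*% v
      den <- obs %*% (v^2)
      u <- as.numeric(num) / pmax(as.numeric(den), .Machine$double.eps)
      # v_j = sum_obs x_ij u_i / sum_obs u_i^2
      num <- crossprod(X, u)
      den <- crossprod(obs, u^2)
      v <- as.numeric(num) / pmax(as.numeric(den), .Machine$double.eps)
      nv <- sqrt(sum(v^2))
      if (nv == 0) break
      v <- v / nv
      if (sqrt(sum((v - vOld)^2)) < tol) break
      if (it == maxIter)
        stop(sprintf("component %d did not converge to tolerance %g in %d iterations",
                     l, tol, maxIter))
    }
    # orient: largest-magnitude loading positive
    jmax <- which.max(abs(v))
    if (v[jmax] < 0) { v <- -v; u <- -u }
    fit <- outer(u, v)
    X <- X - fit
    X[!obs] <- 0
    rss <- sum(X[obs]^2)
    ve[l] <- max(rssPrev - rss, 0) / tss
    rssPrev <- rss
    scores[, l] <- u
  }
  # order components by decreasing variance (extraction order can deviate
  # slightly when cells are missing)
  ord <- order(ve, decreasing = TRUE)
  scores <- scores[, ord, drop = FALSE]
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  new("ProjectionResult", coordinates = scores,
      varianceExplained = ve[ord], method = "pca")
}

#' Elastic-map configuration
#'
#' The elastic map fits a regular 2D grid ("principal manifold") to the
#' data by minimizing approximation error plus stretching and bending
#' penalties; annealing the penalties from stiff to soft lets the grid
#' first find the global orientation (the PCA plane) and then bend into the
#' data. Energies are
#' \eqn{U = U_{approx} + \lambda U_{stretch} + \mu U_{bend}} with
#' \eqn{U_{approx} = \sum_i \|x_i - y_{k(i)}\|^2} over nearest grid nodes,
#' \eqn{U_{stretch} = \sum_{edges} \|y_a - y_b\|^2}, and
#' \eqn{U_{bend} = \sum_{ribs} \|y_a - 2 y_b + y_c\|^2} over consecutive
#' collinear grid triples.
#'
#' @param gridRows,gridCols grid dimensions (each at least 2); default
#'   12 x 12.
#' @param schedule list of epochs, each `c(lambda, mu, iterations)`, run in
#'   order; the default anneals (1, 10) to (0.1, 1) to (0.01, 0.1), 20
#'   iterations each.
#' @param seed integer kept for reproducibility bookkeeping (the fit itself
#'   is deterministic: grid initialization comes from the PCA plane).
#' @return a list of class `ElasticMapConfig`.
#' @export
elasticMapConfig <- function(gridRows = 12L, gridCols = 12L,
                             schedule = list(c(1.0, 10.0, 20L),
                                             c(0.1, 1.0, 20L),
                                             c(0.01, 0.1, 20L)),
                             seed = 1L) {
  if (gridRows < 2L || gridCols < 2L) stop("grid must be at least 2 x 2")
  if (length(schedule) == 0L) stop("annealing schedule must be nonempty")
  for (ep in schedule) {
    if (length(ep) != 3L || ep[1] <= 0 || ep[2] <= 0 || ep[3] < 1)
      stop("each epoch must be c(lambda > 0, mu > 0, iterations >= 1)")
  }
  structure(list(gridRows = as.integer(gridRows),
                 gridCols = as.integer(gridCols),
                 schedule = schedule, seed = as.integer(seed)),
            class = "ElasticMapConfig")
}

# Stretch (grid-graph Laplacian) and bend (second-difference Gram) matrices
# for an R x C grid, node index g = (col - 1) * R + row.
gridPenaltyMatrices <- function(R, C) {
  g <- R * C
  idx <- function(r, c) (c - 1L) * R + r
  E <- matrix(0, g, g)
  addEdge <- function(a, b) {
    E[a, a] <<- E[a, a] + 1; E[b, b] <<- E[b, b] + 1
    E[a, b] <<- E[a, b] - 1; E[b, a] <<- E[b, a] - 1
  }
  for (c in seq_len(C)) for (r in seq_len(R - 1L)) addEdge(idx(r, c), idx(r + 1L, c))
  for (c in seq_len(C - 1L)) for (r in seq_len(R)) addEdge(idx(r, c), idx(r, c + 1L))
  S <- matrix(0, g, g)
  addRib <- function(a, b, cc) {
    w <- c(1, -2, 1); ids <- c(a, b, cc)
    for (p in 1:3) for (q in 1:3) S[ids[p], ids[q]] <<- S[ids[p], ids[q]] + w[p] * w[q]
  }
  for (c in seq_len(C)) for (r in seq_len(R - 2L))
    addRib(idx(r, c), idx(r + 1L, c), idx(r + 2L, c))
  for (c in seq_len(C - 2L)) for (r in seq_len(R))
    addRib(idx(r, c), idx(r, c + 1L), idx(r, c + 2L))
  list(E = E, S = S)
}

#' Fit a 2D elastic-map principal manifold
#'
#' Fits a rectangular grid to the node profiles by expectation-maximization:
#' each iteration assigns every data point to its nearest grid node, then
#' solves the linear system that minimizes the total elastic energy for that
#' assignment (so the energy never increases within an epoch), annealing the
#' elasticity coefficients down the schedule. The grid is initialized on the
#' plane of the first two principal components spanning the data.
#'
#' Missing entries are handled without imputation: distances use observed
#' coordinates only, rescaled by the ratio of total to observed dimensions.
#'
#' The returned 2D coordinate of a data point is its piecewise-linear
#' projection onto the fitted manifold, expressed in internal grid
#' coordinates scaled to data units (the initial grid spacing along each
#' axis), so that for near-planar data the coordinates are comparable to
#' PCA scores. The variance explained is `1 - RSS / TSS` with residuals
#' taken to the projection point, not the nearest grid node.
#'
#' @param mat numeric matrix (rows = nodes), `NA` allowed.
#' @param config an [elasticMapConfig()] list.
#' @return a [ProjectionResult-class] with method `"elmap"`; variance
#'   explained is a single fraction for the whole manifold, and the
#'   per-iteration total energies (one numeric vector per epoch) are
#'   attached as attribute `"energy"` of the coordinate matrix.
#' @export
elasticMap <- function(mat, config = elasticMapConfig()) {
  if (!inherits(config, "ElasticMapConfig")) stop("config must come from elasticMapConfig()")
  if (!is.matrix(mat) || nrow(mat) < 3L) stop("need at least 3 data points")
  if (is.null(rownames(mat))) stop("matrix must have node IDs as rownames")
  obs <- !is.na(mat)
  if (any(rowSums(obs) == 0L)) stop("row with no observed values")
  p <- ncol(mat)
  n <- nrow(mat)
  # per-row weight: dimension-ratio rescaling for missing coordinates
  w <- p / rowSums(obs)
  m <- colMeans(mat, na.rm = TRUE)
  Xc <- sweep(mat, 2, m)
  X0 <- Xc; X0[!obs] <- 0
  if (max(abs(X0)) == 0) stop("degenerate data: a single distinct point")

  # initialize the grid on the PCA plane spanning the data
  pc <- pcaMissing(mat, nComponents = 2L)
  sc <- projCoordinates(pc)
  if (ncol(sc) < 2L) stop("data are one-dimensional; elastic map needs 2 spanning components")
  # unit directions of the two components in data space (least-squares loadings)
  dir1 <- as.numeric(crossprod(X0, sc[, 1])) ; dir1 <- dir1 / sqrt(sum(dir1^2))
  dir2 <- as.numeric(crossprod(X0, sc[, 2]))
  dir2 <- dir2 - sum(dir2 * dir1) * dir1
  if (sqrt(sum(dir2^2)) < 1e-12) { # data collinear: pick any orthogonal direction
    dir2 <- numeric(p); dir2[which.min(abs(dir1))] <- 1
    dir2 <- dir2 - sum(dir2 * dir1) * dir1
  }
  dir2 <- dir2 / sqrt(sum(dir2^2))
  R <- config$gridRows; C <- config$gridCols; g <- R * C
  s1 <- range(sc[, 1]); s2 <- range(sc[, 2])
  if (diff(s2) == 0) s2 <- s2 + c(-1, 1) * 0.05 * max(diff(s1), 1)
  colPos <- seq(s1[1], s1[2], length.out = C)
  rowPos <- seq(s2[1], s2[2], length.out = R)
  dx <- diff(s1) / (C - 1L); dy <- diff(s2) / (R - 1L)
  Y <- matrix(0, g, p)
  for (cc in seq_len(C)) for (r in seq_len(R))
    Y[(cc - 1L) * R + r, ] <- colPos[cc] * dir1 + rowPos[r] * dir2

  pen <- gridPenaltyMatrices(R, C)
  complete <- all(obs)

  # weighted squared distance of every point to every grid node
  distToNodes <- function(Y) {
    if (complete) {
      d2 <- outer(rowSums(X0^2), rowSums(Y^2), "+") - 2 * X0 %*% t(Y)
    } else {
      d2 <- matrix(0, n, g)
      Yt2 <- Y^2
      for (i in seq_len(n)) {
        o <- obs[i, ]
        xi <- Xc[i, o]
        d2[i, ] <- w[i] * (sum(xi^2) - 2 * as.numeric(Y[, o, drop = FALSE] %*% xi) +
                             rowSums(Yt2[, o, drop = FALSE]))
      }
    }
    pmax(d2, 0)
  }

  energyLog <- list()
  for (e in seq_along(config$schedule)) {
    ep <- config$schedule[[e]]
    lambda <- ep[1]; mu <- ep[2]; iters <- as.integer(ep[3])
    energies <- numeric(iters)
    for (it in seq_len(iters)) {
      d2 <- distToNodes(Y)
      assign <- max.col(-d2, ties.method = "first")
      # solve per data dimension: (W_d + lambda E + mu S) y_d = c_d
      A0 <- lambda * pen$E + mu * pen$S
      if (complete) {
        tab <- tabulate(assign, nbins = g)
        A <- A0; diag(A) <- diag(A) + tab
        B <- matrix(0, g, p)
        for (i in seq_len(n)) B[assign[i], ] <- B[assign[i], ] + X0[i, ]
        Y <- solve(A, B)
      } else {
        for (d in seq_len(p)) {
          sel <- obs[, d]
          wd <- numeric(g); cd <- numeric(g)
          if (any(sel)) {
            ai <- assign[sel]; wi <- w[sel]; xi <- Xc[sel, d]
            for (t in seq_along(ai)) {
              wd[ai[t]] <- wd[ai[t]] + wi[t]
              cd[ai[t]] <- cd[ai[t]] + wi[t] * xi[t]
            }
          }
          A <- A0; diag(A) <- diag(A) + wd
          Y[, d] <- solve(A, cd)
        }
      }
      uStretch <- sum(diag(t(Y) %*% pen$E %*% Y))
      uBend <- sum(diag(t(Y) %*% pen$S %*% Y))
      d2new <- distToNodes(Y)
      uApproxNew <- sum(d2new[cbind(seq_len(n), assign)])
      energies[it] <- uApproxNew + lambda * uStretch + mu * uBend
    }
    energyLog[[e]] <- energies
  }

  proj <- projectOntoGrid(Xc, obs, w, Y, R, C)
  coords <- cbind(proj$u * dx, proj$v * dy)
  dimnames(coords) <- list(rownames(mat), c("EM1", "EM2"))
  tssW <- sum((X0^2) * (if (complete) 1 else w[row(X0)]))
  ve <- max(0, 1 - proj$rss / tssW)
  out <- new("ProjectionResult", coordinates = coords,
             varianceExplained = ve, method = "elmap")
  attr(out@coordinates, "energy") <- energyLog
  out
}

# Piecewise-linear projection of points onto the grid manifold: each grid
# cell is split into two triangles; points are projected onto every
# triangle (clamped to it) and the closest projection wins. Returns
# continuous internal grid coordinates (u along columns, v along rows,
# origin at the grid corner) and the weighted residual sum of squares.
projectOntoGrid <- function(Xc, obs, w, Y, R, C) {
  n <- nrow(Xc)
  complete <- all(obs)
  X0 <- Xc; X0[!obs] <- 0
  idx <- function(r, c) (c - 1L) * R + r
  best <- rep(Inf, n)
  bu <- numeric(n); bv <- numeric(n)
  tris <- list()
  for (cc in seq_len(C - 1L)) for (r in seq_len(R - 1L)) {
    # triangle vertex order: (a, b, c) with grid coords attached
    tris[[length(tris) + 1L]] <- rbind(
      c(idx(r, cc), cc - 1L, r - 1L),
      c(idx(r, cc + 1L), cc, r - 1L),
      c(idx(r + 1L, cc), cc - 1L, r))
    tris[[length(tris) + 1L]] <- rbind(
      c(idx(r + 1L, cc + 1L), cc, r),
      c(idx(r + 1L, cc), cc - 1L, r),
      c(idx(r, cc + 1L), cc, r - 1L))
  }
  for (tri in tris) {
    a <- Y[tri[1, 1], ]; b <- Y[tri[2, 1], ]; cpt <- Y[tri[3, 1], ]
    e1 <- b - a; e2 <- cpt - a
    if (complete) {
      G <- rbind(c(sum(e1 * e1), sum(e1 * e2)), c(sum(e1 * e2), sum(e2 * e2)))
      D <- X0 - matrix(a, n, length(a), byrow = TRUE)
      rhs <- cbind(as.numeric(D %*% e1), as.numeric(D %*% e2))
      st <- clampBary(rhs, G)
      P <- matrix(a, n, length(a), byrow = TRUE) +
        st[, 1] %o% e1 + st[, 2] %o% e2
      d2 <- rowSums((X0 - P)^2)
    } else {
      st <- matrix(0, n, 2); d2 <- numeric(n)
      for (i in seq_len(n)) {
        o <- obs[i, ]
        e1o <- e1[o]; e2o <- e2[o]
        di <- Xc[i, o] - a[o]
        G <- rbind(c(sum(e1o^2), sum(e1o * e2o)), c(sum(e1o * e2o), sum(e2o^2)))
        s <- clampBary(matrix(c(sum(di * e1o), sum(di * e2o)), 1, 2), G)
        st[i, ] <- s
        ri <- di - s[1] * e1o - s[2] * e2o
        d2[i] <- w[i] * sum(ri^2)
      }
    }
    upd <- d2 < best
    if (any(upd)) {
      best[upd] <- d2[upd]
      # internal coordinates: affine combination of the vertices' grid coords
      bu[upd] <- tri[1, 2] + st[upd, 1] * (tri[2, 2] - tri[1, 2]) +
        st[upd, 2] * (tri[3, 2] - tri[1, 2])
      bv[upd] <- tri[1, 3] + st[upd, 1] * (tri[2, 3] - tri[1, 3]) +
        st[upd, 2] * (tri[3, 3] - tri[1, 3])
    }
  }
  list(u = bu, v = bv, rss = sum(best))
}

# Solve G (s,t)' = rhs' rowwise and clamp to the triangle s,t >= 0,
# s + t <= 1; outside solutions fall back to the best edge projection.
clampBary <- function(rhs, G) {
  det <- G[1, 1] * G[2, 2] - G[1, 2]^2
  if (det < .Machine$double.eps * max(G[1, 1], G[2, 2], 1)) {
    # degenerate triangle: project on the longer edge only
    s <- rhs[, 1] / max(G[1, 1], .Machine$double.eps)
    return(cbind(pmin(pmax(s, 0), 1), 0))
  }
  s <- (G[2, 2] * rhs[, 1] - G[1, 2] * rhs[, 2]) / det
  t <- (G[1, 1] * rhs[, 2] - G[1, 2] * rhs[, 1]) / det
  inside <- s >= 0 & t >= 0 & s + t <= 1
  if (all(inside)) return(cbind(s, t))
  # candidate edge projections for outside points
  out <- which(!inside)
  # edge AB: t = 0
  sAB <- pmin(pmax(rhs[out, 1] / G[1, 1], 0), 1)
  dAB <- G[1, 1] * sAB^2 - 2 * sAB * rhs[out, 1]
  # edge AC: s = 0
  tAC <- pmin(pmax(rhs[out, 2] / G[2, 2], 0), 1)
  dAC <- G[2, 2] * tAC^2 - 2 * tAC * rhs[out, 2]
  # edge BC: s + t = 1, parameterize t in [0,1]
  # q(t) = |(1-t)e1 + t e2 - d|^2 up to constants
  aa <- G[1, 1] - 2 * G[1, 2] + G[2, 2]
  bb <- G[1, 2] - G[1, 1] + rhs[out, 1] - rhs[out, 2]
  tBC <- if (aa > .Machine$double.eps) pmin(pmax(-bb / aa, 0), 1) else rep(0, length(out))
  sBC <- 1 - tBC
  dBC <- G[1, 1] * sBC^2 + 2 * G[1, 2] * sBC * tBC + G[2, 2] * tBC^2 -
    2 * (sBC * rhs[out, 1] + tBC * rhs[out, 2])
  pick <- max.col(-cbind(dAB, dAC, dBC), ties.method = "first")
  s[out] <- ifelse(pick == 1, sAB, ifelse(pick == 2, 0, sBC))
  t[out] <- ifelse(pick == 1, 0, ifelse(pick == 2, tAC, tBC))
  cbind(s, t)
}

#' Variance-explained report
#'
#' @param result a [ProjectionResult-class].
#' @return numeric vector of per-component variance fractions, with a
#'   printed summary as a side effect.
#' @export
varianceReport <- function(result) {
  stopifnot(is(result, "ProjectionResult"))
  ve <- varianceExplained(result)
  labels <- if (projMethod(result) == "pca")
    paste0("PC", seq_along(ve)) else "manifold"
  for (i in seq_along(ve))
    message(sprintf("%s: %.1f%% of variance", labels[i], 100 * ve[i]))
  stats::setNames(ve, labels)
}
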