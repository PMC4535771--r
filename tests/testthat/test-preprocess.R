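test_that("missing-value filter is strict at the threshold", {
  m <- namedMatrix(rnorm(100), 10, 10)
  m[1, 1:3] <- NA # 30 % missing -> excluded
  m[2, 1:2] <- NA # 20 % missing -> kept
  res <- filterMissing(m)
  expect_true("n01" %in% res$excluded)
  expect_true("n02" %in% rownames(res$kept))
  expect_equal(rownames(res$kept), setdiff(rownames(m), "n01"))

  complete <- namedMatrix(1:20, 4, 5)
  res <- filterMissing(complete)
  expect_identical(res$kept, complete)
  expect_length(res$excluded, 0)

  allBad <- namedMatrix(NA_real_, 2, 4)
  allBad[, 1] <- 1 # 75 % missing everywhere
  expect_error(filterMissing(allBad), "no usable data points")
})

test_that("filter boundary sits at 20 % when sweeping missing fractions", {
  # rows with 0,5,...,50 % missing out of 20 columns
  fracs <- seq(0, 0.5, by = 0.05)
  m <- namedMatrix(rnorm(length(fracs) * 20), length(fracs), 20)
  for (i in seq_along(fracs)) if (fracs[i] > 0) m[i, seq_len(round(20 * fracs[i]))] <- NA
  res <- filterMissing(m)
  keptFracs <- fracs[rownames(m) %in% rownames(res$kept)]
  expect_equal(max(keptFracs), 0.20)
  expect_equal(min(fracs[rownames(m) %in% res$excluded]), 0.25)
})

test_that("double-centering zeroes row and column means and is idempotent", {
  # additive matrix centers to exactly zero
  expect_equal(doubleCenter(namedMatrix(c(1, 3, 2, 4), 2, 2)),
               namedMatrix(0, 2, 2))
  expect_equal(doubleCenter(namedMatrix(c(5, 7), 1, 2)), namedMatrix(0, 1, 2))

  X <- randomMatrix(17, 9, seed = 11)
  dc <- doubleCenter(X)
  expect_lt(max(abs(rowMeans(dc))), 1e-10)
  expect_lt(max(abs(colMeans(dc))), 1e-10)
  expect_equal(doubleCenter(dc), dc, tolerance = 1e-12)

  # missing cells stay missing; means use observed cells only
  Xm <- X; Xm[3, 5] <- NA
  dcm <- doubleCenter(Xm)
  expect_true(is.na(dcm[3, 5]))
  expect_equal(sum(is.na(dcm)), 1)

  bad <- X; bad[2, ] <- NA
  expect_error(doubleCenter(bad), "zero observed cells")
})

test_that("Laplacian basis has the analytic P3 spectrum and component structure", {
  p3 <- graphFromPairs(c("A", "B", "B", "C"))
  b <- laplacianBasis(p3)
  expect_equal(basisValues(b), c(0, 1, 3), tolerance = 1e-10)
  # constant eigenvector spans the zero eigenspace of a connected graph
  v0 <- basisVectors(b)[, 1]
  expect_lt(diff(range(v0)), 1e-10)

  two <- graphFromPairs(c("A", "B", "C", "D"))
  b2 <- laplacianBasis(two)
  expect_equal(componentCount(b2), 2L)
  expect_equal(sum(abs(basisValues(b2)) < 1e-10), 2)
})

test_that("k follows the smoothing-parameter formula and is monotone", {
  expect_equal(kFromPns(0, 10, 1), 10L)
  expect_equal(kFromPns(1, 10, 1), 3L)
  expect_equal(kFromPns(0.5, 12, 2), 8L)
  expect_error(kFromPns(1.3, 10, 1), "\\[0, 1\\]")
  ks <- vapply(seq(0, 1, by = 0.05), kFromPns, integer(1), N = 37, nc = 2)
  expect_true(all(diff(ks) <= 0))
  expect_warning(kFromPns(0.5, 4, 2), "k = N")
})

test_that("smoothing is the expected orthogonal projection", {
  fx <- generateFixture(nClusters = 2, nodesPerCluster = 10, pWithin = 0.5,
                        pBetween = 0.08, nSamples = 6, seed = 21)
  g <- fx$network
  b <- laplacianBasis(g)
  X <- fx$data
  # k = N: identity
  smN <- smoothMatrix(X, b, pns = 0)
  expect_lt(max(abs(smN - X[rownames(smN), ])), 1e-8)
  # maximal smoothing: rank <= nc + 2
  sm1 <- smoothMatrix(X, b, pns = 1)
  expect_lte(qr(sm1, tol = 1e-9)$rank, componentCount(b) + 2)
  # idempotence at intermediate k
  k <- kFromPns(0.5, igraph::vcount(g), componentCount(b))
  smk <- smoothMatrix(X, b, k = k)
  expect_equal(smoothMatrix(smk, b, k = k), smk, tolerance = 1e-9)
  # column norms never grow
  expect_true(all(sqrt(colSums(smk^2)) <= sqrt(colSums(X^2)) + 1e-10))
  # columns constant within components are unchanged for any k >= nc
  comp <- igraph::components(g)$membership[rownames(X)]
  Xc <- X
  Xc[, 1] <- as.numeric(comp)
  smc <- smoothMatrix(Xc, b, k = componentCount(b) + 1L)
  expect_equal(smc[, 1], Xc[rownames(smc), 1], tolerance = 1e-8)
})

test_that("smoothing operator matches the explicit projector on small graphs", {
  for (seed in c(3, 17, 42)) {
    g <- randomGraph(10, 0.3, seed)
    b <- laplacianBasis(g)
    N <- igraph::vcount(g)
    for (k in c(componentCount(b) + 2L, N - 2L, N)) {
      V <- basisVectors(b)[, seq_len(k), drop = FALSE]
      P <- V %*% t(V)
      expect_lt(max(abs(P - t(P))), 1e-10) # symmetric
      expect_lt(max(abs(P %*% P - P)), 1e-10) # idempotent
      ev <- eigen(P, symmetric = TRUE, only.values = TRUE)$values
      expect_true(all(abs(ev) < 1e-8 | abs(ev - 1) < 1e-8))
      X <- randomMatrix(N, 5, seed + k)
      rownames(X) <- basisNodeIds(b)
      expect_equal(smoothMatrix(X, b, k = k), P %*% X,
                   tolerance = 1e-9, ignore_attr = TRUE)
    }
  }
})

test_that("basis cache round-trips and validates", {
  g <- randomGraph(10, 0.35, 9)
  b <- laplacianBasis(g)
  f <- withr::local_tempfile(fileext = ".basis")
  saveBasis(b, f)
  b2 <- loadBasis(f, network = g)
  expect_equal(basisValues(b2), basisValues(b), tolerance = 1e-10)
  # smoothing with the loaded basis equals smoothing with a fresh one
  X <- randomMatrix(10, 4, seed = 5)
  rownames(X) <- basisNodeIds(b)
  expect_equal(smoothMatrix(X, b2, pns = 0.7), smoothMatrix(X, b, pns = 0.7),
               tolerance = 1e-9)
  # hash mismatch refused
  other <- randomGraph(10, 0.35, 10)
  igraph::V(other)$name <- basisNodeIds(b)
  expect_error(loadBasis(f, network = other), "fingerprint")
  # corrupting orthonormality is caught on load
  lines <- readLines(f)
  vecLine <- grep("^vec\t", lines)[1]
  parts <- strsplit(lines[vecLine], "\t")[[1]]
  parts[2] <- "0.9"
  lines[vecLine] <- paste(parts, collapse = "\t")
  writeLines(lines, f)
  expect_error(loadBasis(f), "orthonormal")
})

test_that("missing entries are mean-imputed with a warning before smoothing", {
  g <- randomGraph(8, 0.4, 2)
  b <- laplacianBasis(g)
  X <- randomMatrix(8, 5, seed = 3)
  rownames(X) <- basisNodeIds(b)
  Xm <- X; Xm[2, 3] <- NA
  expect_warning(sm <- smoothMatrix(Xm, b, pns = 0.5), "imputed")
  Xf <- Xm; Xf[2, 3] <- mean(Xm[2, ], na.rm = TRUE)
  expect_equal(sm, smoothMatrix(Xf, b, pns = 0.5), tolerance = 1e-12)
})
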