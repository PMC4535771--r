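test_that("component count follows the 10-component cap rule", {
  X <- randomMatrix(50, 20, seed = 1)
  p <- pcaMissing(X)
  expect_equal(ncol(projCoordinates(p)), 10)

  X8 <- randomMatrix(8, 20, seed = 2)
  expect_equal(ncol(projCoordinates(pcaMissing(X8))), 7) # rows - 1 when <= 10 rows

  expect_error(pcaMissing(X[1, , drop = FALSE]), "at least 2 rows")
})

test_that("collinear data put all variance on the first component", {
  t <- seq(-2, 2, length.out = 15)
  dir <- c(1, -2, 0.5, 3, 1) / sqrt(sum(c(1, -2, 0.5, 3, 1)^2))
  X <- outer(t, dir)
  dimnames(X) <- list(sprintf("n%02d", 1:15), sprintf("s%02d", 1:5))
  p <- pcaMissing(X, nComponents = 3)
  ve <- varianceExplained(p)
  expect_equal(ve[1], 1, tolerance = 1e-6)
  expect_lt(sum(ve[-1]), 1e-6)
})

test_that("ALS scores on complete data equal classical SVD scores up to sign", {
  for (dims in list(c(30, 8), c(100, 20), c(12, 5))) {
    X <- randomMatrix(dims[1], dims[2], seed = sum(dims))
    p <- pcaMissing(X)
    k <- ncol(projCoordinates(p))
    expect_lt(maxSignAdjustedDiff(projCoordinates(p), svdScores(X, k)), 1e-6)
  }
})

test_that("first component survives 10 % missingness on rank-1 data", {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(31)
  u <- rnorm(60); v <- rnorm(10)
  X <- outer(u, v) + matrix(rnorm(600, sd = 0.05), 60, 10)
  dimnames(X) <- list(sprintf("n%02d", 1:60), sprintf("s%02d", 1:10))
  full <- projCoordinates(pcaMissing(X, 1))[, 1]
  Xm <- X
  Xm[matrix(runif(600) < 0.10, 60, 10)] <- NA
  Xm <- filterMissing(Xm)$kept
  holey <- projCoordinates(pcaMissing(Xm, 1))[, 1]
  r <- cor(full[rownames(Xm)], holey)
  expect_gt(abs(r), 0.99)
})

test_that("scores are invariant to row permutation", {
  X <- randomMatrix(25, 6, seed = 4)
  p1 <- projCoordinates(pcaMissing(X, 3))
  perm <- rev(seq_len(nrow(X)))
  p2 <- projCoordinates(pcaMissing(X[perm, ], 3))
  expect_equal(p2[rownames(p1), ], p1, tolerance = 1e-7)
})

test_that("elastic-map energy is non-increasing within each epoch", {
  fx <- generateFixture(nClusters = 2, nodesPerCluster = 15, nSamples = 6,
                        seed = 8)
  em <- elasticMap(fx$data, elasticMapConfig(gridRows = 8, gridCols = 8))
  for (energies in attr(projCoordinates(em), "energy")) {
    expect_true(all(diff(energies) <= 1e-8 * max(abs(energies), 1)))
  }
})

test_that("a stiff elastic map recovers the PCA plane on planar data", {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(12)
  B <- qr.Q(qr(matrix(rnorm(36), 6, 6)))[, 1:2]
  S <- cbind(rnorm(70, sd = 4), rnorm(70, sd = 1.5))
  X <- S %*% t(B)
  dimnames(X) <- list(sprintf("n%02d", 1:70), sprintf("s%02d", 1:6))
  em <- elasticMap(X, elasticMapConfig(schedule = list(c(0.01, 100, 30))))
  pc <- projCoordinates(pcaMissing(X, 2))
  emc <- projCoordinates(em)
  al <- alignLayouts(emc, pc)
  expect_lt(al$residual / sum(scale(pc, scale = FALSE)^2), 0.01)
  expect_gt(varianceExplained(em), 0.99)
})

test_that("a soft elastic map explains at least as much variance as 2-component PCA", {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(19)
  # S-shaped sheet embedded in 3D
  t <- runif(90, -3 * pi / 2, 3 * pi / 2)
  width <- runif(90, 0, 2)
  X <- cbind(sin(t), width, sign(t) * (cos(t) - 1)) +
    matrix(rnorm(270, sd = 0.02), 90, 3)
  dimnames(X) <- list(sprintf("n%02d", 1:90), c("s1", "s2", "s3"))
  em <- elasticMap(X, elasticMapConfig(gridRows = 10, gridCols = 10))
  vePca <- sum(varianceExplained(pcaMissing(X, 2)))
  expect_gte(varianceExplained(em) + 1e-8, vePca)
})

test_that("elastic map handles missing entries without imputation", {
  fx <- generateFixture(nClusters = 2, nodesPerCluster = 12, nSamples = 8,
                        missingRate = 0.08, seed = 23)
  mat <- filterMissing(fx$data)$kept
  em <- elasticMap(mat, elasticMapConfig(gridRows = 6, gridCols = 6))
  expect_equal(nrow(projCoordinates(em)), nrow(mat))
  expect_true(all(is.finite(projCoordinates(em))))
  ve <- varianceExplained(em)
  expect_gte(ve, 0)
  expect_lte(ve, 1)
})

test_that("variance report matches sampling expectations", {
  X <- randomMatrix(400, 4, seed = 6)
  p <- pcaMissing(X)
  ve <- suppressMessages(varianceReport(p))
  expect_lt(max(abs(ve[1:4] - 0.25)), 0.05)
  expect_lte(sum(ve), 1 + 1e-8)

  line <- outer(seq_len(12), 2)
  dimnames(line) <- list(sprintf("n%02d", 1:12), "s01")
  p1 <- pcaMissing(line, 1)
  expect_equal(unname(suppressMessages(varianceReport(p1))), 1, tolerance = 1e-9)
})

test_that("projections are deterministic given the configuration", {
  fx <- generateFixture(nClusters = 2, nodesPerCluster = 10, nSamples = 6,
                        seed = 44)
  expect_identical(projCoordinates(pcaMissing(fx$data)),
                   projCoordinates(pcaMissing(fx$data)))
  cfg <- elasticMapConfig(gridRows = 6, gridCols = 6, seed = 3)
  expect_identical(projCoordinates(elasticMap(fx$data, cfg)),
                   projCoordinates(elasticMap(fx$data, cfg)))
})
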