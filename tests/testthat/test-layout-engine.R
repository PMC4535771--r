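test_that("coincident nodes are jittered apart within the radius bound", {
  g <- graphFromPairs(c("A", "B", "B", "C", "C", "D"))
  proj <- matrix(c(0, 0, 5, 3, 0, 0, 1, 4), 4, 2, byrow = TRUE,
                 dimnames = list(c("A", "B", "C", "D"), c("x", "y")))
  cfg <- postprocessConfig(seed = 7)
  lay <- buildLayout(proj, g, config = cfg)
  d <- as.matrix(dist(lay))
  expect_gt(min(d[upper.tri(d)]), 0)
  # displacement never exceeds the jitter radius (fraction of the diagonal)
  moved <- sqrt(rowSums((lay[rownames(proj), ] - proj)^2))
  diag0 <- sqrt(sum((apply(proj, 2, max) - apply(proj, 2, min))^2))
  expect_true(all(moved <= cfg$jitterRadius * diag0 + 1e-12))
})

test_that("layout equals the raw projection when all steps are no-ops", {
  g <- graphFromPairs(c("A", "B", "B", "C"))
  proj <- matrix(c(0, 0, 1, 0.5, 2, 1.5), 3, 2, byrow = TRUE,
                 dimnames = list(c("A", "B", "C"), c("x", "y")))
  lay <- buildLayout(proj, g)
  expect_equal(lay[rownames(proj), ], proj, ignore_attr = TRUE)
})

test_that("excluded nodes land at the mean of placed neighbours", {
  g <- graphFromPairs(c("A", "E", "B", "E"))
  proj <- matrix(c(0, 0, 2, 2), 2, 2, byrow = TRUE,
                 dimnames = list(c("A", "B"), c("x", "y")))
  lay <- buildLayout(proj, g, excluded = "E")
  expect_equal(unname(lay["E", ]), c(1, 1))
})

test_that("outliers are pulled to the threshold distance, others untouched", {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(5)
  pts <- matrix(runif(20, -1, 1), 10, 2,
                dimnames = list(sprintf("n%02d", 1:10), c("x", "y")))
  far <- rbind(pts, outlier = c(1000, 0))
  cfg <- postprocessConfig()
  pulled <- pullInOutliers(far, cfg)
  ctr <- colMeans(far)
  thr <- cfg$outlierFactor * median(sqrt(rowSums(sweep(far, 2, ctr)^2)))
  expect_equal(sqrt(sum((pulled["outlier", ] - ctr)^2)), thr, tolerance = 1e-9)
  expect_equal(pulled[rownames(pts), ], far[rownames(pts), ])
  # re-application is a contraction: it only ever touches the previously
  # pulled node, moving it further toward the barycenter by a shrinking step
  twice <- pullInOutliers(pulled, cfg)
  expect_equal(twice[rownames(pts), ], pulled[rownames(pts), ])
  step1 <- sqrt(sum((pulled["outlier", ] - far["outlier", ])^2))
  step2 <- sqrt(sum((twice["outlier", ] - pulled["outlier", ])^2))
  expect_lt(step2, step1)

  # all nodes equidistant from the barycenter: nothing moves
  theta <- seq(0, 2 * pi, length.out = 9)[-9]
  ring <- cbind(cos(theta), sin(theta))
  rownames(ring) <- sprintf("r%d", 1:8)
  expect_equal(unname(pullInOutliers(ring, cfg)), unname(ring))
})

test_that("excluded placement iterates through chains and falls back to the barycenter", {
  chain <- graphFromPairs(c("A", "B", "B", "C"))
  lay <- matrix(c(0, 0, 4, 0), 2, 2, byrow = TRUE,
                dimnames = list(c("A", "C"), c("x", "y")))
  placed <- placeExcluded(lay, chain, "B")
  expect_equal(unname(placed["B", ]), c(2, 0))

  # two-hop chain: C placed, A then B filled in over two passes
  hop <- graphFromPairs(c("C", "A", "A", "B"))
  lay1 <- matrix(c(1, 1), 1, 2, dimnames = list("C", c("x", "y")))
  placed <- placeExcluded(lay1, hop, c("A", "B"))
  expect_equal(unname(placed["A", ]), c(1, 1))
  expect_equal(unname(placed["B", ]), c(1, 1))

  # node with no placed neighbour anywhere: barycenter of placed nodes
  iso <- graphFromPairs(c("A", "B"), isolated = "Z")
  lay2 <- matrix(c(0, 0, 2, 4), 2, 2, byrow = TRUE,
                 dimnames = list(c("A", "B"), c("x", "y")))
  placed <- placeExcluded(lay2, iso, "Z")
  expect_equal(unname(placed["Z", ]), c(1, 2))

  expect_error(placeExcluded(lay2[0, , drop = FALSE], iso, "Z"), "no placed nodes")
})

test_that("layout construction is deterministic and total", {
  fx <- generateFixture(nClusters = 2, nodesPerCluster = 12, nSamples = 6,
                        missingRate = 0.15, seed = 13)
  res1 <- dataDrivenLayout(fx$network, fx$data, method = "pca")
  res2 <- dataDrivenLayout(fx$network, fx$data, method = "pca")
  expect_identical(res1$layout, res2$layout)
  expect_setequal(rownames(res1$layout), igraph::V(fx$network)$name)
  expect_true(all(is.finite(res1$layout)))
})

test_that("unplaceable projections raise errors", {
  g <- graphFromPairs(c("A", "B"))
  proj <- matrix(0, 1, 2, dimnames = list("Q", c("x", "y")))
  expect_error(buildLayout(proj, g), "not in network")
  proj2 <- matrix(0, 1, 2, dimnames = list("A", c("x", "y")))
  expect_error(buildLayout(proj2, g), "neither projected nor excluded")
})
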