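test_that("nearest-neighbour distances match hand values and brute force", {
  a <- CellMap(data.frame(x = 0, y = 0, phenotype = "CD8T"))
  b <- CellMap(data.frame(x = 3, y = 4, phenotype = "TAM"))
  expect_equal(nnDistances(a, b), 5)

  two <- CellMap(data.frame(x = c(0, 7), y = c(0, 0),
                            phenotype = c("CD8T", "CD8T")))
  expect_equal(nnDistances(two, two, excludeSelf = TRUE), c(7, 7))

  set.seed(42)
  xy <- cbind(runif(6, 0, 100), runif(6, 0, 100))
  expect_equal(nnDistances(xy, xy, excludeSelf = TRUE),
               bruteNN(xy, xy, excludeIdx = TRUE))
  xy2 <- cbind(runif(4, 0, 100), runif(4, 0, 100))
  expect_equal(nnDistances(xy, xy2), bruteNN(xy, xy2))

  expect_error(nnDistances(a, a[0]), "empty")
  expect_error(nnDistances(a, a, excludeSelf = TRUE), "self-exclusion")
})

test_that("coincident distinct cells count at distance zero", {
  cm <- CellMap(data.frame(x = c(5, 5, 9), y = c(5, 5, 5),
                           phenotype = rep("CD8T", 3)))
  d <- nnDistances(cm, cm, excludeSelf = TRUE)
  expect_equal(d[1:2], c(0, 0))
})

test_that("degenerate nulls are flagged undefined, not zero", {
  cm <- CellMap(data.frame(x = c(0, 1, 2), y = c(0, 0, 0),
                           phenotype = rep("TAM", 3)))
  r <- permutationNNZ(cm, "TAM", "TAM", mode = "exhaustive")
  expect_true(r@undefined)
  expect_true(is.na(r@z))
  expect_equal(r@nullSd, 0)
})

test_that("unit-square exhaustive enumeration is geometry-forced", {
  cm <- CellMap(data.frame(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1),
                           phenotype = c("CD4T", "CD8T", "CD4T", "CD8T")))
  r <- permutationNNZ(cm, "CD4T", "CD8T", mode = "exhaustive")
  expect_equal(r@observedMeanNN, 1.0)
  expect_equal(r@nPerm, choose(4, 2) * choose(2, 2))
  # every 2/2 split of the unit square gives mean NN distance exactly 1,
  # so the null is degenerate and the z-score is flagged
  expect_true(r@undefined)
})

test_that("exhaustive null matches full multiset enumeration", {
  xy <- cbind(c(0, 1, 2, 10, 11), c(0, 0, 0, 0, 0))
  lab <- c("CD8T", "CD8T", "Other", "Other", "Other")
  cm <- CellMap(data.frame(x = xy[, 1], y = xy[, 2], phenotype = lab))
  r <- permutationNNZ(cm, "CD8T", "CD8T", mode = "exhaustive")
  oracle <- bruteExhaustiveNull(xy, lab, "CD8T", "CD8T")
  expect_equal(r@nPerm, 10L)  # C(5,2) placements of the T pair
  expect_equal(r@nullMean, oracle$mean, tolerance = 1e-12)
  expect_equal(r@nullSd, oracle$sd, tolerance = 1e-12)
  # cells 0 and 1 are adjacent: observed mean 1.0, well below the null
  expect_equal(r@observedMeanNN, 1.0)
  expect_lt(r@z, 0)
})

test_that("observed statistic is invariant to row order and ids", {
  set.seed(5)
  d <- data.frame(cell_id = sprintf("c%d", 1:30),
                  x = runif(30, 0, 100), y = runif(30, 0, 100),
                  phenotype = sample(c("CD8T", "TAM"), 30, TRUE))
  r1 <- permutationNNZ(CellMap(d), "CD8T", "TAM", nPerm = 10, seed = 1)
  shuf <- d[sample(nrow(d)), ]
  shuf$cell_id <- sprintf("z%d", seq_len(nrow(shuf)))
  r2 <- permutationNNZ(CellMap(shuf), "CD8T", "TAM", nPerm = 10, seed = 1)
  expect_equal(r1@observedMeanNN, r2@observedMeanNN)
})

test_that("missing types error in the scalar API and flag in the table", {
  cm <- CellMap(data.frame(x = 1:3, y = 1:3, phenotype = rep("TAM", 3)))
  expect_error(permutationNNZ(cm, "CD8T", "TAM", nPerm = 10), "CD8T")

  zs <- zscoreMatrix(cm, c("TAM:TAM", "CD8T:TAM", "TAM:CD8T"),
                     nPerm = 20, seed = 1)
  expect_equal(nrow(zs), 3L)
  expect_true(all(zs$undefined[2:3]))

  zsEmpty <- zscoreMatrix(cm[0], c("TAM:TAM", "CD4T:CD8T"), nPerm = 5)
  expect_true(all(zsEmpty$undefined))
  expect_equal(nrow(zsEmpty), 2L)
})

test_that("sampled mode converges to the exhaustive null", {
  set.seed(13)
  cm <- CellMap(data.frame(x = runif(8, 0, 50), y = runif(8, 0, 50),
                           phenotype = c(rep("CD8T", 3), rep("TAM", 5))))
  ex <- permutationNNZ(cm, "CD8T", "TAM", mode = "exhaustive")
  nP <- 10000
  sa <- permutationNNZ(cm, "CD8T", "TAM", nPerm = nP, seed = 3)
  seMean <- ex@nullSd / sqrt(nP)
  expect_lt(abs(sa@nullMean - ex@nullMean), 3 * seMean)
  seSd <- ex@nullSd / sqrt(2 * nP)
  expect_lt(abs(sa@nullSd - ex@nullSd), 3 * seSd)
})

test_that("vessel-distance KS handles the canonical configurations", {
  vessel <- list(MembraneHull(circleRingT(0, 0, 5), marker = "CD31"))

  # identical distance multisets in both groups
  cmSame <- CellMap(data.frame(x = c(10, 20, 30, 10, 20, 30), y = 0,
                               phenotype = rep(c("CD8T", "Other"),
                                               each = 3)))
  r0 <- vesselDistanceKS(cmSame, vessel, "CD8T")
  expect_equal(r0@D, 0)

  # positives inside the vessel, negatives at >= 10 um
  cmSep <- CellMap(data.frame(x = c(0, 1, 2, 20, 25, 30), y = 0,
                              phenotype = rep(c("CD8T", "Other"),
                                              each = 3)))
  r1 <- vesselDistanceKS(cmSep, vessel, "CD8T")
  expect_equal(r1@D, 1)
  expect_equal(r1@medianPos, 0)

  # distances {1,2,3} vs {4,5,6}: D = 1, exact two-sided p = 0.1
  cm13 <- CellMap(data.frame(x = c(6, 7, 8, 9, 10, 11), y = 0,
                             phenotype = rep(c("CD8T", "Other"),
                                             each = 3)))
  r2 <- vesselDistanceKS(cm13, vessel, "CD8T")
  expect_equal(r2@D, 1)
  expect_equal(r2@pValue, 0.1, tolerance = 1e-12)

  expect_error(vesselDistanceKS(cmSame, list(), "CD8T"), "vessel")
  expect_error(vesselDistanceKS(cmSame, vessel, "BCell"), "empty group")
})

test_that("KS subsampling caps group sizes and records them", {
  set.seed(2)
  n <- 500
  cm <- CellMap(data.frame(x = runif(n, 0, 400), y = runif(n, 0, 400),
                           phenotype = sample(c("CD8T", "Other"), n, TRUE)))
  vessel <- list(MembraneHull(circleRingT(200, 200, 20), marker = "CD31"))
  r <- vesselDistanceKS(cm, vessel, "CD8T", maxPerGroup = 50, seed = 9)
  expect_equal(r@nPos, 50L)
  expect_equal(r@nNeg, 50L)
  # deterministic under the seed
  r2 <- vesselDistanceKS(cm, vessel, "CD8T", maxPerGroup = 50, seed = 9)
  expect_equal(r@D, r2@D)
})
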