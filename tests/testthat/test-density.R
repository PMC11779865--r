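test_that("a single-point kernel integrates to one and peaks at the point", {
  f <- kdeField(cbind(300, 400), sigma = 50)
  integral <- sum(fieldValues(f)) * f@spacing^2
  expect_lt(abs(integral - 1), 0.01)
  g <- gridNodes(f)
  peak <- which(fieldValues(f) == max(fieldValues(f)), arr.ind = TRUE)
  expect_lt(abs(g$x[peak[1]] - 300), f@spacing / 2 + 1e-9)
  expect_lt(abs(g$y[peak[2]] - 400), f@spacing / 2 + 1e-9)
})

test_that("two-point fields match the analytic Gaussian sum exactly", {
  pts <- rbind(c(100, 100), c(180, 140))
  sigma <- 40
  f <- kdeField(pts, sigma = sigma)
  g <- gridNodes(f)
  probeI <- round(seq(5, length(g$x) - 5, length.out = 3))
  probeJ <- round(seq(5, length(g$y) - 5, length.out = 3))
  for (i in probeI) for (j in probeJ) {
    d1 <- (g$x[i] - pts[1, 1])^2 + (g$y[j] - pts[1, 2])^2
    d2 <- (g$x[i] - pts[2, 1])^2 + (g$y[j] - pts[2, 2])^2
    want <- (exp(-d1 / (2 * sigma^2)) + exp(-d2 / (2 * sigma^2))) /
      (2 * pi * sigma^2)
    expect_equal(fieldValues(f)[i, j], want, tolerance = 1e-12)
  }
})

test_that("corrected density hits its trivial limits", {
  set.seed(3)
  pts <- cbind(runif(200, 0, 500), runif(200, 0, 500))
  total <- kdeField(pts, sigma = 100)
  grid <- list(origin = total@origin, spacing = total@spacing,
               nx = nrow(fieldValues(total)), ny = ncol(fieldValues(total)))
  # positives = all points -> ratio 1 wherever unmasked
  ratioAll <- correctedDensity(kdeField(pts, 100, grid), total)
  expect_true(all(abs(fieldValues(ratioAll)[fieldMask(ratioAll)] - 1) < 1e-9))
  # no positives -> ratio 0
  ratioNone <- correctedDensity(
    suppressWarnings(kdeField(pts[0, , drop = FALSE], 100, grid)), total)
  expect_true(all(fieldValues(ratioNone)[fieldMask(ratioNone)] == 0))
  # mismatched grids refuse to combine
  other <- kdeField(pts + 10, sigma = 100)
  expect_error(correctedDensity(other, total), "mismatch")
})

test_that("half-plane labelling yields the expected ratio profile", {
  set.seed(11)
  n <- 1500
  pts <- cbind(runif(n, 0, 2000), runif(n, 0, 1000))
  positive <- pts[, 1] < 1000
  sigma <- 200
  total <- kdeField(pts, sigma)
  grid <- list(origin = total@origin, spacing = total@spacing,
               nx = nrow(fieldValues(total)), ny = ncol(fieldValues(total)))
  ratio <- correctedDensity(kdeField(pts[positive, ], sigma, grid), total)
  probe <- function(x, y) {
    v <- densityAtCells(ratio, cbind(x, y))
    expect_true(v$defined)
    v$value
  }
  expect_lt(abs(probe(150, 500) - 1), 0.05)   # deep in the positive half
  expect_lt(abs(probe(1850, 500) - 0), 0.05)  # deep in the negative half
  expect_lt(abs(probe(1000, 500) - 0.5), 0.05)  # on the boundary
})

test_that("ratio fields are bounded and scale-equivariant", {
  set.seed(21)
  pts <- cbind(runif(300, 0, 800), runif(300, 0, 800))
  positive <- runif(300) < 0.4
  sigma <- 150
  total <- kdeField(pts, sigma)
  grid <- list(origin = total@origin, spacing = total@spacing,
               nx = nrow(fieldValues(total)), ny = ncol(fieldValues(total)))
  ratio <- correctedDensity(kdeField(pts[positive, ], sigma, grid), total)
  v <- fieldValues(ratio)[fieldMask(ratio)]
  expect_true(all(v >= 0 & v <= 1))

  # scaling coordinates and sigma by c leaves sampled ratios unchanged
  c0 <- 3.7
  totalS <- kdeField(pts * c0, sigma * c0)
  gridS <- list(origin = totalS@origin, spacing = totalS@spacing,
                nx = nrow(fieldValues(totalS)),
                ny = ncol(fieldValues(totalS)))
  ratioS <- correctedDensity(kdeField(pts[positive, ] * c0, sigma * c0,
                                      gridS), totalS)
  probes <- pts[1:50, ]
  a <- densityAtCells(ratio, probes)
  b <- densityAtCells(ratioS, probes * c0)
  expect_identical(a$defined, b$defined)
  expect_lt(max(abs(a$value[a$defined] - b$value[b$defined])), 1e-9)
})

test_that("planted label proportions are recovered by the ratio field", {
  p <- 0.3
  devs <- numeric(10)
  for (s in seq_len(10)) {
    set.seed(100 + s)
    pts <- cbind(runif(500, 0, 1000), runif(500, 0, 1000))
    positive <- runif(500) < p
    total <- kdeField(pts, 200)
    grid <- list(origin = total@origin, spacing = total@spacing,
                 nx = nrow(fieldValues(total)),
                 ny = ncol(fieldValues(total)))
    ratio <- correctedDensity(kdeField(pts[positive, , drop = FALSE],
                                       200, grid), total)
    g <- gridNodes(ratio)
    interior <- outer(g$x >= 200 & g$x <= 800, g$y >= 200 & g$y <= 800,
                      "&") & fieldMask(ratio)
    devs[s] <- mean(fieldValues(ratio)[interior]) - p
  }
  expect_lt(abs(mean(devs)), 0.05)
})

test_that("bilinear sampling matches nodes, midpoints and a gridless oracle", {
  set.seed(5)
  pts <- cbind(runif(200, 0, 600), runif(200, 0, 600))
  positive <- runif(200) < 0.5
  sigma <- 150
  total <- kdeField(pts, sigma)
  grid <- list(origin = total@origin, spacing = total@spacing,
               nx = nrow(fieldValues(total)), ny = ncol(fieldValues(total)))
  ratio <- correctedDensity(kdeField(pts[positive, ], sigma, grid), total)
  g <- gridNodes(ratio)

  # a cell exactly on a (defined) node returns the node value
  ci <- round(length(g$x) / 2); cj <- round(length(g$y) / 2)
  v <- densityAtCells(ratio, cbind(g$x[ci], g$y[cj]))
  expect_true(v$defined)
  expect_equal(v$value, fieldValues(ratio)[ci, cj])
  # the midpoint of four nodes returns their mean
  mid <- densityAtCells(ratio,
                        cbind(mean(g$x[ci + 0:1]), mean(g$y[cj + 0:1])))
  expect_equal(mid$value, mean(fieldValues(ratio)[ci + 0:1, cj + 0:1]),
               tolerance = 1e-12)
  # cells outside the grid are flagged, not dropped
  far <- densityAtCells(ratio, cbind(1e6, 1e6))
  expect_false(far$defined)
  expect_true(is.na(far$value))

  # gridless kernel-sum oracle at the cells themselves (2% tolerance
  # for grid discretisation)
  sampled <- densityAtCells(ratio, pts)
  kern <- function(q, set) {
    if (nrow(set) == 0L) return(0)
    sum(exp(-((q[1] - set[, 1])^2 + (q[2] - set[, 2])^2) /
              (2 * sigma^2)))
  }
  direct <- vapply(seq_len(nrow(pts)), function(i)
    kern(pts[i, ], pts[positive, , drop = FALSE]) / kern(pts[i, ], pts),
    numeric(1))
  ok <- sampled$defined
  expect_gt(mean(ok), 0.95)
  expect_lt(max(abs(sampled$value[ok] - direct[ok])), 0.02)
})

test_that("equal-count binning is exact, stable and errors when starved", {
  b40 <- pooledEqualCountBins(runif(40), nBins = 20)
  expect_true(all(table(b40) == 2))

  v41 <- runif(41)
  b41 <- pooledEqualCountBins(v41, nBins = 20)
  tab <- table(b41)
  expect_equal(sort(unique(as.integer(tab))), c(2L, 3L))
  expect_equal(sum(tab == 3L), 1L)
  expect_equal(as.integer(tab[1]), 3L)  # the extra cell goes to bin 1

  # ordering by value is exact: all of bin b <= all of bin b+1
  v <- rnorm(200)
  b <- pooledEqualCountBins(v, nBins = 10)
  for (k in 1:9) expect_lte(max(v[b == k]), min(v[b == k + 1]))

  # ties: stable input order still gives equal occupancies
  bTies <- pooledEqualCountBins(rep(1, 60), nBins = 20)
  expect_true(all(table(bTies) == 3))
  expect_equal(bTies[1:3], rep(1L, 3))

  # NA values are excluded but keep their position
  vNA <- c(NA, 5, 1, NA, 3, 2)
  bNA <- pooledEqualCountBins(vNA, nBins = 2)
  expect_true(all(is.na(bNA[c(1, 4)])))
  expect_equal(bNA[c(3, 6)], c(1L, 1L))

  expect_error(pooledEqualCountBins(runif(5), nBins = 10), "5 defined")
})

test_that("bin composition fractions behave and normalise", {
  set.seed(9)
  n <- 200
  d <- data.frame(x = runif(n), y = runif(n),
                  phenotype = sample(c("CD8T", "TAM", "GTC"), n, TRUE),
                  sample_id = sample(c("s1", "s2"), n, TRUE))
  cm <- CellMap(d)
  vals <- runif(n)
  bins <- pooledEqualCountBins(vals, nBins = 5)

  bt <- binComposition(bins, cm, sampleGroups = c(s1 = "high", s2 = "low"),
                       values = vals)
  # mean density is non-decreasing with bin index
  expect_true(all(diff(bt$binSummary$mean_density) >= 0))
  # group fractions per bin sum to one
  expect_equal(bt$binSummary$frac_high + bt$binSummary$frac_low,
               rep(1, 5))
  # phenotype fractions per bin x group sum to one
  agg <- aggregate(fraction ~ bin + group, bt$phenotypeFractions, sum)
  expect_true(all(abs(agg$fraction - 1) < 1e-9))

  # single-group data puts fraction one everywhere
  bt1 <- binComposition(bins, cm, sampleGroups = c(s1 = "g", s2 = "g"))
  expect_true(all(bt1$binSummary$frac_g == 1))

  expect_error(binComposition(bins, cm, sampleGroups = c(s1 = "high")),
               "unknown group")
})
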