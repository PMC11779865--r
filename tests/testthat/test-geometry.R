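test_that("morphological closing keeps squares tight and contains input", {
  sq <- squareHull(0, 0, 200)
  out <- buildHulls(list(sq), smoothing = 5)
  expect_length(out, 1L)
  ratio <- hullArea(out[[1]]) / hullArea(sq)
  expect_gte(ratio, 1.0)
  expect_lte(ratio, 1.05)
  # input vertices (nudged inside) are contained in the output
  inner <- cbind(c(1, 199, 199, 1), c(1, 1, 199, 199))
  expect_true(all(hullContains(out[[1]], inner)))
})

test_that("closing merges near fragments and keeps far ones apart", {
  a <- squareHull(0, 0, 30)
  bNear <- squareHull(31, 0, 30)   # 1 um gap
  bFar <- squareHull(130, 0, 30)   # 100 um gap
  expect_length(buildHulls(list(a, bNear), smoothing = 5), 1L)
  expect_length(buildHulls(list(a, bFar), smoothing = 5), 2L)
})

test_that("degenerate polygons are skipped with a warning", {
  good <- squareHull(0, 0, 20)
  degen <- cbind(c(0, 10, 20), c(0, 0, 0))  # collinear: zero area
  expect_warning(out <- buildHulls(list(good, degen), smoothing = 2),
                 "degenerate")
  expect_length(out, 1L)
})

test_that("containment respects holes, nesting and boundaries", {
  ann <- annulusHull(0, 0, 30, 90)
  expect_false(hullContains(ann, cbind(0, 0)))      # in the hole
  expect_true(hullContains(ann, cbind(60, 0)))      # in the ring
  expect_false(hullContains(ann, cbind(120, 0)))    # outside

  # nested hulls resolve to the smallest containing area
  outer <- squareHull(0, 0, 100)
  inner <- squareHull(25, 25, 40)
  assign <- assignCellsToHulls(cbind(c(30, 10), c(30, 10)),
                               list(outer, inner))
  expect_equal(unname(assign), c(2L, 1L))

  # boundary points are contained
  expect_true(hullContains(outer, cbind(0, 50)))
  expect_true(hullContains(outer, cbind(100, 100)))
})

test_that("assignment agrees with a raster oracle at 0.5 um", {
  set.seed(31)
  hulls <- list(squareHull(10, 10, 150), annulusHull(300, 100, 20, 70),
                squareHull(50, 40, 60))
  pts <- cbind(runif(400, 0, 400), runif(400, 0, 200))
  # keep clear of ring edges where pixel snapping is ambiguous
  keep <- minEdgeDistT(pts, hulls) > 1
  got <- assignCellsToHulls(pts[keep, , drop = FALSE], hulls)
  want <- rasterAssignOracle(pts[keep, , drop = FALSE], hulls, res = 0.5)
  expect_identical(unname(got), want)
})

test_that("cuff detection applies the more-than-two-T-cells rule exactly", {
  ann <- annulusHull(100, 100, 20, 60)
  mk <- function(n, phen = "CD8T") {
    th <- seq(0, 2 * pi, length.out = n + 1)[-1]
    data.frame(x = 100 + 40 * cos(th), y = 100 + 40 * sin(th),
               phenotype = phen)
  }
  # two T cells: no cuff
  expect_equal(nrow(detectCuffs(CellMap(mk(2)), list(ann))), 0L)
  # three T cells: a cuff with exactly three members
  c3 <- detectCuffs(CellMap(mk(3)), list(ann))
  expect_equal(nrow(c3), 1L)
  expect_equal(c3$t_cell_count, 3L)
  # non-T cells never count
  expect_equal(nrow(detectCuffs(CellMap(mk(5, "TAM")), list(ann))), 0L)
})

test_that("a constructed two-annulus scene yields exactly two cuffs", {
  a1 <- annulusHull(100, 100, 20, 60)
  a2 <- annulusHull(400, 100, 20, 60)
  inAnn <- function(cx, n) {
    th <- seq(0.3, 2 * pi, length.out = n + 1)[-1]
    data.frame(x = cx + 40 * cos(th), y = 100 + 40 * sin(th),
               phenotype = "CD4T")
  }
  set.seed(7)
  stroma <- data.frame(x = runif(10, 600, 900), y = runif(10, 0, 200),
                       phenotype = "CD8T")
  cm <- CellMap(rbind(inAnn(100, 3), inAnn(400, 5), stroma))
  cuffs <- detectCuffs(cm, list(a1, a2))
  expect_equal(nrow(cuffs), 2L)
  expect_setequal(cuffs$t_cell_count, c(3L, 5L))
  # cuff invariants: members contained, radius consistent with area
  for (i in seq_len(nrow(cuffs))) {
    h <- list(a1, a2)[[cuffs$hull_id[i]]]
    mem <- cellData(cm)[cellData(cm)$cell_id %in% cuffs$members[[i]], ]
    expect_true(all(hullContains(h, cbind(mem$x, mem$y))))
    expect_equal(cuffs$equivalent_radius[i]^2 * pi, cuffs$area[i],
                 tolerance = 1e-6)
  }
})

test_that("adding a T cell inside a cuff never removes it", {
  ann <- annulusHull(100, 100, 20, 60)
  base <- data.frame(x = 100 + 40 * cos(1:3), y = 100 + 40 * sin(1:3),
                     phenotype = "CD8T")
  c1 <- detectCuffs(CellMap(base), list(ann))
  more <- rbind(base, data.frame(x = 100 - 40, y = 100, phenotype = "CD4T"))
  c2 <- detectCuffs(CellMap(more), list(ann))
  expect_equal(nrow(c2), 1L)
  expect_gte(c2$t_cell_count, c1$t_cell_count)
})

test_that("area-adjusted counts convert to cells per mm^2", {
  # 2 mm^2 square region with 10 cells inside
  region <- squareHull(0, 0, sqrt(2) * 1000)
  cm <- CellMap(data.frame(x = runif(10, 100, 1200),
                           y = runif(10, 100, 1200),
                           phenotype = "CD8T"))
  expect_equal(areaAdjustedCount(cm, region, "CD8T"), 5, tolerance = 1e-9)
  expect_equal(areaAdjustedCount(cm, region, "TAM"), 0)
})

test_that("cuff and stroma counts partition the in-tissue total", {
  set.seed(17)
  outline <- squareHull(0, 0, 600)
  a1 <- annulusHull(150, 150, 20, 70)
  a2 <- annulusHull(450, 400, 20, 70)
  pts <- cbind(runif(300, 0, 600), runif(300, 0, 600))
  inTissue <- hullContains(outline, pts)
  inA1 <- hullContains(a1, pts)
  inA2 <- hullContains(a2, pts)
  # annuli are disjoint and inside the tissue outline, so cuff-region
  # counts plus stroma counts partition the in-tissue total
  expect_false(any(inA1 & inA2))
  expect_true(all(inTissue[inA1 | inA2]))
  stromaCount <- sum(inTissue & !inA1 & !inA2)
  expect_equal(stromaCount + sum(inA1) + sum(inA2), sum(inTissue))
})

test_that("ROI phenotype calls follow the cuff/stromal/absent taxonomy", {
  noT <- CellMap(data.frame(x = 1:3, y = 1:3, phenotype = "TAM"))
  emptyCuffs <- detectCuffs(noT, list())
  expect_equal(classifyROIPhenotype(noT, emptyCuffs), "absent")
  withT <- CellMap(data.frame(x = 1:3, y = 1:3,
                              phenotype = c("CD8T", "TAM", "TAM")))
  expect_equal(classifyROIPhenotype(withT, emptyCuffs), "stromal_T")
  fakeCuffs <- data.frame(hull_id = 1L, t_cell_count = 3L)
  expect_equal(classifyROIPhenotype(withT, fakeCuffs), "cuff")
})

test_that("registration recovers identity and planted rotations", {
  rect <- MembraneHull(cbind(c(0, 400, 400, 0), c(0, 0, 200, 200)))
  same <- registerOutlines(rect, rect, angleStep = 1, maxAngle = 5,
                           translationStep = 20, maxTranslation = 60,
                           resolution = 5)
  expect_equal(same$rotation, 0)
  expect_equal(unname(same$translation), c(0, 0))
  expect_gte(same$iouAfter, 0.99)
  expect_gte(same$iouAfter, same$iouBefore)
  expect_false(is.null(same$consensus))

  # rectangle rotated by +10 degrees: recovered within the angle step
  rot <- MembraneHull(rotateRingT(rect@exterior, 10))
  reg <- registerOutlines(rect, rot, angleStep = 1, maxAngle = 14,
                          translationStep = 20, maxTranslation = 40,
                          resolution = 5)
  expect_lte(abs(reg$rotation - (-10)), 1)
  expect_gte(reg$iouAfter, reg$iouBefore)
  expect_gte(reg$iouAfter, 0.9)
})

test_that("disjoint outlines give an empty consensus with a warning", {
  a <- squareHull(0, 0, 50)
  b <- squareHull(5000, 5000, 50)
  expect_warning(
    reg <- registerOutlines(a, b, angleStep = 5, maxAngle = 5,
                            translationStep = 25, maxTranslation = 50,
                            resolution = 12.5),
    "consensus")
  expect_null(reg$consensus)
  expect_equal(reg$iouAfter, 0)
})
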