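test_that("circularity matches closed forms", {
  expect_lt(abs(circularity(regularPolygon(2000)) - 1), 0.005)
  expect_equal(circularity(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))), pi / 4)
  expect_equal(circularity(regularPolygon(6)), pi * sqrt(3) / 6)
  # scale invariance
  hex <- regularPolygon(6, radius = 3.7)
  expect_equal(circularity(hex), circularity(hex * 12))
  # n-gon circularity increases monotonically to 1
  cs <- vapply(c(8, 16, 32, 64, 128), function(n)
    circularity(regularPolygon(n)), 0)
  expect_true(all(diff(cs) > 0))
  expect_true(all(cs < 1))
})

test_that("a rasterized disk traces to a near-circular boundary", {
  lab <- matrix(0L, 190, 190)
  lab[diskMask(190, 80)] <- 1L
  bt <- tracePlacodeBoundary(lab, 1L, pixelSize = 1)
  expect_false(bt@midlineChord)
  expect_lt(abs(bt@perimeter - 2 * pi * 80) / (2 * pi * 80), 0.03)
  expect_lt(abs(bt@area - pi * 80^2) / (pi * 80^2), 0.005)
  expect_gt(bt@circularity, 0.98)
  expect_lte(bt@circularity, 1.02)
})

test_that("the ventral midline closes the contour with a chord", {
  lab <- matrix(0L, 120, 120)
  lab[diskMask(120, 45)] <- 1L
  bt <- tracePlacodeBoundary(lab, 1L, pixelSize = 1, midlineY = 60)
  expect_true(bt@midlineChord)
  expect_lte(max(bt@contour[, 2]), 60)
  expect_lt(abs(bt@area - pi * 45^2 / 2) / (pi * 45^2 / 2), 0.01)
  # excluding the chord from the perimeter lowers it by the chord length
  noChord <- tracePlacodeBoundary(lab, 1L, pixelSize = 1, midlineY = 60,
                                  chordInPerimeter = FALSE)
  expect_lt(abs((bt@perimeter - noChord@perimeter) - 90) / 90, 0.05)
})

test_that("scene boundary perimeter and area match the disk construction", {
  sc <- generateScene(sceneConfig(nCells = 60, surroundCells = 60, seed = 61))
  r0 <- sqrt(60 * 20 / pi)
  bt <- tracePlacodeBoundary(labelImage(sc), sc@placodeIds, pixelSize = 0.2)
  expect_lt(abs(bt@perimeter - 2 * pi * r0) / (2 * pi * r0), 0.03)
  expect_lt(abs(bt@area - pi * r0^2) / (pi * r0^2), 0.005)
  expect_lt(abs(bt@area - sum(cellAreas(sc)[sc@placodeIds]) * 1.0) /
            bt@area, 0.005)
})

test_that("one-cell-layer shifts follow edge adjacency", {
  lab <- squareGridLabels(7, 7, 6)
  centerIds <- as.integer(outer(2:6, (2:6 - 1) * 7, "+"))  # central 5x5
  # raw marching-squares contours (no simplification) for exact-ish areas
  inner <- shiftBoundary(lab, centerIds, "inner", pixelSize = 1,
                         simplifyTol = 0)
  expect_equal(inner@area, 9 * 36, tolerance = 0.005)  # central 3x3 survives
  outer <- shiftBoundary(lab, centerIds, "outer", pixelSize = 1,
                         simplifyTol = 0)
  expect_equal(outer@area, (25 + 20) * 36, tolerance = 0.005)  # + edge cross
  pl <- tracePlacodeBoundary(lab, centerIds, pixelSize = 1, simplifyTol = 0)
  expect_lt(inner@area, pl@area)
  expect_lt(pl@area, outer@area)
  # single-cell placode: no inner layer exists
  expect_error(shiftBoundary(lab, 25L, "inner"), "one cell layer")
  one <- shiftBoundary(lab, 25L, "outer", pixelSize = 1, simplifyTol = 0)
  expect_equal(one@area, 5 * 36, tolerance = 0.01)
})

test_that("disconnected placodes are rejected with a component list", {
  lab <- squareGridLabels(4, 4, 5)
  expect_error(tracePlacodeBoundary(lab, c(1L, 16L)), "components")
})

test_that("cell contours respect the isoperimetric bound", {
  sc <- generateScene(sceneConfig(nCells = 80, seed = 62))
  cs <- vapply(cellPolygons(sc), circularity, 0)
  expect_true(all(cs <= 1.02))
  expect_true(all(cs > 0))
})

test_that("smooth placodes are rounder than their shifted boundaries", {
  cp <- co <- ci <- numeric(6)
  for (s in 1:6) {
    sc <- generateScene(sceneConfig(nCells = 50, surroundCells = 60,
                                    seed = 900 + s, pixelSize = 0.4))
    lab <- labelImage(sc)
    cp[s] <- tracePlacodeBoundary(lab, sc@placodeIds,
                                  pixelSize = 0.4)@circularity
    co[s] <- shiftBoundary(lab, sc@placodeIds, "outer",
                           pixelSize = 0.4)@circularity
    ci[s] <- shiftBoundary(lab, sc@placodeIds, "inner",
                           pixelSize = 0.4)@circularity
  }
  expect_true(all(cp > co) && all(cp > ci))
  rep <- circularityComparison(cp, outer = co, inner = ci)
  expect_lt(rep$placodeVsOuter$p, 0.05)
  expect_lt(rep$placodeVsInner$p, 0.05)
  expect_equal(rep$summary$mean[rep$summary$group == "placode"], mean(cp))
  expect_equal(rep$summary$sem[rep$summary$group == "outer"],
               sd(co) / sqrt(length(co)))
})

test_that("identical circularity groups give a zero t statistic", {
  rep <- circularityComparison(c(0.9, 0.9), outer = c(0.9, 0.9))
  expect_equal(rep$placodeVsOuter$t, 0)
})
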