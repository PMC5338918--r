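test_that("cell partition splits band and interior as the geometry dictates", {
  lab <- matrix(0L, 20, 20)
  lab[6:15, 6:15] <- 1L
  pc <- partitionCell(lab, 1L, bandWidth = 2, pixelSize = 1)
  # 10x10 square with a 1-px band: interior about 8x8
  expect_equal(sum(pc$apicomedial), 64)
  expect_false(pc$emptyMedial)
  # masks partition the cell exactly
  expect_equal(sum(pc$junctional) + sum(pc$apicomedial), 100)
  expect_equal(sum(pc$junctional & pc$apicomedial), 0)
  # a band wider than the inradius consumes the whole cell
  wide <- partitionCell(lab, 1L, bandWidth = 12, pixelSize = 1)
  expect_true(wide$emptyMedial)
  expect_error(partitionCell(lab, 1L, bandWidth = 0), "bandWidth")
  # pixel counts track exact polygon offsetting on a square cell:
  # inner square side = 10 - 2 * band/2
  expect_lt(abs(sum(pc$apicomedial) - (10 - 2)^2) / 64, 0.10)
})

test_that("integrated density is the clipped background-corrected sum", {
  img <- matrix(5, 4, 4)
  mask <- matrix(TRUE, 4, 4)
  expect_equal(integratedDensity(img, mask, 5), 0)
  expect_equal(integratedDensity(img, mask, 2), 16 * 3)
  expect_error(integratedDensity(img, matrix(FALSE, 4, 4)), "empty")
  # adding a constant and raising the background level changes nothing
  sc <- quietScene()
  lab <- labelImage(sc)
  pc <- partitionCell(lab, 3L, bandWidth = 0.4, pixelSize = 0.2)
  d0 <- integratedDensity(myosinImage(sc), pc$junctional, 0)
  d1 <- integratedDensity(myosinImage(sc) + 7.5, pc$junctional, 7.5)
  expect_equal(d0, d1)
})

test_that("medial density of rendered cells matches the configured pool", {
  sc <- quietScene()
  ip <- measureIntensityPartition(myosinImage(sc), labelImage(sc),
                                  bandWidth = sc@config@junctionWidth,
                                  pixelSize = 0.2, backgroundLevel = 0)
  expect_lt(max(abs(ip$apicomedial - sc@trueMedial) /
                pmax(sc@trueMedial, 1)), 0.10)
})

test_that("junctional:apicomedial ratio handles the degenerate pool", {
  p <- junctionalApicomedialRatio(data.frame(junctional = c(2, 3),
                                             apicomedial = c(2, 0)))
  expect_equal(p$ratio[1], 1)
  expect_true(is.na(p$ratio[2]))
  expect_true(p$undefined_ratio[2])
})

test_that("configured ratios are recovered within tolerance", {
  # noise and PSF on, measurement band matched to the rendered ridge
  for (r in c(0.5, 2)) {
    cfg <- sceneConfig(nCells = 40, seed = 55, medialRatio = r)
    sc <- renderChannels(generateScene(cfg))
    ip <- junctionalApicomedialRatio(measureIntensityPartition(
      myosinImage(sc), labelImage(sc),
      bandWidth = matchedBandWidth(cfg), pixelSize = cfg@pixelSize))
    expect_lt(abs(median(ip$ratio, na.rm = TRUE) - r) / r, 0.15)
  }
})

test_that("0-100 rescaling is the order-preserving affine map", {
  expect_equal(rescaleIntensity0100(c(2, 4, 6)), c(0, 50, 100))
  set.seed(56)
  v <- rnorm(50)
  rs <- rescaleIntensity0100(v)
  expect_equal(min(rs), 0)
  expect_equal(max(rs), 100)
  expect_equal(cor(rank(v), rank(rs)), 1)
  expect_error(rescaleIntensity0100(rep(3, 5)), "constant")
})

test_that("area-intensity correlation matches closed forms and nulls", {
  a <- seq(5, 30, length.out = 20)
  r <- areaIntensityCorrelation(a, 100 - 2 * a)
  expect_equal(r$R, -1)
  expect_equal(r$slope, -2)
  set.seed(57)
  for (i in 1:5) {
    x <- rnorm(1000); y <- rnorm(1000)
    expect_lt(abs(areaIntensityCorrelation(x, y)$R), 0.1)
  }
  expect_error(areaIntensityCorrelation(1:5, rep(2, 5)), "zero variance")
  expect_error(areaIntensityCorrelation(1:2, 1:2), "at least 3")
})

test_that("medial pools scaling as 1/area give a negative correlation", {
  geo <- generateScene(sceneConfig(nCells = 60, seed = 58))
  cfg <- sceneConfig(nCells = 60, seed = 58,
                     medialDensity = 3e4 / cellAreas(geo))
  sc <- renderChannels(generateScene(cfg))
  lab <- labelImage(sc)
  meanInt <- vapply(seq_along(cellAreas(sc)), function(i)
    mean(myosinImage(sc)[lab == i]), 0)
  r <- areaIntensityCorrelation(cellAreas(sc), rescaleIntensity0100(meanInt))
  expect_lt(r$R, -0.5)
})
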