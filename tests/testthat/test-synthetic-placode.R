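test_that("uniform field gives near-equal realized areas", {
  sc <- generateScene(sceneConfig(nCells = 100, fieldMode = "uniform",
                                  seed = 11))
  a <- cellAreas(sc)
  expect_lt(sd(a) / mean(a), 0.15)
})

test_that("clustered and random modes share the same area multiset", {
  scC <- geomScene("clustered", seed = 12)
  scR <- geomScene("random", seed = 12)
  aC <- sort(cellAreas(scC))
  aR <- sort(cellAreas(scR))
  expect_lt(max(abs(aC - aR) / aC), 0.15)
  # and the same target multiset exactly: random is a permutation
  expect_equal(sort(scC@targetAreas), sort(scR@targetAreas))
})

test_that("clustered mode constricts cells near the pit", {
  sc <- generateScene(sceneConfig(nCells = 150, fieldMode = "clustered",
                                  constrictionDepth = 0.5, seed = 13))
  ct <- cellTable(sc)
  sig <- sc@config@constrictionSigma
  near <- ct$area[ct$dist_pit < sig]
  far <- ct$area[ct$dist_pit > 3 * sig]
  expect_gt(length(near), 3)
  expect_gt(length(far), 3)
  expect_lt(mean(near), mean(far))
})

test_that("realized areas track targets within the declared tolerance", {
  for (mode in c("clustered", "uniform")) {
    sc <- generateScene(sceneConfig(nCells = 120, fieldMode = mode, seed = 14))
    expect_lt(max(abs(sc@areas - sc@targetAreas) / sc@targetAreas), 0.15)
  }
})

test_that("identical seed and config give bit-identical scenes", {
  cfg <- sceneConfig(nCells = 40, seed = 15)
  s1 <- renderChannels(generateScene(cfg))
  s2 <- renderChannels(generateScene(cfg))
  expect_identical(labelImage(s1), labelImage(s2))
  expect_identical(cellAreas(s1), cellAreas(s2))
  expect_identical(junctionImage(s1), junctionImage(s2))
  expect_identical(myosinImage(s1), myosinImage(s2))
})

test_that("per-cell areas conserve the total placode area", {
  sc <- generateScene(sceneConfig(nCells = 80, seed = 16))
  px <- sc@config@pixelSize
  union <- placodeQuant:::traceMask(labelImage(sc) > 0, px, simplifyTol = px / 2)
  expect_lt(abs(sum(cellAreas(sc)) - polygonArea(union)) / sum(cellAreas(sc)),
            0.005)
  # polygon shoelace areas agree with the pixel-count ground truth per cell
  shoe <- vapply(cellPolygons(sc), polygonArea, 0)
  expect_lt(max(abs(shoe - cellAreas(sc)) / cellAreas(sc)), 0.05)
})

test_that("sizing error is raised when the canvas cannot hold the cells", {
  expect_error(generateScene(sceneConfig(nCells = 200, canvasSize = 10,
                                         seed = 1)),
               "sizing")
})

test_that("rendered junction channel is the exact ridge without PSF or noise", {
  sc <- quietScene()
  J <- junctionImage(sc)
  expect_setequal(unique(as.vector(J)), c(0, sc@config@junctionAmp))
})

test_that("zero medial pool leaves eroded cell interiors empty", {
  cfg <- sceneConfig(nCells = 30, seed = 17, noiseModel = "none", psfSigma = 0,
                     background = 0, medialDensity = 0)
  sc <- renderChannels(generateScene(cfg))
  lab <- labelImage(sc)
  idist <- placodeQuant:::interfaceDistance(lab)
  interior <- lab > 0 & idist > cfg@junctionWidth / (2 * cfg@pixelSize)
  expect_equal(sum(myosinImage(sc)[interior]), 0)
})

test_that("pixel summation of rendered channels recovers the configured ratio", {
  sc <- quietScene()
  ip <- junctionalApicomedialRatio(measureIntensityPartition(
    myosinImage(sc), labelImage(sc),
    bandWidth = sc@config@junctionWidth, pixelSize = sc@config@pixelSize,
    backgroundLevel = 0))
  expect_lt(max(abs(ip$ratio - sc@config@medialRatio) / sc@config@medialRatio,
                na.rm = TRUE), 0.10)
})

test_that("ground truth round-trips through TIFF and CSV export", {
  sc <- renderChannels(generateScene(sceneConfig(nCells = 25, seed = 18)))
  d <- withr::local_tempdir()
  p <- exportGroundTruth(sc, d)
  expect_identical(readLabelTIFF(p$label), labelImage(sc))
  cells <- utils::read.csv(p$cells)
  expect_equal(nrow(cells), 25)
  cfg <- jsonlite::read_json(p$config)
  j <- readChannelTIFF(p$junction, cfg$junction_scale)
  # 16-bit quantisation: half a grey level at the recorded scale
  expect_lt(max(abs(j - junctionImage(sc))), cfg$junction_scale / 65535)
  expect_lt(abs(sum(cells$area) -
                polygonArea(placodeQuant:::traceMask(labelImage(sc) > 0,
                                                     sc@config@pixelSize))) /
            sum(cells$area), 0.005)
})

test_that("degenerate pulse configurations behave exactly", {
  tr <- generatePulseTraces(pulsationConfig(sdInterval = 0, meanInterval = 100,
                                            noiseSd = 0), 1, seed = 21)
  expect_equal(diff(tr[[1]]@eventTimes), rep(100, length(tr[[1]]@eventTimes) - 1))
  tr0 <- generatePulseTraces(pulsationConfig(amplitude = 0, noiseSd = 0,
                                             baseline = 10), 1, seed = 22)
  expect_equal(unique(tr0[[1]]@intensities), 10)
})

test_that("generated inter-pulse gaps match the configured statistics", {
  pcfg <- pulsationConfig(noiseSd = 0)
  tr <- generatePulseTraces(pcfg, nCells = 10, seed = 23)
  gaps <- unlist(lapply(tr, function(x) diff(x@eventTimes)))
  expect_gte(length(gaps), 50)
  se <- sd(gaps) / sqrt(length(gaps))
  expect_lt(abs(mean(gaps) - 131.7), 2 * se + 1.5) # + truncation shift bound
  # stationarity at large n: moments converge to the truncated-normal
  # values implied by the configuration (gaps resampled until > pulseWidth)
  trBig <- generatePulseTraces(pulsationConfig(nFrames = 1500L, noiseSd = 0),
                               nCells = 50, seed = 24)
  gBig <- unlist(lapply(trBig, function(x) diff(x@eventTimes)))
  expect_gte(length(gBig), 500)
  z <- (30 - 131.7) / 42.8
  lam <- dnorm(z) / (1 - pnorm(z))
  muTrunc <- 131.7 + 42.8 * lam
  sdTrunc <- 42.8 * sqrt(1 + z * lam - lam^2)
  expect_lt(abs(mean(gBig) / muTrunc - 1), 0.03)
  expect_lt(abs(sd(gBig) / sdTrunc - 1), 0.03)
})

test_that("too-short traces to estimate intervals raise a warning", {
  expect_warning(generatePulseTraces(pulsationConfig(nFrames = 40L), 1,
                                     seed = 25),
                 "shorter")
})
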