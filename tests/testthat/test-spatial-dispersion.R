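test_that("pit-relative coordinates follow the axis convention", {
  cells <- data.frame(cell_id = 1:3, centroid_x = c(10, 15, 10),
                      centroid_y = c(20, 23, 20), area = c(5, 6, 7))
  pf <- pitRelativeCoordinates(cells, c(10, 20))
  expect_equal(pf$dx, c(0, 5, 0))
  expect_equal(pf$dy, c(0, 3, 0))
  # mean displacement equals centroid-of-centroids minus pit
  expect_equal(c(mean(pf$dx), mean(pf$dy)),
               c(mean(cells$centroid_x) - 10, mean(cells$centroid_y) - 20))
  expect_error(pitRelativeCoordinates(cells), "pitCenter")
})

test_that("lower-quantile selection takes the smallest areas with id ties", {
  set.seed(51)
  cells <- data.frame(cell_id = 1:100, area = runif(100, 5, 30),
                      centroid_x = runif(100), centroid_y = runif(100))
  sub <- lowerQuantileCells(cells, 0.10)
  expect_equal(nrow(sub), 10)
  expect_lte(max(sub$area), min(cells$area[!cells$cell_id %in% sub$cell_id]))
  ties <- cells; ties$area <- 7
  expect_equal(lowerQuantileCells(ties, 0.2)$cell_id, 1:20)
  expect_error(lowerQuantileCells(cells, 1.2), "q must be")
})

test_that("dispersion statistics are sample SDs per axis", {
  expect_equal(dispersionStats(data.frame(dx = c(-1, 1), dy = c(0, 0))),
               c(sd_AP = sqrt(2), sd_DV = 0))
  one <- data.frame(dx = rep(2, 5), dy = rep(-3, 5))
  expect_equal(unname(dispersionStats(one)), c(0, 0))
  expect_error(dispersionStats(data.frame(dx = 1, dy = 1)), "at least 2")
  # translation invariance: shifting cells and pit together changes nothing
  sc <- geomScene("clustered", seed = 52)
  ct <- cellTable(sc)
  d0 <- dispersionStats(pitRelativeCoordinates(ct, pitCenter(sc)))
  ct2 <- ct
  ct2$centroid_x <- ct$centroid_x + 11.5
  ct2$centroid_y <- ct$centroid_y - 4.25
  d1 <- dispersionStats(pitRelativeCoordinates(ct2, pitCenter(sc) +
                                                 c(11.5, -4.25)))
  expect_equal(d0, d1)
})

test_that("constricted cells gather near the pit in clustered scenes", {
  sc <- geomScene("clustered", seed = 53)
  ct <- cellTable(sc)
  sub <- lowerQuantileCells(ct, 0.3)
  expect_lt(mean(sub$dist_pit), mean(ct$dist_pit))
})

test_that("clustered scenes disperse less than random ones along D/V", {
  wins <- 0L
  n <- 25L
  for (s in seq_len(n)) {
    scC <- geomScene("clustered", seed = 600 + s)
    scR <- geomScene("random", seed = 600 + s)
    dC <- dispersionStats(pitRelativeCoordinates(
      lowerQuantileCells(cellTable(scC), 0.3), pitCenter(scC)))
    dR <- dispersionStats(pitRelativeCoordinates(
      lowerQuantileCells(cellTable(scR), 0.3), pitCenter(scR)))
    wins <- wins + (dC[["sd_DV"]] < dR[["sd_DV"]])
  }
  expect_gte(wins / n, 0.95)
})

test_that("permutation p-value follows the add-one formula", {
  # constricted cells co-located: observed statistic beats every null draw
  set.seed(54)
  cells <- data.frame(cell_id = 1:50,
                      centroid_x = c(rep(5, 15), runif(35, 0, 100)),
                      centroid_y = c(rep(5, 15), runif(35, 0, 100)),
                      area = c(rep(1, 15), runif(35, 10, 30)))
  expect_warning(p <- clusteringPermutationTest(cells, q = 0.3, nPerm = 9),
                 "permutations")
  p <- clusteringPermutationTest(cells, q = 0.3, nPerm = 99, seed = 3)
  expect_equal(p, 0.01)
  expect_true(p > 0 && p <= 1)
})

test_that("clustering test has power on clustered fields", {
  hits <- 0L
  for (s in 1:10) {
    sc <- geomScene("clustered", seed = 700 + s)
    p <- clusteringPermutationTest(cellTable(sc), q = 0.3, nPerm = 199,
                                   seed = s)
    hits <- hits + (p < 0.05)
  }
  expect_gte(hits, 9)
})
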