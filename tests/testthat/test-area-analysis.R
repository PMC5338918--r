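test_that("area histogram percentages follow the bin definition", {
  ad <- areaDistribution(c(1, 3, 5, 9), binWidth = 4)
  expect_equal(ad@percentage, c(50, 25, 25))
  expect_equal(ad@binEdges, c(0, 4, 8, 12))
  expect_equal(ad@cumulative[length(ad@cumulative)], 100)
  expect_error(areaDistribution(numeric(0)), "no areas")
  expect_error(areaDistribution(c(1, -2)), "> 0")
  # cumulative always ends at 100
  set.seed(41)
  for (i in 1:5) {
    ad <- areaDistribution(rlnorm(50, 2.5, 0.5))
    expect_equal(ad@cumulative[length(ad@cumulative)], 100)
  }
})

test_that("histogram matches analytic lognormal bin masses", {
  set.seed(42)
  n <- 1000
  areas <- rlnorm(n, meanlog = 3, sdlog = 0.4)
  ad <- areaDistribution(areas, binWidth = 4)
  e <- ad@binEdges
  p <- plnorm(e[-1], 3, 0.4) - plnorm(e[-length(e)], 3, 0.4)
  # 3 binomial SEs per bin, plus a two-count allowance for the discreteness
  # of near-empty tail bins
  tol <- 3 * sqrt(n * p * (1 - p)) + 2
  expect_true(all(abs(ad@percentage / 100 * n - n * p) <= tol))
})

test_that("KS statistic equals the brute-force CDF gap maximum", {
  expect_equal(ksStatistic(1:5, 1:5), 0)
  expect_equal(ksStatistic(1:3, 11:13), 1)
  expect_equal(ksStatistic(c(1, 2, 3), c(2, 3, 4)), 1 / 3)
  set.seed(43)
  for (i in 1:25) {
    a <- round(runif(sample(2:20, 1), 0, 10), 1)
    b <- round(runif(sample(2:20, 1), 0, 10), 1)
    # oracle: scan every pooled point with stats::ecdf
    grid <- c(a, b)
    oracle <- max(abs(ecdf(a)(grid) - ecdf(b)(grid)))
    expect_equal(ksStatistic(a, b), oracle)
    expect_equal(ksStatistic(a, b), ksStatistic(b, a))
    expect_equal(ksStatistic(a, b),
                 unname(suppressWarnings(ks.test(a, b)$statistic)))
  }
})

test_that("distribution comparison reports U and D with p-values", {
  set.seed(44)
  a <- rlnorm(40, 3, 0.3)
  b <- rlnorm(45, 3.3, 0.3)
  rep <- compareDistributions(a, b)
  expect_equal(rep$U, unname(suppressWarnings(wilcox.test(a, b)$statistic)))
  expect_equal(rep$D, ksStatistic(a, b))
  expect_true(rep$pU > 0 && rep$pU <= 1 && rep$pKS > 0 && rep$pKS <= 1)
  expect_error(compareDistributions(1, a), "at least 2")
})

test_that("median scaling realizes the normalization factor exactly", {
  ms <- medianScale(c(10, 20, 30), c(12, 24, 36))
  expect_equal(ms$factor, 1.2)
  expect_equal(median(ms$scaled), 24)
  expect_equal(medianScale(1:9, 1:9)$factor, 1)
  ref <- c(3, 7, 12, 20)
  ms2 <- medianScale(ref / 2, ref)
  expect_equal(ms2$factor, 2)
  expect_equal(ms2$scaled, ref)
  # idempotence: a second application is the identity
  again <- medianScale(ms$scaled, c(12, 24, 36))
  expect_equal(again$factor, 1)
  expect_equal(again$scaled, ms$scaled)
  expect_error(medianScale(c(0, 0), 1:3), "positive")
})

test_that("area heat maps use a fixed shared scale", {
  sc <- geomScene("clustered", seed = 45)
  lab <- labelImage(sc)
  hm <- renderAreaHeatmap(lab, cellAreas(sc))
  # constant areas map to a single colour
  hm1 <- renderAreaHeatmap(lab, rep(5, length(cellAreas(sc))),
                           colorScale = c(0, 10))
  expect_equal(length(unique(hm1$mapped[!is.na(hm1$mapped)])), 1)
  # endpoint areas hit the scale endpoints
  lab2 <- matrix(0L, 6, 3); lab2[1:2, ] <- 1L; lab2[5:6, ] <- 2L
  hm2 <- renderAreaHeatmap(lab2, c(2, 8), colorScale = c(2, 8))
  expect_setequal(unique(hm2$mapped[!is.na(hm2$mapped)]), c(0, 1))
  # clustered field: mapped values near the pit are lower
  ct <- cellTable(sc)
  nearIds <- ct$cell_id[ct$dist_pit < 8]
  farIds <- ct$cell_id[ct$dist_pit > 24]
  expect_lt(mean(hm$mapped[lab %in% nearIds]),
            mean(hm$mapped[lab %in% farIds]))
})
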