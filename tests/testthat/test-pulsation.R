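test_that("peak detection finds apexes and rejects flat traces", {
  t <- seq(0, 500, by = 5)
  y <- 10 + 50 * exp(-(t - 250)^2 / (2 * 7.5^2))
  pk <- detectPeaks(y, times = t)
  expect_equal(length(pk), 1)
  expect_equal(t[pk], 250)
  expect_equal(length(detectPeaks(rep(3, 100), times = seq_len(100))), 0)
})

test_that("noiseless pulse pairs recover their interval to one frame", {
  t <- seq(0, 600, by = 5)
  y <- 10 + 50 * exp(-(t - 200)^2 / 112.5) + 50 * exp(-(t - 330)^2 / 112.5)
  tr <- new("PulseTrace", times = t, intensities = y, peaks = integer(0),
            intervals = numeric(0), eventTimes = c(200, 330))
  tr <- detectPeaks(tr)
  expect_equal(length(peakIndices(tr)), 2)
  expect_lte(abs(peakIntervals(tr) - 130), 5)
  # quantization bound over random noiseless placements
  set.seed(71)
  for (i in 1:10) {
    t1 <- runif(1, 100, 200); gap <- runif(1, 60, 250)
    y2 <- 10 + 50 * (exp(-(t - t1)^2 / 112.5) +
                     exp(-(t - t1 - gap)^2 / 112.5))
    tr2 <- detectPeaks(new("PulseTrace", times = t, intensities = y2,
                           peaks = integer(0), intervals = numeric(0),
                           eventTimes = c(t1, t1 + gap)))
    expect_lte(abs(peakIntervals(tr2) - gap), 5)
  }
})

test_that("intervals are invariant under time shifts", {
  tr <- generatePulseTraces(pulsationConfig(), 1, seed = 72)[[1]]
  tr <- detectPeaks(tr)
  shifted <- new("PulseTrace", times = tr@times + 1234,
                 intensities = tr@intensities, peaks = integer(0),
                 intervals = numeric(0), eventTimes = tr@eventTimes + 1234)
  shifted <- detectPeaks(shifted)
  expect_equal(peakIntervals(shifted), peakIntervals(tr))
})

test_that("interval statistics pool across cells", {
  tr1 <- new("PulseTrace", times = c(0, 100, 200), intensities = c(0, 1, 0),
             peaks = c(1L, 2L, 3L), intervals = c(100, 100),
             eventTimes = numeric(0))
  st <- intervalStatistics(list(tr1))
  expect_equal(st$mean, 100)
  expect_equal(st$sd, 0)
  expect_equal(st$nIntervals, 2)
  empty <- new("PulseTrace", times = as.numeric(1:10),
               intensities = rep(0, 10), peaks = integer(0),
               intervals = numeric(0), eventTimes = numeric(0))
  expect_error(intervalStatistics(list(empty)), "no inter-peak")
})

test_that("detection is sensitive and precise on generator traces", {
  tr <- lapply(generatePulseTraces(pulsationConfig(), 30, seed = 73),
               detectPeaks)
  tp <- np <- ne <- 0
  for (x in tr) {
    pk <- x@times[x@peaks]
    ev <- x@eventTimes[x@eventTimes >= 0 & x@eventTimes <= max(x@times)]
    used <- logical(length(ev))
    for (p in pk) {
      j <- which(!used & abs(ev - p) <= 30)
      if (length(j)) { used[j[1]] <- TRUE; tp <- tp + 1 }
    }
    np <- np + length(pk); ne <- ne + length(ev)
  }
  expect_gte(tp / ne, 0.9)
  expect_gte(tp / np, 0.9)
})

test_that("pooled interval estimates recover the generating parameters", {
  tr <- generatePulseTraces(pulsationConfig(), 60, seed = 74)
  st <- intervalStatistics(tr)
  expect_gte(st$nIntervals, 200)
  expect_lt(abs(st$mean - 131.7) / 131.7, 0.05)
  expect_lt(abs(st$sd - 42.8) / 42.8, 0.15)
  expect_equal(st$nCells, 60)
  expect_equal(length(st$perCellMean), 60)
})
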