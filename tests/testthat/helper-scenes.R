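# Scenes shared across test files, built once per run.
.sceneCache <- new.env(parent = emptyenv())

cachedScene <- function(key, builder) {
  if (is.null(.sceneCache[[key]])) assign(key, builder(), envir = .sceneCache)
  get(key, envir = .sceneCache)
}

# default study conditions: 150 cells, clustered field, PSF + shot noise
defaultScene <- function() cachedScene("default150", function()
  renderChannels(generateScene(sceneConfig(nCells = 150, seed = 1))))

# small noise- and blur-free scene for exact rendering checks
quietScene <- function() cachedScene("quiet40", function()
  renderChannels(generateScene(sceneConfig(
    nCells = 40, seed = 2, noiseModel = "none", psfSigma = 0,
    background = 0))))

# geometry-only scene at coarser raster for Monte-Carlo suites
geomScene <- function(mode, seed, nCells = 150L) {
  generateScene(sceneConfig(nCells = nCells, fieldMode = mode, seed = seed,
                            pixelSize = 0.4))
}

# match segmented cells to ground-truth cells by nearest centroid
matchToTruth <- function(segCells, trueCells) {
  vapply(seq_len(nrow(segCells)), function(i) {
    which.min((trueCells$centroid_x - segCells$centroid_x[i])^2 +
              (trueCells$centroid_y - segCells$centroid_y[i])^2)
  }, 0L)
}

# label image of an nx-by-ny grid of square cells, cellPx pixels on a side,
# with a background border
squareGridLabels <- function(nx, ny, cellPx, border = 2L) {
  lab <- matrix(0L, nx * cellPx + 2L * border, ny * cellPx + 2L * border)
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    lab[border + (i - 1L) * cellPx + seq_len(cellPx),
        border + (j - 1L) * cellPx + seq_len(cellPx)] <-
      i + (j - 1L) * nx
  }
  lab
}

diskMask <- function(n, radiusPx, center = c(n, n) / 2) {
  ij <- expand.grid(i = seq_len(n), j = seq_len(n))
  m <- matrix(FALSE, n, n)
  m[as.matrix(ij[, 1:2])] <-
    (ij$i - 0.5 - center[1])^2 + (ij$j - 0.5 - center[2])^2 <= radiusPx^2
  m
}
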