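#' Generate a synthetic placode with known per-cell geometry
#'
#' Builds the ground-truth geometry of a placode: \code{nCells} polygonal
#' cells tiling a disk, realised by a capacity-adjusted power-diagram
#' tessellation with Lloyd relaxation so that each cell's pixel area
#' approaches its target area. Targets follow the configured spatial field:
#' in \code{"clustered"} mode the expected area grows with distance d from
#' the pit as \code{baseArea * (1 - constrictionDepth * exp(-d^2 / (2 *
#' constrictionSigma^2)))}, mimicking clustered apical constriction around
#' the invagination pit; \code{"random"} spatially permutes the same target
#' multiset (dispersed constriction, as in *fog* mutants); \code{"uniform"}
#' and \code{"expanded"} are flat fields at \code{baseArea} and
#' \code{baseArea * (1 + constrictionDepth)}. Target areas are rescaled by a
#' common factor so they sum to the tessellated disk area. With
#' \code{surroundCells > 0} an annulus of surrounding epithelial cells is
#' tessellated in the same pass, and pixels are partitioned exactly at the
#' placode disk so the placode outline stays a smooth circle.
#'
#' \code{pitCenter} in the configuration is interpreted relative to the
#' placode centre; the default places the pit halfway towards the posterior
#' (+x) edge, as in the dorsal-posterior pit of the salivary-gland placode.
#'
#' @param config a [SceneConfig-class].
#' @return A [PlacodeScene-class] with geometry filled in and empty channel
#'   images (see [renderChannels()]).
#' @examples
#' sc <- generateScene(sceneConfig(nCells = 30, seed = 1))
#' sc
#' @seealso [renderChannels()], [exportGroundTruth()], [cellTable()]
#' @export
generateScene <- function(config) {
  validObject(config)
  set.seed(config@seed)
  nC <- config@nCells
  nS <- config@surroundCells
  px <- config@pixelSize

  r0 <- sqrt(nC * config@baseArea / pi)
  r2 <- if (nS > 0) sqrt(r0^2 + nS * config@baseArea / pi) else r0
  side <- 2 * (r2 + config@margin)
  if (!is.na(config@canvasSize)) {
    if (config@canvasSize < 2 * r2 + 2 * px)
      stop(sprintf(
        "sizing error: %d cells need a canvas of at least %.1f um, got %.1f um",
        nC + nS, 2 * r2 + 2 * px, config@canvasSize))
    side <- config@canvasSize
  }
  ctr <- c(side / 2, side / 2)

  sampleDisk <- function(n, rmin, rmax) {
    out <- matrix(NA_real_, n, 2)
    got <- 0L
    while (got < n) {
      p <- matrix(stats::runif(2L * (n - got), -rmax, rmax), ncol = 2)
      r <- sqrt(rowSums(p^2))
      p <- p[r <= rmax & r >= rmin, , drop = FALSE]
      take <- min(nrow(p), n - got)
      if (take > 0) out[(got + 1L):(got + take), ] <- p[seq_len(take), ]
      got <- got + take
    }
    out
  }
  seedsP <- sampleDisk(nC, 0, 0.95 * r0)
  pit <- if (anyNA(config@pitCenter)) c(r0 / 2, 0) else config@pitCenter

  d <- sqrt((seedsP[, 1] - pit[1])^2 + (seedsP[, 2] - pit[2])^2)
  fld <- config@baseArea *
    (1 - config@constrictionDepth * exp(-d^2 / (2 * config@constrictionSigma^2)))
  targets <- switch(config@fieldMode,
    clustered = fld,
    random = fld[sample.int(nC)],
    uniform = rep(config@baseArea, nC),
    expanded = rep(config@baseArea * (1 + config@constrictionDepth), nC))
  targets <- targets * (pi * r0^2) / sum(targets)

  seeds <- seedsP
  groups <- rep(0L, nC)
  if (nS > 0) {
    seedsS <- sampleDisk(nS, r0 + 0.02 * (r2 - r0), 0.98 * r2)
    tS <- rep(pi * (r2^2 - r0^2) / nS, nS)
    seeds <- rbind(seeds, seedsS)
    targets <- c(targets, tS)
    groups <- c(groups, rep(1L, nS))
  }
  seeds <- sweep(seeds, 2, ctr, "+")
  pit <- pit + ctr

  nx <- ny <- as.integer(round(side / px))
  cx <- (seq_len(nx) - 0.5) * px
  cy <- (seq_len(ny) - 0.5) * px
  gx <- rep(cx, times = ny)
  gy <- rep(cy, each = nx)
  rr <- sqrt((gx - ctr[1])^2 + (gy - ctr[2])^2)
  pgroup <- ifelse(rr <= r0, 0L, ifelse(nS > 0 & rr <= r2, 1L, NA_integer_))
  keep <- !is.na(pgroup)

  ts <- .powerDiagram(gx[keep], gy[keep], pgroup[keep], seeds, groups,
                      targets, px^2, nIter = 80L, lloydIters = 40L, eta = 0.4)
  if (any(ts$area <= 0))
    stop("tessellation produced an empty cell; reduce nCells or enlarge the canvas")

  label <- matrix(0L, nx, ny)
  label[keep] <- ts$assign + 1L

  n <- nC + nS
  polys <- vector("list", n)
  for (i in seq_len(n)) {
    polys[[i]] <- traceCellPolygon(label, i, px)
  }

  adj <- labelAdjacency(label)
  isPlacode <- function(l) l >= 1L & l <= nC
  bnd <- logical(n)
  for (k in seq_len(nrow(adj))) {
    a <- adj[k, 1]; b <- adj[k, 2]
    if (isPlacode(b) && !isPlacode(a)) bnd[b] <- TRUE
    if (a >= 1L && isPlacode(a) && !isPlacode(b)) bnd[a] <- TRUE
    if (a >= 1L && !isPlacode(a) && b > 0) { # surround cell at annulus edge
      if (a > nC && b == 0) bnd[a] <- TRUE
    }
  }
  # surround cells touching background
  if (nS > 0) {
    for (k in seq_len(nrow(adj))) {
      if (adj[k, 1] == 0L && adj[k, 2] > nC) bnd[adj[k, 2]] <- TRUE
    }
  }

  new("PlacodeScene", labelImage = label, polygons = polys,
      areas = ts$area, targetAreas = targets, centroids = ts$centroids,
      pitCenter = pit, placodeIds = seq_len(nC), boundaryCell = bnd,
      junctionImage = matrix(numeric(0), 0, 0),
      myosinImage = matrix(numeric(0), 0, 0),
      trueJunctional = numeric(0), trueMedial = numeric(0),
      trueRatio = numeric(0), config = config)
}

# Trace one cell's outline from the label raster (cropped for speed).
traceCellPolygon <- function(label, id, pixelSize, simplifyTol = 0.5 * pixelSize) {
  idx <- which(label == id, arr.ind = TRUE)
  x0 <- min(idx[, 1]); x1 <- max(idx[, 1])
  y0 <- min(idx[, 2]); y1 <- max(idx[, 2])
  sub <- label[x0:x1, y0:y1, drop = FALSE] == id
  ring <- traceMask(sub, pixelSize, simplifyTol)
  ring[, 1] <- ring[, 1] + (x0 - 1L) * pixelSize
  ring[, 2] <- ring[, 2] + (y0 - 1L) * pixelSize
  ring
}

#' Render the junctional and myosin channels of a scene
#'
#' Fills in the two intensity channels. The junctional-marker channel is a
#' ridge of width \code{junctionWidth} along every cell-cell and
#' cell-background interface at amplitude \code{junctionAmp}. The myosin
#' channel is the same ridge at \code{myosinJunctionAmp} (junctional myosin)
#' plus, for every placode cell, a centred Gaussian apicomedial blob whose
#' integrated density over the cell interior equals the configured
#' apicomedial density - either \code{medialDensity} directly or the cell's
#' junctional density divided by \code{medialRatio}. Both channels are then
#' PSF-blurred (Gaussian, \code{psfSigma}), offset by \code{background} and,
#' under the \code{"poisson"} noise model, replaced by Poisson draws of the
#' expected counts.
#'
#' @param scene a [PlacodeScene-class] from [generateScene()].
#' @return The scene with \code{junctionImage}, \code{myosinImage} and the
#'   per-cell ground-truth intensity pools filled in.
#' @examples
#' sc <- renderChannels(generateScene(sceneConfig(nCells = 20, seed = 3)))
#' range(junctionImage(sc))
#' @export
renderChannels <- function(scene) {
  cfg <- scene@config
  px <- cfg@pixelSize
  label <- scene@labelImage
  n <- length(scene@areas)
  nC <- length(scene@placodeIds)

  idist <- interfaceDistance(label)
  # pixel centre at interface distance d is d + 0.5 px from the contour
  half <- max(cfg@junctionWidth / (2 * px) - 0.5, 0)
  band <- label > 0L & idist <= half

  bandCount <- tabulate(label[band], nbins = n)
  trueJ <- cfg@myosinJunctionAmp * bandCount

  ratio <- rep_len(cfg@medialRatio, nC)
  if (length(cfg@medialDensity)) {
    dens <- rep_len(cfg@medialDensity, nC)
  } else {
    dens <- trueJ[seq_len(nC)] / ratio
  }

  junction <- cfg@junctionAmp * band
  myosin <- cfg@myosinJunctionAmp * band
  trueM <- numeric(n)
  # keep the medial pool clear of the PSF-spread junctional ridge so the two
  # pools stay separable by a band of width junctionWidth + O(psfSigma)
  inset <- max(half, (cfg@junctionWidth / 2 + 3 * cfg@psfSigma) / px - 0.5)
  for (i in seq_len(nC)) {
    if (dens[i] <= 0) next
    inner <- which(label == i & idist > inset)
    if (!length(inner)) inner <- which(label == i & idist > half)
    if (!length(inner)) next
    ij <- arrayInd(inner, dim(label))
    wx <- (ij[, 1] - 0.5) * px - scene@centroids[i, 1]
    wy <- (ij[, 2] - 0.5) * px - scene@centroids[i, 2]
    sig <- 0.25 * sqrt(scene@areas[i])
    w <- exp(-(wx^2 + wy^2) / (2 * sig^2))
    myosin[inner] <- myosin[inner] + dens[i] * w / sum(w)
    trueM[i] <- dens[i]
  }

  if (cfg@psfSigma > 0) {
    s <- cfg@psfSigma / px
    junction <- matrix(EBImage::imageData(
      EBImage::gblur(EBImage::Image(junction), sigma = s)), nrow(label))
    myosin <- matrix(EBImage::imageData(
      EBImage::gblur(EBImage::Image(myosin), sigma = s)), nrow(label))
  }
  junction <- junction + cfg@background
  myosin <- myosin + cfg@background
  if (cfg@noiseModel == "poisson") {
    set.seed(cfg@seed + 1000003L)
    junction <- matrix(stats::rpois(length(junction), pmax(junction, 0)),
                       nrow(label))
    myosin <- matrix(stats::rpois(length(myosin), pmax(myosin, 0)),
                     nrow(label))
  }

  scene@junctionImage <- junction
  scene@myosinImage <- myosin
  scene@trueJunctional <- trueJ
  scene@trueMedial <- trueM
  scene@trueRatio <- ifelse(trueM > 0, trueJ / trueM, NA_real_)
  scene
}

#' Read and write label and channel TIFFs
#'
#' Label images are written as 16-bit single-channel TIFFs (labels must be
#' below 65536) and round-trip exactly. Channel images are scaled to the
#' unit interval by their maximum before 16-bit quantisation; the scale is
#' returned (and recorded by [exportGroundTruth()]) so intensities can be
#' restored.
#'
#' @param label integer matrix of labels.
#' @param image numeric matrix of intensities (a.u.).
#' @param path TIFF file path.
#' @param scale intensity value mapped to the 16-bit maximum.
#' @return \code{writeChannelTIFF()} returns the scale used;
#'   \code{readLabelTIFF()} an integer matrix; \code{readChannelTIFF()} a
#'   numeric matrix.
#' @export
writeLabelTIFF <- function(label, path) {
  if (max(label) > 65535L) stop("labels exceed 16-bit range")
  tiff::writeTIFF(t(label) / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' @rdname writeLabelTIFF
#' @export
readLabelTIFF <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(t(m) * 65535)), ncol(m), nrow(m))
}

#' @rdname writeLabelTIFF
#' @export
writeChannelTIFF <- function(image, path, scale = max(image, 1e-12)) {
  tiff::writeTIFF(pmin(pmax(t(image) / scale, 0), 1), path,
                  bits.per.sample = 16L, compression = "none")
  invisible(scale)
}

#' @rdname writeLabelTIFF
#' @export
readChannelTIFF <- function(path, scale = 1) {
  m <- tiff::readTIFF(path)
  t(m) * scale
}

#' Export a scene's ground truth to disk
#'
#' Writes the label image, the rendered channels (if present), the per-cell
#' table and a JSON echo of the configuration (including the channel
#' quantisation scales) into a directory.
#'
#' @param scene a [PlacodeScene-class].
#' @param dir output directory (created if missing).
#' @return Invisibly, a named list of the written file paths.
#' @export
exportGroundTruth <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    label = file.path(dir, "label.tif"),
    cells = file.path(dir, "cells.csv"),
    config = file.path(dir, "scene_config.json"))
  writeLabelTIFF(scene@labelImage, paths$label)
  utils::write.csv(cellTable(scene), paths$cells, row.names = FALSE)
  cfgList <- sceneConfigAsList(scene@config)
  if (length(scene@junctionImage)) {
    paths$junction <- file.path(dir, "junction.tif")
    paths$myosin <- file.path(dir, "myosin.tif")
    cfgList$junction_scale <- writeChannelTIFF(scene@junctionImage, paths$junction)
    cfgList$myosin_scale <- writeChannelTIFF(scene@myosinImage, paths$myosin)
  }
  jsonlite::write_json(cfgList, paths$config, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

sceneConfigAsList <- function(cfg) {
  sl <- methods::slotNames(cfg)
  out <- lapply(sl, function(s) methods::slot(cfg, s))
  names(out) <- sl
  out
}
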