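#' Maximum-intensity projection of selected focal planes
#'
#' Pixelwise maximum over the chosen planes of a z-stack, as used to
#' collapse the two or three apical focal planes of a confocal stack into
#' one image before segmentation.
#'
#' @param stack 3D numeric array \code{[x, y, z]} (a matrix is treated as a
#'   single-plane stack).
#' @param planeIndices planes to project; defaults to all.
#' @return A numeric matrix.
#' @examples
#' st <- array(runif(32), dim = c(4, 4, 2))
#' mp <- maxProject(st)
#' @export
maxProject <- function(stack, planeIndices = NULL) {
  if (is.matrix(stack)) stack <- array(stack, dim = c(dim(stack), 1L))
  nz <- dim(stack)[3]
  if (is.null(planeIndices)) planeIndices <- seq_len(nz)
  if (any(planeIndices < 1L | planeIndices > nz))
    stop("plane index out of range")
  out <- stack[, , planeIndices[1]]
  for (k in planeIndices[-1]) out <- pmax(out, stack[, , k])
  out
}

#' Segment apical cell outlines from a junctional-marker image
#'
#' Seeded-watershed segmentation along the junctional signal: the image is
#' Gaussian-smoothed, thresholded (Otsu by default) to separate bright
#' junctional ridges from cell interiors, and the distance transform of the
#' interiors is watershed-split into one basin per cell (shallow maxima are
#' merged by \code{tolerance}). Basin labels are then propagated across the
#' remaining junction-line pixels of the mask so every mask pixel is
#' assigned, and regions smaller than \code{minArea} are dissolved into
#' their surroundings. All steps are deterministic.
#'
#' @param junctionImage numeric matrix (a.u.), junctional-marker channel.
#' @param mask logical matrix of tissue pixels (same shape); \code{NULL}
#'   uses the whole image.
#' @param pixelSize micrometres per pixel.
#' @param smoothSigma Gaussian pre-smoothing sigma in pixels.
#' @param threshold junction/interior intensity threshold on the smoothed,
#'   0-1-normalised image; \code{NULL} for Otsu's method within the mask.
#' @param tolerance watershed merge tolerance on the distance transform
#'   (pixels); larger values merge more over-segmented fragments.
#' @param minArea smallest retained cell area (um^2).
#' @return A list with \code{labels} (integer matrix, 0 = background,
#'   labels in raster order of first occurrence) and \code{cells}, a
#'   data.frame with columns \code{cell_id}, \code{area} (um^2, pixel count
#'   times pixel area), \code{centroid_x}, \code{centroid_y} (um),
#'   \code{boundary_cell} (touches the mask edge) and \code{polygon_area}
#'   (um^2, shoelace area of the traced outline), plus the traced
#'   \code{polygons} as an attribute.
#' @examples
#' sc <- renderChannels(generateScene(sceneConfig(nCells = 25, seed = 4)))
#' seg <- segmentCells(junctionImage(sc), labelImage(sc) > 0, pixelSize = 0.2)
#' nrow(seg$cells)
#' @export
segmentCells <- function(junctionImage, mask = NULL, pixelSize = 1,
                         smoothSigma = 1, threshold = NULL, tolerance = 1,
                         minArea = 4) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(junctionImage), ncol(junctionImage))
  if (!all(dim(mask) == dim(junctionImage)))
    stop("image and mask must have the same shape")
  mask <- mask > 0
  if (!any(mask)) stop("no cells: the tissue mask is empty")

  sm <- junctionImage
  if (smoothSigma > 0)
    sm <- matrix(EBImage::imageData(
      EBImage::gblur(EBImage::Image(junctionImage), sigma = smoothSigma)),
      nrow(junctionImage))
  rng <- range(sm[mask])
  if (diff(rng) == 0) {
    # constant signal: nothing to segment along; the mask is one region
    labels <- matrix(0L, nrow(mask), ncol(mask))
    labels[mask] <- 1L
    return(list(labels = labels,
                cells = segmentTable(labels, mask, pixelSize)))
  }
  nrm <- (sm - rng[1]) / diff(rng)
  nrm[!mask] <- 1  # outside the tissue counts as "junction", not interior
  thr <- if (is.null(threshold)) EBImage::otsu(EBImage::Image(nrm)) else threshold

  interior <- mask & (nrm < thr)
  dm <- EBImage::distmap(EBImage::Image(interior * 1))
  ws <- EBImage::watershed(dm, tolerance = tolerance, ext = 1)
  seeds <- matrix(as.integer(EBImage::imageData(ws)), nrow(mask))
  if (max(seeds) == 0L) stop("no cells: no interior basins found")

  filled <- EBImage::propagate(EBImage::Image(nrm), EBImage::Image(seeds),
                               mask = EBImage::Image(mask * 1), lambda = 1e-4)
  labels <- matrix(as.integer(EBImage::imageData(filled)), nrow(mask))

  # dissolve fragments below minArea into their most-adjacent neighbour
  minPix <- max(1L, round(minArea / pixelSize^2))
  repeat {
    cnt <- tabulate(labels[labels > 0L], nbins = max(labels))
    small <- which(cnt > 0L & cnt < minPix)
    if (!length(small)) break
    adj <- labelAdjacency(labels)
    changed <- FALSE
    for (s in small) {
      nb <- c(adj[adj[, 1] == s, 2], adj[adj[, 2] == s, 1])
      nb <- nb[nb > 0L & nb != s]
      if (length(nb)) {
        # merge into the neighbour sharing the longest border
        labels[labels == s] <- as.integer(names(which.max(table(nb))))
        changed <- TRUE
      } else {
        labels[labels == s] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  labels <- relabelRasterOrder(labels)
  list(labels = labels, cells = segmentTable(labels, mask, pixelSize))
}

relabelRasterOrder <- function(labels) {
  u <- unique(as.integer(labels))
  u <- u[u > 0L]
  map <- integer(max(c(u, 0L)))
  map[u] <- seq_along(u)  # unique() returns labels in raster-scan order
  out <- labels
  out[labels > 0L] <- map[labels[labels > 0L]]
  out
}

segmentTable <- function(labels, mask, pixelSize) {
  n <- max(labels)
  idx <- which(labels > 0L)
  ij <- arrayInd(idx, dim(labels))
  lab <- labels[idx]
  cnt <- tabulate(lab, nbins = n)
  cx <- (vapply(split((ij[, 1] - 0.5) * pixelSize, lab), mean, 0))
  cy <- (vapply(split((ij[, 2] - 0.5) * pixelSize, lab), mean, 0))
  edge <- ij[, 1] == 1L | ij[, 1] == nrow(labels) |
          ij[, 2] == 1L | ij[, 2] == ncol(labels)
  # pixels adjacent to non-mask: boundary of the tissue
  dmask <- interfaceDistance((mask > 0) * 1L)
  touches <- dmask[idx] <= 1
  onBnd <- vapply(split(touches | edge, lab), any, TRUE)
  polys <- lapply(seq_len(n), function(i) traceCellPolygon(labels, i, pixelSize))
  df <- data.frame(cell_id = seq_len(n),
                   area = cnt * pixelSize^2,
                   centroid_x = as.numeric(cx),
                   centroid_y = as.numeric(cy),
                   boundary_cell = as.logical(onBnd),
                   polygon_area = vapply(polys, polygonArea, 0))
  attr(df, "polygons") <- polys
  df
}

#' Classify the invagination stage of a placode
#'
#' Applies the depth thresholds of the four-stage invagination series:
#' cells internalized more than 2 um put the sample at deep invagination;
#' any internalization up to 2 um marks the beginning of invagination
#' (cells one to a few focal planes, 0.37-1.11 um, below their neighbours);
#' with every cell at the surface the sample is at clustered apical
#' constriction if the smallest-area cells are significantly clustered in
#' space ([clusteringPermutationTest()] p below \code{clusteringAlpha}),
#' and before invagination otherwise. Depth must be supplied per cell (from
#' focal-plane offsets in real data; ground truth in synthetic data) - it
#' cannot be inferred from a single projection.
#'
#' @param cells data.frame with columns \code{area}, \code{centroid_x},
#'   \code{centroid_y} and \code{depth} (um).
#' @param clusteringAlpha significance level of the clustering test.
#' @param q area quantile defining the "constricted" subset.
#' @param nPerm permutation count.
#' @param seed RNG seed for the permutation test.
#' @return A [StageCall-class].
#' @examples
#' sc <- generateScene(sceneConfig(nCells = 60, seed = 5))
#' classifyStage(cellTable(sc))
#' @export
classifyStage <- function(cells, clusteringAlpha = 0.05, q = 0.3,
                          nPerm = 499, seed = 1L) {
  if (is.null(cells$depth) || anyNA(cells$depth))
    stop("stage classification requires a per-cell 'depth' column (um)")
  md <- max(cells$depth)
  if (md > 2) {
    return(new("StageCall", stage = "deep_invagination", maxDepth = md,
               clusteringP = NA_real_))
  }
  if (md > 0) {
    return(new("StageCall", stage = "beginning_invagination", maxDepth = md,
               clusteringP = NA_real_))
  }
  p <- clusteringPermutationTest(cells, q = q, nPerm = nPerm, seed = seed)
  stage <- if (p < clusteringAlpha) "clustered_constriction" else
    "before_invagination"
  new("StageCall", stage = stage, maxDepth = 0, clusteringP = p)
}
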