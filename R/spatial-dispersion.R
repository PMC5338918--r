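#' Pit-relative cell coordinates
#'
#' Expresses cell centroids relative to the invagination pit: \code{dx} is
#' the signed distance along the A/P axis (x) and \code{dy} along the D/V
#' axis (y), with the pit at the origin.
#'
#' @param cells data.frame with \code{centroid_x}, \code{centroid_y} (um)
#'   and (carried through) \code{cell_id} and \code{area}.
#' @param pitCenter numeric length-2 pit position (um).
#' @return A data.frame with \code{cell_id}, \code{dx}, \code{dy} and, when
#'   present in the input, \code{area}.
#' @examples
#' sc <- generateScene(sceneConfig(nCells = 30, seed = 7))
#' pf <- pitRelativeCoordinates(cellTable(sc), pitCenter(sc))
#' @export
pitRelativeCoordinates <- function(cells, pitCenter) {
  if (missing(pitCenter) || length(pitCenter) != 2L || anyNA(pitCenter))
    stop("pitCenter (x, y) is required")
  out <- data.frame(
    cell_id = if (!is.null(cells$cell_id)) cells$cell_id else seq_len(nrow(cells)),
    dx = cells$centroid_x - pitCenter[1],
    dy = cells$centroid_y - pitCenter[2])
  if (!is.null(cells$area)) out$area <- cells$area
  out
}

#' Cells in the lower apical-area quantile
#'
#' The \code{floor(q * n)} cells with the smallest apical areas - the
#' "most constricted" subset plotted against all cells in pit-relative
#' scatter plots. Ties are broken by \code{cell_id} for determinism.
#'
#' @param cells data.frame with \code{area} and \code{cell_id} columns.
#' @param q quantile in (0, 1); typically 0.10, 0.20 or 0.30.
#' @return The subset of rows, ordered by area then id.
#' @examples
#' sc <- generateScene(sceneConfig(nCells = 40, seed = 8))
#' nrow(lowerQuantileCells(cellTable(sc), 0.3))
#' @export
lowerQuantileCells <- function(cells, q) {
  if (q <= 0 || q >= 1) stop("q must be in (0, 1)")
  k <- floor(q * nrow(cells))
  ord <- order(cells$area, cells$cell_id)
  cells[ord[seq_len(k)], , drop = FALSE]
}

#' Axis-wise dispersion of pit-relative positions
#'
#' Sample (n - 1) standard deviations of the pit-relative A/P and D/V
#' coordinates, the dispersion measure used to compare how tightly
#' constricted cells gather around the pit.
#'
#' @param pitFrame data.frame with \code{dx}, \code{dy} columns (um), as
#'   from [pitRelativeCoordinates()].
#' @return Named numeric vector \code{c(sd_AP, sd_DV)} (um).
#' @examples
#' dispersionStats(data.frame(dx = c(-1, 1), dy = c(0, 0)))
#' @export
dispersionStats <- function(pitFrame) {
  if (nrow(pitFrame) < 2L) stop("need at least 2 cells for dispersion")
  c(sd_AP = stats::sd(pitFrame$dx), sd_DV = stats::sd(pitFrame$dy))
}

#' Permutation test for spatial clustering of constricted cells
#'
#' Tests whether the smallest-area cells sit closer together than expected
#' if constriction were assigned to cells at random. The observed statistic
#' is the mean pairwise centroid distance among the lower-\code{q} cells;
#' the null resamples which cells are "constricted" (random relabelling of
#' the same centroids) \code{nPerm} times. The p-value uses the add-one
#' correction \code{p = (1 + #\{null <= observed\}) / (nPerm + 1)}, so it is
#' never exactly zero.
#'
#' @param cells data.frame with \code{area}, \code{cell_id},
#'   \code{centroid_x}, \code{centroid_y}.
#' @param q area quantile defining the constricted subset.
#' @param nPerm number of permutations (a warning is given below 99).
#' @param seed RNG seed.
#' @return The permutation p-value in (0, 1].
#' @examples
#' sc <- generateScene(sceneConfig(nCells = 80, seed = 9))
#' clusteringPermutationTest(cellTable(sc), nPerm = 199)
#' @export
clusteringPermutationTest <- function(cells, q = 0.3, nPerm = 999, seed = 1L) {
  if (nrow(cells) < 10L) stop("need at least 10 cells")
  if (nPerm < 99) warning("fewer than 99 permutations; p-value resolution is poor")
  xy <- cbind(cells$centroid_x, cells$centroid_y)
  k <- floor(q * nrow(cells))
  if (k < 2L) stop("lower-quantile subset has fewer than 2 cells")
  ord <- order(cells$area, cells$cell_id)
  obs <- .meanPairwiseDist(xy[ord[seq_len(k)], , drop = FALSE])
  set.seed(as.integer(seed))
  null <- vapply(seq_len(nPerm), function(i) {
    .meanPairwiseDist(xy[sample.int(nrow(xy), k), , drop = FALSE])
  }, 0)
  (1 + sum(null <= obs)) / (nPerm + 1)
}

#' Estimate the pit centre from deep cells
#'
#' On real data the pit is located morphologically: when cells internalized
#' deeper than 2 um exist, the pit is taken as the centroid of those cells;
#' otherwise the pit must be supplied by the user.
#'
#' @param cells data.frame with \code{centroid_x}, \code{centroid_y},
#'   \code{depth}.
#' @param depthThreshold internalization depth (um) defining pit cells.
#' @return Numeric length-2 pit estimate, or \code{NULL} when no cell
#'   exceeds the threshold.
#' @export
estimatePitCenter <- function(cells, depthThreshold = 2) {
  deep <- cells$depth > depthThreshold
  if (!any(deep)) return(NULL)
  c(mean(cells$centroid_x[deep]), mean(cells$centroid_y[deep]))
}
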