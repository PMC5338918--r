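#' Trace the placode boundary
#'
#' Traces the outline of the union of the given placode cells as a
#' sub-pixel marching-squares contour of the label raster, simplified with
#' a one-pixel tolerance so staircase artefacts do not inflate the
#' perimeter. When a ventral midline is given and the placode reaches it,
#' the contour is closed by the straight midline chord (the embryo midline
#' serves as the ventral boundary of the traced shape); by default the
#' chord contributes to the perimeter.
#'
#' @param labels integer label matrix.
#' @param placodeIds labels forming the placode; they must form one
#'   edge-connected component.
#' @param pixelSize micrometres per pixel.
#' @param midlineY ventral midline position (um, larger y = more ventral)
#'   or \code{NULL}.
#' @param chordInPerimeter count the midline chord in the perimeter?
#' @param simplifyTol contour simplification tolerance (um); defaults to
#'   one pixel.
#' @param which trace type recorded in the result.
#' @return A [BoundaryTrace-class].
#' @examples
#' sc <- generateScene(sceneConfig(nCells = 40, seed = 11))
#' bt <- tracePlacodeBoundary(labelImage(sc), sc@placodeIds, pixelSize = 0.2)
#' bt@circularity
#' @export
tracePlacodeBoundary <- function(labels, placodeIds, pixelSize = 1,
                                 midlineY = NULL, chordInPerimeter = TRUE,
                                 simplifyTol = pixelSize,
                                 which = "placode") {
  mask <- matrix(labels %in% placodeIds, nrow(labels), ncol(labels))
  if (!any(mask)) stop("no pixels carry the requested placode labels")
  comp <- EBImage::bwlabel(EBImage::Image(mask * 1))
  ncomp <- max(comp)
  if (ncomp > 1L) {
    sizes <- tabulate(as.integer(EBImage::imageData(comp)), nbins = ncomp)
    stop(sprintf("placode is not connected: %d components of %s pixels",
                 ncomp, paste(sizes, collapse = ", ")))
  }
  ring <- traceMask(mask, pixelSize, simplifyTol)
  chord <- FALSE
  chordLen <- 0
  if (!is.null(midlineY)) {
    eps <- pixelSize
    if (max(ring[, 2]) > midlineY - eps) {
      clipped <- clipRingBelow(ring, midlineY)
      chord <- TRUE
      onChord <- abs(clipped[, 2] - midlineY) < 1e-9
      i2 <- c(2:nrow(clipped), 1L)
      seg <- sqrt((clipped[i2, 1] - clipped[, 1])^2 +
                  (clipped[i2, 2] - clipped[, 2])^2)
      chordLen <- sum(seg[onChord & onChord[i2]])
      ring <- clipped
    }
  }
  per <- polygonPerimeter(ring)
  if (chord && !chordInPerimeter) per <- per - chordLen
  ar <- polygonArea(ring)
  new("BoundaryTrace", contour = ring, perimeter = per, area = ar,
      circularity = 4 * pi * ar / per^2, which = which,
      midlineChord = chord)
}

#' Boundary shifted one cell layer out or in
#'
#' Builds the boundary one cell layer outside or inside the placode, using
#' edge adjacency on the label graph (corner contact does not count): the
#' outer region adds every non-placode cell sharing an edge with the
#' placode, the inner region removes the placode's boundary cells (cells
#' touching a non-placode label or the background). The resulting region is
#' traced like the placode boundary.
#'
#' @inheritParams tracePlacodeBoundary
#' @param direction \code{"outer"} or \code{"inner"}.
#' @return A [BoundaryTrace-class] with \code{which} set to the direction.
#' @examples
#' lab <- matrix(0L, 12, 12)
#' for (i in 0:4) for (j in 0:4) lab[2 + i * 2 + 0:1, 2 + j * 2 + 0:1] <-
#'   1L + i + 5L * j
#' inner <- shiftBoundary(lab, 1:25, direction = "inner")
#' @export
shiftBoundary <- function(labels, placodeIds, direction = c("outer", "inner"),
                          pixelSize = 1, midlineY = NULL,
                          chordInPerimeter = TRUE, simplifyTol = pixelSize) {
  direction <- match.arg(direction)
  adj <- labelAdjacency(labels)
  inP <- function(l) l %in% placodeIds
  bndCells <- unique(c(
    adj[inP(adj[, 2]) & !inP(adj[, 1]), 2],
    adj[inP(adj[, 1]) & !inP(adj[, 2]) & adj[, 1] > 0, 1]))
  if (direction == "outer") {
    nb <- unique(c(
      adj[inP(adj[, 1]) & !inP(adj[, 2]) & adj[, 2] > 0, 2],
      adj[inP(adj[, 2]) & !inP(adj[, 1]) & adj[, 1] > 0, 1]))
    ids <- union(placodeIds, nb)
  } else {
    ids <- setdiff(placodeIds, bndCells)
    if (!length(ids))
      stop("inner boundary undefined: the placode is one cell layer thick")
  }
  tracePlacodeBoundary(labels, ids, pixelSize = pixelSize,
                       midlineY = midlineY,
                       chordInPerimeter = chordInPerimeter,
                       simplifyTol = simplifyTol, which = direction)
}

#' Isoperimetric circularity
#'
#' \code{C = 4 * pi * area / perimeter^2}: 1 for a perfect circle and less
#' for any other closed shape, used as a proxy for boundary smoothness and
#' tissue-boundary tension.
#'
#' @param x a closed polygon (two-column matrix) or a
#'   [BoundaryTrace-class].
#' @return The circularity value.
#' @examples
#' circularity(regularPolygon(1000))          # ~1
#' circularity(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))  # pi/4
#' @export
setGeneric("circularity", function(x) standardGeneric("circularity"))

#' @rdname circularity
#' @export
setMethod("circularity", "matrix", function(x) {
  p <- polygonPerimeter(x)
  if (p <= 0) stop("degenerate contour")
  4 * pi * polygonArea(x) / p^2
})

#' @rdname circularity
#' @export
setMethod("circularity", "BoundaryTrace", function(x) x@circularity)

#' Compare circularity across boundary types
#'
#' Group means with standard errors and unpaired two-tailed t-tests of
#' placode versus outer and placode versus inner boundary circularities
#' across placodes. Either shifted group may be absent (as when
#' neighbouring epithelia are out of the focal plane and only placode and
#' inner boundaries are measurable).
#'
#' @param placode numeric circularities of the placode boundaries.
#' @param outer,inner circularities of the shifted boundaries, or
#'   \code{NULL}.
#' @return A list with a \code{summary} data.frame (group, n, mean, sem)
#'   and t-test results \code{placodeVsOuter}, \code{placodeVsInner}
#'   (each \code{NULL} when the group is absent, otherwise a list with
#'   \code{t}, \code{df}, \code{p}).
#' @examples
#' circularityComparison(c(.9, .92), outer = c(.8, .82), inner = c(.78, .8))
#' @export
circularityComparison <- function(placode, outer = NULL, inner = NULL) {
  if (length(placode) < 2L) stop("need at least 2 placodes")
  groups <- list(placode = placode, outer = outer, inner = inner)
  groups <- groups[!vapply(groups, is.null, TRUE)]
  summ <- do.call(rbind, lapply(names(groups), function(g) {
    v <- groups[[g]]
    data.frame(group = g, n = length(v), mean = mean(v),
               sem = stats::sd(v) / sqrt(length(v)))
  }))
  tt <- function(v) {
    if (is.null(v)) return(NULL)
    if (length(v) < 2L) stop("need at least 2 placodes per group")
    if (stats::sd(c(placode, v)) == 0)
      return(list(t = 0, df = length(placode) + length(v) - 2, p = 1))
    ht <- stats::t.test(placode, v, var.equal = FALSE)
    list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
  }
  list(summary = summ, placodeVsOuter = tt(outer), placodeVsInner = tt(inner))
}
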