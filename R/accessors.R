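#' Accessors for synthetic scenes and traces
#'
#' Accessor generics for the central classes: \code{cellTable()} assembles
#' the per-cell ground-truth table of a scene, \code{labelImage()},
#' \code{junctionImage()} and \code{myosinImage()} return the raster layers,
#' \code{pitCenter()} the pit position, \code{cellAreas()} and
#' \code{cellPolygons()} the per-cell geometry, \code{peakIndices()} and
#' \code{peakIntervals()} the detection results of a trace.
#'
#' @param x a [PlacodeScene-class] or [PulseTrace-class] object.
#' @return \code{cellTable()} returns a data.frame with one row per cell
#'   and columns \code{cell_id}, \code{area} (um^2), \code{centroid_x},
#'   \code{centroid_y} (um), \code{dist_pit} (um), \code{depth} (um),
#'   \code{boundary_cell}, \code{placode} (logical) and, after rendering,
#'   \code{true_junctional}, \code{true_medial}, \code{true_ratio}. The
#'   raster accessors return matrices; the others numeric vectors.
#' @examples
#' sc <- generateScene(sceneConfig(nCells = 20, fieldMode = "uniform",
#'                                 noiseModel = "none", seed = 2))
#' head(cellTable(sc))
#' @name scene-accessors
NULL

#' @rdname scene-accessors
#' @export
setGeneric("cellTable", function(x) standardGeneric("cellTable"))

#' @rdname scene-accessors
#' @export
setGeneric("labelImage", function(x) standardGeneric("labelImage"))

#' @rdname scene-accessors
#' @export
setGeneric("junctionImage", function(x) standardGeneric("junctionImage"))

#' @rdname scene-accessors
#' @export
setGeneric("myosinImage", function(x) standardGeneric("myosinImage"))

#' @rdname scene-accessors
#' @export
setGeneric("pitCenter", function(x) standardGeneric("pitCenter"))

#' @rdname scene-accessors
#' @export
setGeneric("cellAreas", function(x) standardGeneric("cellAreas"))

#' @rdname scene-accessors
#' @export
setGeneric("cellPolygons", function(x) standardGeneric("cellPolygons"))

#' @rdname scene-accessors
#' @export
setGeneric("peakIndices", function(x) standardGeneric("peakIndices"))

#' @rdname scene-accessors
#' @export
setGeneric("peakIntervals", function(x) standardGeneric("peakIntervals"))

#' @rdname scene-accessors
#' @export
setMethod("cellTable", "PlacodeScene", function(x) {
  n <- length(x@areas)
  df <- data.frame(
    cell_id = seq_len(n),
    area = x@areas,
    centroid_x = x@centroids[, 1],
    centroid_y = x@centroids[, 2],
    dist_pit = sqrt((x@centroids[, 1] - x@pitCenter[1])^2 +
                    (x@centroids[, 2] - x@pitCenter[2])^2),
    depth = 0,
    boundary_cell = x@boundaryCell,
    placode = seq_len(n) %in% x@placodeIds)
  if (length(x@trueJunctional)) {
    df$true_junctional <- x@trueJunctional
    df$true_medial <- x@trueMedial
    df$true_ratio <- x@trueRatio
  }
  df
})

#' @rdname scene-accessors
#' @export
setMethod("labelImage", "PlacodeScene", function(x) x@labelImage)

#' @rdname scene-accessors
#' @export
setMethod("junctionImage", "PlacodeScene", function(x) x@junctionImage)

#' @rdname scene-accessors
#' @export
setMethod("myosinImage", "PlacodeScene", function(x) x@myosinImage)

#' @rdname scene-accessors
#' @export
setMethod("pitCenter", "PlacodeScene", function(x) x@pitCenter)

#' @rdname scene-accessors
#' @export
setMethod("cellAreas", "PlacodeScene", function(x) x@areas)

#' @rdname scene-accessors
#' @export
setMethod("cellPolygons", "PlacodeScene", function(x) x@polygons)

#' @rdname scene-accessors
#' @export
setMethod("peakIndices", "PulseTrace", function(x) x@peaks)

#' @rdname scene-accessors
#' @export
setMethod("peakIntervals", "PulseTrace", function(x) x@intervals)
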