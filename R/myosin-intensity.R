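#' Junctional and apicomedial masks of one cell
#'
#' Splits a cell of a label image into its junctional band - pixels within
#' \code{bandWidth / 2} of the nearest cell-cell or cell-background
#' interface, so bands shared with neighbours are divided at the contour
#' midline - and the apicomedial interior, the remaining cell pixels. This
#' automates the manual inner/outer tracing of junctional-marker outlines
#' with a reproducible, configurable band width.
#'
#' @param labels integer label matrix.
#' @param cellId label of the cell to partition.
#' @param bandWidth full junctional band width (um); default 0.5 um.
#' @param pixelSize micrometres per pixel.
#' @param interfaceDist optional precomputed interface-distance matrix (in
#'   pixels) to reuse across cells.
#' @return A list with logical matrices \code{junctional} and
#'   \code{apicomedial} and the flag \code{emptyMedial}, set when the band
#'   consumes the whole cell.
#' @examples
#' lab <- matrix(0L, 20, 20); lab[6:15, 6:15] <- 1L
#' pc <- partitionCell(lab, 1L, bandWidth = 2, pixelSize = 1)
#' sum(pc$apicomedial)
#' @export
partitionCell <- function(labels, cellId, bandWidth = 0.5, pixelSize = 1,
                          interfaceDist = NULL) {
  if (bandWidth <= 0) stop("bandWidth must be > 0")
  if (is.null(interfaceDist)) interfaceDist <- interfaceDistance(labels)
  # interface pixel centres sit half a pixel inside the traced contour, so
  # a pixel's distance to the contour is its interface distance plus 0.5 px
  half <- max(bandWidth / (2 * pixelSize) - 0.5, 0)
  cell <- labels == cellId
  if (!any(cell)) stop("no pixels with label ", cellId)
  junct <- cell & interfaceDist <= half
  medial <- cell & !junct
  list(junctional = junct, apicomedial = medial,
       emptyMedial = !any(medial))
}

#' Junctional band width matched to a rendered scene
#'
#' The measurement band that captures essentially all of a synthetic
#' scene's junctional ridge after PSF blurring: the rendered ridge width
#' plus four PSF sigmas (two on each side). Using a narrower band lets
#' blurred junctional signal spill into the apicomedial mask and biases
#' the junctional:apicomedial ratio downwards.
#'
#' @param config a [SceneConfig-class].
#' @return Band width in micrometres.
#' @examples
#' matchedBandWidth(sceneConfig())  # 0.4 + 4 * 0.15 = 1
#' @export
matchedBandWidth <- function(config) {
  config@junctionWidth + 4 * config@psfSigma
}

#' Background-corrected integrated density
#'
#' Sum of background-subtracted pixel intensities over a mask, with
#' negative post-subtraction pixels clipped to zero (integrated density is
#' a nonnegative quantity).
#'
#' @param image numeric intensity matrix (a.u.).
#' @param mask logical matrix of the measurement region.
#' @param backgroundLevel background per pixel (a.u.).
#' @return The integrated density (a.u.).
#' @examples
#' integratedDensity(matrix(5, 3, 3), matrix(TRUE, 3, 3), 2)  # 27
#' @export
integratedDensity <- function(image, mask, backgroundLevel = 0) {
  if (!any(mask)) stop("empty measurement mask")
  sum(pmax(image[mask] - backgroundLevel, 0))
}

#' Per-cell junctional/apicomedial intensity partition
#'
#' Measures, for every cell of a label image, the background-corrected
#' integrated myosin density in the junctional band and in the apicomedial
#' interior. The background defaults to the mean intensity outside the
#' labelled tissue.
#'
#' @param image myosin-channel matrix (a.u.).
#' @param labels integer label matrix.
#' @param bandWidth junctional band width (um).
#' @param pixelSize micrometres per pixel.
#' @param backgroundLevel background per pixel (a.u.); \code{NULL} for the
#'   mean over unlabelled pixels.
#' @param cellIds cells to measure; defaults to all labels.
#' @return A data.frame (one row per cell) with \code{cell_id},
#'   \code{junctional}, \code{apicomedial} integrated densities (a.u.),
#'   \code{empty_medial} flag and the \code{background} level used.
#' @examples
#' sc <- renderChannels(generateScene(sceneConfig(nCells = 20, seed = 10)))
#' ip <- measureIntensityPartition(myosinImage(sc), labelImage(sc))
#' head(ip)
#' @export
measureIntensityPartition <- function(image, labels, bandWidth = 0.5,
                                      pixelSize = 1, backgroundLevel = NULL,
                                      cellIds = NULL) {
  if (!all(dim(image) == dim(labels))) stop("image and labels differ in shape")
  if (is.null(backgroundLevel)) {
    out <- labels == 0L
    backgroundLevel <- if (any(out)) mean(image[out]) else 0
  }
  if (is.null(cellIds)) {
    cellIds <- sort(unique(as.integer(labels)))
    cellIds <- cellIds[cellIds > 0L]
  }
  idist <- interfaceDistance(labels)
  res <- lapply(cellIds, function(id) {
    pc <- partitionCell(labels, id, bandWidth, pixelSize, idist)
    data.frame(
      cell_id = id,
      junctional = integratedDensity(image, pc$junctional, backgroundLevel),
      apicomedial = if (pc$emptyMedial) 0 else
        integratedDensity(image, pc$apicomedial, backgroundLevel),
      empty_medial = pc$emptyMedial,
      background = backgroundLevel)
  })
  do.call(rbind, res)
}

#' Junctional:apicomedial density ratio
#'
#' Ratio of junctional to apicomedial integrated density per cell. Cells
#' with zero apicomedial density get an \code{NA} ratio and an
#' \code{undefined_ratio} flag rather than an infinity.
#'
#' @param partition data.frame from [measureIntensityPartition()] (columns
#'   \code{junctional}, \code{apicomedial}).
#' @return The input with \code{ratio} and \code{undefined_ratio} columns
#'   added.
#' @examples
#' junctionalApicomedialRatio(data.frame(junctional = 2, apicomedial = 2))$ratio
#' @export
junctionalApicomedialRatio <- function(partition) {
  und <- partition$apicomedial <= 0
  partition$ratio <- ifelse(und, NA_real_,
                            partition$junctional / partition$apicomedial)
  partition$undefined_ratio <- und
  partition
}

#' Rescale per-cell mean intensities to 0-100
#'
#' Affine rescaling of per-cell mean intensities within one placode so the
#' minimum maps to 0 and the maximum to 100 a.u., the normalization used
#' before pooling placodes in area-intensity scatter plots.
#'
#' @param values numeric per-cell intensities with at least two distinct
#'   values.
#' @return The rescaled values.
#' @examples
#' rescaleIntensity0100(c(2, 4, 6))  # 0 50 100
#' @export
rescaleIntensity0100 <- function(values) {
  r <- range(values)
  if (diff(r) == 0) stop("constant intensities: the 0-100 scale is undefined")
  (values - r[1]) / diff(r) * 100
}

#' Correlation between apical area and myosin intensity
#'
#' Pearson correlation (with two-sided p-value) between per-cell apical
#' area and rescaled mean myosin intensity, plus the least-squares
#' trendline, used to show the negative area-intensity relation during
#' deep invagination.
#'
#' @param areas apical areas (um^2), length >= 3.
#' @param intensities per-cell intensities (a.u.), same length.
#' @return A list with \code{R}, \code{p}, \code{slope}, \code{intercept}
#'   and \code{n}.
#' @examples
#' areaIntensityCorrelation(1:10, 100 - (1:10) * 3)$R  # -1
#' @export
areaIntensityCorrelation <- function(areas, intensities) {
  if (length(areas) != length(intensities)) stop("length mismatch")
  if (length(areas) < 3L) stop("need at least 3 cells")
  if (stats::sd(areas) == 0 || stats::sd(intensities) == 0)
    stop("zero variance: correlation undefined")
  ct <- stats::cor.test(areas, intensities, method = "pearson")
  fit <- stats::lm(intensities ~ areas)
  list(R = unname(ct$estimate), p = ct$p.value,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       n = length(areas))
}
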