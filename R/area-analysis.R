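#' Binned apical-area frequency distribution
#'
#' Histogram of apical areas in uniform half-open bins \code{[k*w,
#' (k+1)*w)} anchored at 0 um^2, expressed as percentages of all cells,
#' with the cumulative percentage curve. The default bin width of 4 um^2 is
#' the convention used for salivary-gland apical-area distributions.
#'
#' @param areas positive apical areas (um^2).
#' @param binWidth bin width (um^2).
#' @param group optional group label carried into the result.
#' @return An [AreaDistribution-class].
#' @examples
#' ad <- areaDistribution(c(1, 3, 5, 9))
#' ad@percentage   # 50, 25, 25
#' @export
areaDistribution <- function(areas, binWidth = 4, group = "") {
  if (!length(areas)) stop("no areas supplied")
  if (any(areas <= 0)) stop("areas must be > 0")
  edges <- seq(0, binWidth * ceiling(max(areas) / binWidth + 1e-12), binWidth)
  if (length(edges) < 2L) edges <- c(0, binWidth)
  cnt <- tabulate(pmin(floor(areas / binWidth) + 1L, length(edges) - 1L),
                  nbins = length(edges) - 1L)
  pct <- 100 * cnt / length(areas)
  new("AreaDistribution", binEdges = edges, percentage = pct,
      cumulative = cumsum(pct), nCells = length(areas), group = group)
}

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' Maximum absolute gap between the two empirical CDFs, evaluated over the
#' pooled sample points.
#'
#' @param a,b numeric samples.
#' @return The KS statistic D in [0, 1].
#' @examples
#' ksStatistic(c(1, 2, 3), c(2, 3, 4))  # 1/3
#' @export
ksStatistic <- function(a, b) {
  v <- sort(unique(c(a, b)))
  Fa <- vapply(v, function(t) mean(a <= t), 0)
  Fb <- vapply(v, function(t) mean(b <= t), 0)
  max(abs(Fa - Fb))
}

#' Compare two apical-area distributions
#'
#' Two-sample comparison as used for apical-area distributions across
#' genotypes and stages: the Mann-Whitney U test on the raw areas and the
#' two-sample Kolmogorov-Smirnov test on their empirical CDFs. The KS
#' statistic is computed in-package ([ksStatistic()]); p-values come from
#' [stats::wilcox.test()] and [stats::ks.test()].
#'
#' @param a,b numeric samples of apical areas (each of size >= 2).
#' @return A list with \code{U}, \code{pU}, \code{D}, \code{pKS} and the
#'   sample sizes \code{nA}, \code{nB}.
#' @examples
#' compareDistributions(rlnorm(50, 3), rlnorm(50, 3.2))$D
#' @export
compareDistributions <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("need at least 2 observations per sample")
  wt <- suppressWarnings(stats::wilcox.test(a, b))
  kt <- suppressWarnings(stats::ks.test(a, b))
  list(U = unname(wt$statistic), pU = wt$p.value,
       D = ksStatistic(a, b), pKS = kt$p.value,
       nA = length(a), nB = length(b))
}

#' Median-scaling normalization of apical areas
#'
#' Multiplies every target-sample area by the single factor
#' \code{median(reference) / median(target)} so that the scaled target
#' median equals the reference median, the normalization used to compare
#' mutant area distributions against wild type up to a global size factor.
#'
#' @param target areas to scale (um^2).
#' @param reference areas defining the reference median (um^2).
#' @return A list with \code{scaled} areas and the \code{factor} applied.
#' @examples
#' medianScale(c(10, 20, 30), c(12, 24, 36))$factor  # 1.2
#' @export
medianScale <- function(target, reference) {
  if (!length(target) || !length(reference)) stop("empty input")
  mt <- stats::median(target)
  mr <- stats::median(reference)
  if (mt <= 0 || mr <= 0) stop("medians must be positive")
  f <- mr / mt
  list(scaled = target * f, factor = f)
}

#' Render a per-cell apical-area heat map
#'
#' Fills every cell of a label image with a colour mapped from its apical
#' area on a fixed scale, so panels of different placodes can share one
#' scale.
#'
#' @param labels integer label matrix (0 = background).
#' @param areas per-cell areas (um^2), one per label in \code{cellIds}.
#' @param cellIds labels corresponding to \code{areas}.
#' @param colorScale numeric length-2 range pinned to the colour-map ends;
#'   \code{NULL} uses the range of \code{areas}. Values outside are
#'   clamped.
#' @param palette vector of colours from low to high.
#' @param file optional PNG path to write.
#' @return Invisibly, a list with \code{values} (per-pixel area, NA outside
#'   cells), \code{mapped} (per-pixel position on the scale in [0, 1]) and
#'   \code{rgb} (colour matrix).
#' @examples
#' sc <- generateScene(sceneConfig(nCells = 20, seed = 6))
#' hm <- renderAreaHeatmap(labelImage(sc), cellAreas(sc))
#' @export
renderAreaHeatmap <- function(labels, areas, cellIds = seq_along(areas),
                              colorScale = NULL,
                              palette = grDevices::hcl.colors(256, "viridis"),
                              file = NULL) {
  if (is.null(colorScale)) colorScale <- range(areas)
  vals <- matrix(NA_real_, nrow(labels), ncol(labels))
  pos <- labels > 0L
  vals[pos] <- areas[match(labels[pos], cellIds)]
  span <- diff(colorScale)
  mapped <- if (span > 0) pmin(pmax((vals - colorScale[1]) / span, 0), 1)
            else vals * 0 + 0.5
  colIdx <- 1L + round(mapped * (length(palette) - 1L))
  rgbm <- matrix(NA_character_, nrow(labels), ncol(labels))
  rgbm[!is.na(colIdx)] <- palette[colIdx[!is.na(colIdx)]]
  if (!is.null(file)) {
    arr <- grDevices::col2rgb(ifelse(is.na(rgbm), "#000000", rgbm)) / 255
    img <- array(0, dim = c(ncol(labels), nrow(labels), 3))
    for (k in 1:3) img[, , k] <- t(matrix(arr[k, ], nrow(labels)))
    writePNGViaTIFFFallback(img, file)
  }
  invisible(list(values = vals, mapped = mapped, rgb = rgbm))
}

# png::writePNG if available, else a TIFF next to the requested name.
writePNGViaTIFFFallback <- function(img, file) {
  if (requireNamespace("png", quietly = TRUE)) {
    png::writePNG(img, file)
  } else {
    tiff::writeTIFF(img, sub("\\.png$", ".tif", file))
  }
  invisible(file)
}
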