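#' @useDynLib placodeQuant, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

#' Configuration of a synthetic placode scene
#'
#' Describes the geometry, intensity model and noise model of a synthetic
#' two-channel placode image. All lengths are in micrometres, areas in
#' square micrometres, intensities in arbitrary units (a.u.).
#'
#' @slot nCells integer, number of placode cells (>= 3).
#' @slot fieldMode character, spatial apical-area field: \code{"clustered"}
#'   (areas shrink towards the pit), \code{"random"} (the clustered area
#'   multiset spatially permuted), \code{"uniform"} (all areas equal
#'   \code{baseArea}) or \code{"expanded"} (all areas equal
#'   \code{baseArea * (1 + constrictionDepth)}).
#' @slot pitCenter numeric(2), pit position in micrometres; \code{NA} places
#'   the pit halfway between the placode centre and its posterior edge.
#' @slot constrictionDepth fraction in [0, 1): maximal relative area
#'   reduction at the pit.
#' @slot constrictionSigma length scale (micrometres) of the Gaussian
#'   constriction field around the pit.
#' @slot baseArea unconstricted apical area (square micrometres).
#' @slot junctionWidth width of the rendered junctional intensity ridge
#'   (micrometres).
#' @slot psfSigma Gaussian PSF sigma (micrometres); 0 disables blurring.
#' @slot noiseModel \code{"none"} or \code{"poisson"} (shot noise on
#'   expected counts).
#' @slot pixelSize micrometres per pixel.
#' @slot seed integer RNG seed; identical seed and configuration give a
#'   bit-identical scene.
#' @slot surroundCells integer, number of extra cells tessellating an
#'   annulus around the placode (0 = placode only). With surrounding cells
#'   the placode boundary is the smooth circle of the placode disk, as when
#'   a supracellular actomyosin cable rounds up the tissue outline.
#' @slot junctionAmp ridge amplitude of the junctional-marker channel (a.u.).
#' @slot myosinJunctionAmp ridge amplitude of the junctional myosin pool in
#'   the myosin channel (a.u.).
#' @slot background additive background level in both channels (a.u.).
#' @slot medialRatio configured junctional:apicomedial integrated-density
#'   ratio, scalar or one value per cell.
#' @slot medialDensity optional per-cell apicomedial integrated density
#'   override (a.u.); when non-empty it takes precedence over
#'   \code{medialRatio}.
#' @slot canvasSize optional square canvas side (micrometres); \code{NA}
#'   sizes the canvas to fit the tessellated tissue plus a margin.
#' @slot margin canvas margin around the tissue (micrometres).
#'
#' @seealso [sceneConfig()], [generateScene()]
#' @export
setClass("SceneConfig", representation(
  nCells = "integer", fieldMode = "character", pitCenter = "numeric",
  constrictionDepth = "numeric", constrictionSigma = "numeric",
  baseArea = "numeric", junctionWidth = "numeric", psfSigma = "numeric",
  noiseModel = "character", pixelSize = "numeric", seed = "integer",
  surroundCells = "integer", junctionAmp = "numeric",
  myosinJunctionAmp = "numeric", background = "numeric",
  medialRatio = "numeric", medialDensity = "numeric",
  canvasSize = "numeric", margin = "numeric"))

setValidity("SceneConfig", function(object) {
  msg <- character()
  if (object@nCells < 3L) msg <- c(msg, "nCells must be >= 3")
  if (!object@fieldMode %in% c("clustered", "random", "uniform", "expanded"))
    msg <- c(msg, "fieldMode must be clustered/random/uniform/expanded")
  if (object@constrictionDepth < 0 || object@constrictionDepth >= 1)
    msg <- c(msg, "constrictionDepth must be in [0, 1)")
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be > 0")
  if (!object@noiseModel %in% c("none", "poisson"))
    msg <- c(msg, "noiseModel must be 'none' or 'poisson'")
  if (object@baseArea <= 0) msg <- c(msg, "baseArea must be > 0")
  if (object@junctionWidth <= 0) msg <- c(msg, "junctionWidth must be > 0")
  if (length(msg)) msg else TRUE
})

#' Configuration of pulsatile apicomedial-myosin traces
#'
#' Parameters of the pulse-train model: per cell, pulse event times are laid
#' down with inter-event gaps drawn from a normal distribution truncated to
#' exceed the pulse width (so consecutive pulses never fully overlap), and
#' the intensity trace is a baseline plus a Gaussian-in-time bump of the
#' given amplitude at each event, sampled on a uniform frame grid. Defaults
#' follow the reported salivary-gland statistics: 131.7 s mean and 42.8 s SD
#' between pulses, imaged every 5 s.
#'
#' @slot meanInterval mean inter-pulse interval (s), > 0.
#' @slot sdInterval SD of inter-pulse intervals (s), >= 0.
#' @slot pulseWidth characteristic pulse duration (s); the Gaussian bump has
#'   sigma = pulseWidth / 4 and gaps are truncated to be > pulseWidth.
#' @slot frameInterval acquisition interval (s), > 0.
#' @slot nFrames number of frames per trace.
#' @slot baseline baseline intensity (a.u.).
#' @slot amplitude pulse amplitude above baseline (a.u.).
#' @slot noiseSd SD of additive Gaussian measurement noise (a.u.).
#'
#' @seealso [pulsationConfig()], [generatePulseTraces()]
#' @export
setClass("PulsationConfig", representation(
  meanInterval = "numeric", sdInterval = "numeric", pulseWidth = "numeric",
  frameInterval = "numeric", nFrames = "integer", baseline = "numeric",
  amplitude = "numeric", noiseSd = "numeric"))

setValidity("PulsationConfig", function(object) {
  msg <- character()
  if (object@meanInterval <= 0) msg <- c(msg, "meanInterval must be > 0")
  if (object@sdInterval < 0) msg <- c(msg, "sdInterval must be >= 0")
  if (object@frameInterval <= 0) msg <- c(msg, "frameInterval must be > 0")
  if (object@pulseWidth <= 0) msg <- c(msg, "pulseWidth must be > 0")
  if (object@nFrames < 1L) msg <- c(msg, "nFrames must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Synthetic placode scene with ground truth
#'
#' A generated placode: per-cell polygons and areas, the label image, the
#' rendered junctional-marker and myosin channels, and the true per-cell
#' intensity pools. Images are numeric matrices indexed \code{[x, y]} with
#' pixel \code{(i, j)} centred at \code{((i - 0.5), (j - 0.5)) * pixelSize}
#' micrometres; x runs anterior to posterior (A/P), y dorsal to ventral
#' (D/V). Label 0 is background; labels \code{1..nCells} are placode cells
#' and higher labels the surrounding epithelium, if generated.
#'
#' @slot labelImage integer matrix of cell labels.
#' @slot polygons list of closed cell outlines (two-column matrices, um).
#' @slot areas realised per-cell apical areas (um^2).
#' @slot targetAreas target areas the tessellation was asked to realise.
#' @slot centroids two-column matrix of cell centroids (um).
#' @slot pitCenter pit position (um).
#' @slot placodeIds labels belonging to the placode.
#' @slot boundaryCell logical, cell touches the placode edge.
#' @slot junctionImage,myosinImage rendered channels (a.u.); empty until
#'   [renderChannels()] is called.
#' @slot trueJunctional,trueMedial,trueRatio per-cell ground-truth myosin
#'   integrated densities and their junctional:apicomedial ratio.
#' @slot config the [SceneConfig-class] that produced the scene.
#'
#' @seealso [generateScene()], [renderChannels()], [cellTable()]
#' @export
setClass("PlacodeScene", representation(
  labelImage = "matrix", polygons = "list", areas = "numeric",
  targetAreas = "numeric", centroids = "matrix", pitCenter = "numeric",
  placodeIds = "integer", boundaryCell = "logical",
  junctionImage = "matrix", myosinImage = "matrix",
  trueJunctional = "numeric", trueMedial = "numeric", trueRatio = "numeric",
  config = "SceneConfig"))

setValidity("PlacodeScene", function(object) {
  msg <- character()
  n <- length(object@areas)
  if (any(object@areas <= 0)) msg <- c(msg, "all ground-truth areas must be > 0")
  if (length(object@polygons) != n) msg <- c(msg, "one polygon per cell required")
  labs <- sort(unique(as.integer(object@labelImage)))
  labs <- labs[labs > 0L]
  if (!identical(labs, seq_len(n))) msg <- c(msg, "label image inconsistent with cells")
  if (length(msg)) msg else TRUE
})

#' Apicomedial intensity time series
#'
#' One cell's apicomedial-myosin intensity trace with, once peaks have been
#' detected, the detected peak indices and the inter-peak intervals.
#'
#' @slot times frame times (s), uniformly spaced, strictly increasing.
#' @slot intensities intensity per frame (a.u.).
#' @slot peaks integer indices of detected peaks (1-based), possibly empty.
#' @slot intervals successive peak-time differences (s).
#' @slot eventTimes ground-truth pulse event times (s) when the trace was
#'   simulated; empty for measured traces.
#'
#' @seealso [generatePulseTraces()], [detectPeaks()], [intervalStatistics()]
#' @export
setClass("PulseTrace", representation(
  times = "numeric", intensities = "numeric", peaks = "integer",
  intervals = "numeric", eventTimes = "numeric"))

setValidity("PulseTrace", function(object) {
  msg <- character()
  if (length(object@times) != length(object@intensities))
    msg <- c(msg, "times and intensities must have equal length")
  if (length(object@times) > 1 && any(diff(object@times) <= 0))
    msg <- c(msg, "times must be strictly increasing")
  if (any(object@intervals <= 0)) msg <- c(msg, "intervals must be positive")
  if (length(msg)) msg else TRUE
})

#' Traced tissue boundary with circularity
#'
#' A closed placode (or shifted) boundary contour with its perimeter, area
#' and isoperimetric circularity C = 4*pi*area / perimeter^2 (1 for a
#' perfect circle, < 1 otherwise).
#'
#' @slot contour closed polygon, two-column matrix (um); the last vertex is
#'   implicitly joined to the first.
#' @slot perimeter contour length (um).
#' @slot area enclosed area (um^2).
#' @slot circularity 4*pi*area / perimeter^2.
#' @slot which \code{"placode"}, \code{"outer"} or \code{"inner"}.
#' @slot midlineChord TRUE when the contour was closed by the straight
#'   ventral-midline chord.
#'
#' @seealso [tracePlacodeBoundary()], [shiftBoundary()], [circularity()]
#' @export
setClass("BoundaryTrace", representation(
  contour = "matrix", perimeter = "numeric", area = "numeric",
  circularity = "numeric", which = "character", midlineChord = "logical"))

setValidity("BoundaryTrace", function(object) {
  msg <- character()
  if (object@perimeter <= 0) msg <- c(msg, "perimeter must be > 0")
  if (object@area <= 0) msg <- c(msg, "area must be > 0")
  # isoperimetric inequality with a rasterisation allowance; when the
  # midline chord is excluded from the perimeter the bound need not hold
  if (!object@midlineChord && object@circularity > 1 + 0.02)
    msg <- c(msg, "circularity exceeds the isoperimetric bound")
  if (!object@which %in% c("placode", "outer", "inner"))
    msg <- c(msg, "which must be placode/outer/inner")
  if (length(msg)) msg else TRUE
})

#' Invagination stage call
#'
#' Stage of salivary-gland invagination inferred from apical-surface
#' internalization depths and, at the surface stage, from spatial clustering
#' of the most constricted cells: samples with cells internalized more than
#' 2 um are at deep invagination, internalized cells at 2 um or less mark
#' the beginning of invagination, and flat placodes are split into
#' before-invagination versus clustered-apical-constriction by a
#' permutation test on the positions of the smallest-area cells.
#'
#' @slot stage one of \code{"before_invagination"},
#'   \code{"clustered_constriction"}, \code{"beginning_invagination"},
#'   \code{"deep_invagination"}.
#' @slot maxDepth maximal internalization depth (um).
#' @slot clusteringP permutation p-value of spatial clustering of the most
#'   constricted cells (NA when depth decides the stage).
#'
#' @seealso [classifyStage()]
#' @export
setClass("StageCall", representation(
  stage = "character", maxDepth = "numeric", clusteringP = "numeric"))

setValidity("StageCall", function(object) {
  ok <- object@stage %in% c("before_invagination", "clustered_constriction",
                            "beginning_invagination", "deep_invagination")
  if (ok) TRUE else "unknown stage"
})

#' Binned apical-area frequency distribution
#'
#' Percentages of cells per uniform apical-area bin, with the cumulative
#' percentage curve, as used to compare area distributions across genotypes
#' and stages.
#'
#' @slot binEdges bin edges (um^2), uniform width, starting at 0; bins are
#'   half-open \code{[k*w, (k+1)*w)}.
#' @slot percentage percentage of cells per bin (sums to 100).
#' @slot cumulative cumulative percentage per bin (ends at 100).
#' @slot nCells number of cells.
#' @slot group free-text group label.
#'
#' @seealso [areaDistribution()]
#' @export
setClass("AreaDistribution", representation(
  binEdges = "numeric", percentage = "numeric", cumulative = "numeric",
  nCells = "integer", group = "character"))

setValidity("AreaDistribution", function(object) {
  msg <- character()
  if (length(object@binEdges) != length(object@percentage) + 1L)
    msg <- c(msg, "need one more edge than bins")
  if (abs(sum(object@percentage) - 100) > 1e-9)
    msg <- c(msg, "percentages must sum to 100")
  if (any(diff(object@cumulative) < -1e-12))
    msg <- c(msg, "cumulative percentages must be nondecreasing")
  if (length(msg)) msg else TRUE
})
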