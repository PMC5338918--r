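#' Create a synthetic-scene configuration
#'
#' Constructor for [SceneConfig-class] with defaults emulating a mid-stage
#' salivary-gland placode: 150 cells of ~20 um^2 apical area on 0.2 um
#' pixels, a constriction field halving apical area at the pit over an 8 um
#' length scale, a 0.4 um junctional ridge, mild PSF blur and Poisson shot
#' noise.
#'
#' @param nCells number of placode cells.
#' @param fieldMode \code{"clustered"}, \code{"random"}, \code{"uniform"} or
#'   \code{"expanded"}; see [SceneConfig-class].
#' @param pitCenter pit position (um) or NA for the default posterior pit.
#' @param constrictionDepth,constrictionSigma constriction field parameters.
#' @param baseArea unconstricted apical area (um^2).
#' @param junctionWidth,psfSigma,noiseModel,pixelSize rendering parameters.
#' @param seed integer RNG seed.
#' @param surroundCells number of cells tessellating an annulus around the
#'   placode (0 for placode only).
#' @param junctionAmp,myosinJunctionAmp,background channel amplitudes (a.u.).
#' @param medialRatio configured junctional:apicomedial density ratio
#'   (scalar or per cell).
#' @param medialDensity optional per-cell apicomedial density override.
#' @param canvasSize optional square canvas side (um); NA auto-sizes.
#' @param margin canvas margin (um).
#' @return A validated [SceneConfig-class] object.
#' @examples
#' cfg <- sceneConfig(nCells = 30, fieldMode = "uniform", seed = 1)
#' @export
sceneConfig <- function(nCells = 150L, fieldMode = "clustered",
                        pitCenter = NA_real_, constrictionDepth = 0.5,
                        constrictionSigma = 8, baseArea = 20,
                        junctionWidth = 0.4, psfSigma = 0.15,
                        noiseModel = "poisson", pixelSize = 0.2,
                        seed = 1L, surroundCells = 0L,
                        junctionAmp = 200, myosinJunctionAmp = 150,
                        background = 5, medialRatio = 2,
                        medialDensity = numeric(0),
                        canvasSize = NA_real_, margin = 3) {
  new("SceneConfig", nCells = as.integer(nCells), fieldMode = fieldMode,
      pitCenter = as.numeric(pitCenter), constrictionDepth = constrictionDepth,
      constrictionSigma = constrictionSigma, baseArea = baseArea,
      junctionWidth = junctionWidth, psfSigma = psfSigma,
      noiseModel = noiseModel, pixelSize = pixelSize, seed = as.integer(seed),
      surroundCells = as.integer(surroundCells), junctionAmp = junctionAmp,
      myosinJunctionAmp = myosinJunctionAmp, background = background,
      medialRatio = medialRatio, medialDensity = medialDensity,
      canvasSize = as.numeric(canvasSize), margin = margin)
}

#' Create a pulsation configuration
#'
#' Constructor for [PulsationConfig-class]. The defaults are the reported
#' salivary-gland pulse statistics (mean 131.7 s, SD 42.8 s between pulses)
#' sampled at the 5 s live-imaging frame interval.
#'
#' @param meanInterval,sdInterval inter-pulse interval mean and SD (s).
#' @param pulseWidth characteristic pulse duration (s).
#' @param frameInterval acquisition interval (s).
#' @param nFrames frames per trace.
#' @param baseline,amplitude,noiseSd intensity model (a.u.).
#' @return A validated [PulsationConfig-class] object.
#' @examples
#' pcfg <- pulsationConfig(nFrames = 120)
#' @export
pulsationConfig <- function(meanInterval = 131.7, sdInterval = 42.8,
                            pulseWidth = 30, frameInterval = 5,
                            nFrames = 360L, baseline = 10, amplitude = 50,
                            noiseSd = 2) {
  new("PulsationConfig", meanInterval = meanInterval, sdInterval = sdInterval,
      pulseWidth = pulseWidth, frameInterval = frameInterval,
      nFrames = as.integer(nFrames), baseline = baseline,
      amplitude = amplitude, noiseSd = noiseSd)
}

#' @describeIn sceneConfig Compact display of a scene configuration.
#' @param object a \code{SceneConfig}.
#' @export
setMethod("show", "SceneConfig", function(object) {
  cat(sprintf("SceneConfig: %d cells (+%d surround), %s field\n",
              object@nCells, object@surroundCells, object@fieldMode))
  cat(sprintf("  baseArea %.3g um^2, depth %.2f, sigma %.3g um\n",
              object@baseArea, object@constrictionDepth,
              object@constrictionSigma))
  cat(sprintf("  pixel %.3g um, junction %.3g um, psf %.3g um, noise %s, seed %d\n",
              object@pixelSize, object@junctionWidth, object@psfSigma,
              object@noiseModel, object@seed))
  invisible(NULL)
})

#' @export
setMethod("show", "PulsationConfig", function(object) {
  cat(sprintf(
    "PulsationConfig: intervals N(%.4g, %.4g^2) s truncated > %.3g s\n",
    object@meanInterval, object@sdInterval, object@pulseWidth))
  cat(sprintf("  %d frames every %.3g s; baseline %.3g + amplitude %.3g a.u.\n",
              object@nFrames, object@frameInterval, object@baseline,
              object@amplitude))
  invisible(NULL)
})

#' @export
setMethod("show", "PlacodeScene", function(object) {
  d <- dim(object@labelImage)
  cat(sprintf("PlacodeScene: %d cells (%d placode) on a %dx%d px canvas\n",
              length(object@areas), length(object@placodeIds), d[1], d[2]))
  cat(sprintf("  areas %.3g-%.3g um^2 (median %.3g); pit at (%.3g, %.3g) um\n",
              min(object@areas), max(object@areas),
              stats::median(object@areas),
              object@pitCenter[1], object@pitCenter[2]))
  cat(sprintf("  channels %s\n",
              if (length(object@junctionImage)) "rendered" else "not rendered"))
  invisible(NULL)
})

#' @export
setMethod("show", "PulseTrace", function(object) {
  cat(sprintf("PulseTrace: %d frames over %.4g s, %d detected peaks\n",
              length(object@times), diff(range(object@times)),
              length(object@peaks)))
  invisible(NULL)
})

#' @export
setMethod("show", "BoundaryTrace", function(object) {
  cat(sprintf(
    "BoundaryTrace (%s): %d vertices, perimeter %.4g um, area %.4g um^2, C = %.4f%s\n",
    object@which, nrow(object@contour), object@perimeter, object@area,
    object@circularity, if (object@midlineChord) " [midline chord]" else ""))
  invisible(NULL)
})

#' @export
setMethod("show", "StageCall", function(object) {
  cat(sprintf("StageCall: %s (max depth %.3g um%s)\n", object@stage,
              object@maxDepth,
              if (is.na(object@clusteringP)) "" else
                sprintf(", clustering p = %.4g", object@clusteringP)))
  invisible(NULL)
})

#' @export
setMethod("show", "AreaDistribution", function(object) {
  cat(sprintf("AreaDistribution%s: %d cells in %d bins of width %.3g um^2\n",
              if (nzchar(object@group)) paste0(" [", object@group, "]") else "",
              object@nCells, length(object@percentage),
              diff(object@binEdges[1:2])))
  invisible(NULL)
})
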