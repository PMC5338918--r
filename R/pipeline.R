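#' Default pipeline configuration
#'
#' The full set of pipeline defaults as a nested list; user configurations
#' passed to [runPipeline()] are merged over these, and the effective
#' configuration is always echoed into the output directory, so no default
#' is applied silently.
#'
#' @return A nested list of defaults.
#' @export
defaultPipelineConfig <- function() {
  list(
    outDir = "placode-run",
    seed = 1L,
    input = NULL,  # list(junction=, myosin=, mask=, pixelSize=) for real data
    simulate = list(enabled = TRUE, nCells = 150L,
                    modes = c("clustered", "random"),
                    constrictionDepth = 0.5, constrictionSigma = 8,
                    baseArea = 20, noiseModel = "poisson",
                    pixelSize = 0.2, surroundCells = 0L, medialRatio = 2),
    segment = list(enabled = TRUE, smoothSigma = 1, tolerance = 1,
                   minArea = 4),
    areas = list(enabled = TRUE, binWidth = 4),
    dispersion = list(enabled = TRUE, q = 0.3, nPerm = 499L),
    intensity = list(enabled = TRUE, bandWidth = 0.5),
    circularity = list(enabled = FALSE, simplifyTol = NA_real_),
    pulses = list(enabled = TRUE, nCells = 14L, nFrames = 360L,
                  meanInterval = 131.7, sdInterval = 42.8,
                  frameInterval = 5))
}

mergeConfig <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]))
      base[[nm]] <- mergeConfig(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

stageTry <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s': %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the full synthetic or image-based analysis pipeline
#'
#' Orchestrates simulate, segment, areas, dispersion, intensity,
#' circularity and pulses. By default two synthetic scenes are generated
#' (clustered and random constriction fields from the same seed), the
#' clustered scene is re-segmented from its rendered junctional channel,
#' and all downstream statistics are computed and written as CSV/JSON under
#' \code{outDir}. With \code{config$input} set, the junction/myosin TIFFs
#' are read instead of simulated. Every run writes the effective
#' configuration (\code{config_echo.json}) and a provenance record (config
#' MD5 hash, package version, seed); deterministic stages are bit-identical
#' across reruns with the same configuration.
#'
#' @param config nested list merged over [defaultPipelineConfig()], or a
#'   path to a JSON file holding one.
#' @return Invisibly, a list with the in-memory stage \code{results} and
#'   the written \code{paths}.
#' @examples
#' \donttest{
#' res <- runPipeline(list(outDir = tempfile(), seed = 2,
#'                         simulate = list(nCells = 40L),
#'                         pulses = list(nFrames = 120L)))
#' }
#' @export
runPipeline <- function(config = list()) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  cfg <- mergeConfig(defaultPipelineConfig(), config)
  outDir <- cfg$outDir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  echoPath <- file.path(outDir, "config_echo.json")
  jsonlite::write_json(cfg, echoPath, auto_unbox = TRUE, digits = NA,
                       null = "null")
  prov <- list(config_hash = unname(tools::md5sum(echoPath)),
               package = "placodeQuant",
               version = as.character(utils::packageVersion("placodeQuant")),
               seed = cfg$seed)
  jsonlite::write_json(prov, file.path(outDir, "provenance.json"),
                       auto_unbox = TRUE)
  results <- list()
  paths <- list(config = echoPath)

  scenes <- list()
  if (!is.null(cfg$input)) {
    scenes <- NULL
    stageTry("input", {
      for (f in c("junction", "myosin")) {
        p <- cfg$input[[f]]
        if (!is.null(p) && !file.exists(p))
          stop(sprintf("channel file not found: %s", p))
      }
      if (is.null(cfg$input$junction)) stop("input$junction is required")
    })
    junction <- readChannelTIFF(cfg$input$junction)
    myosin <- if (!is.null(cfg$input$myosin)) readChannelTIFF(cfg$input$myosin)
    mask <- if (!is.null(cfg$input$mask)) readLabelTIFF(cfg$input$mask) > 0
    pixelSize <- if (!is.null(cfg$input$pixelSize)) cfg$input$pixelSize else 1
  } else if (isTRUE(cfg$simulate$enabled)) {
    stageTry("simulate", {
      for (mode in cfg$simulate$modes) {
        sc <- generateScene(sceneConfig(
          nCells = cfg$simulate$nCells, fieldMode = mode,
          constrictionDepth = cfg$simulate$constrictionDepth,
          constrictionSigma = cfg$simulate$constrictionSigma,
          baseArea = cfg$simulate$baseArea,
          noiseModel = cfg$simulate$noiseModel,
          pixelSize = cfg$simulate$pixelSize,
          surroundCells = cfg$simulate$surroundCells,
          medialRatio = cfg$simulate$medialRatio,
          seed = cfg$seed))
        sc <- renderChannels(sc)
        scenes[[mode]] <- sc
        paths[[paste0("scene_", mode)]] <-
          exportGroundTruth(sc, file.path(outDir, paste0("scene_", mode)))
      }
    })
    ref <- scenes[[1]]
    junction <- junctionImage(ref)
    myosin <- myosinImage(ref)
    mask <- labelImage(ref) > 0
    pixelSize <- cfg$simulate$pixelSize
  } else stop("stage 'input': neither input files nor simulation configured")
  results$scenes <- scenes

  seg <- NULL
  if (isTRUE(cfg$segment$enabled)) {
    seg <- stageTry("segment", segmentCells(
      junction, mask, pixelSize = pixelSize,
      smoothSigma = cfg$segment$smoothSigma,
      tolerance = cfg$segment$tolerance, minArea = cfg$segment$minArea))
    d <- file.path(outDir, "segment")
    dir.create(d, showWarnings = FALSE)
    writeLabelTIFF(seg$labels, file.path(d, "labels.tif"))
    utils::write.csv(seg$cells, file.path(d, "cells.csv"), row.names = FALSE)
    paths$segment <- d
    results$segment <- seg
  }

  if (isTRUE(cfg$areas$enabled) && !is.null(seg)) {
    results$areas <- stageTry("areas", {
      ad <- areaDistribution(seg$cells$area, binWidth = cfg$areas$binWidth,
                             group = "segmented")
      d <- file.path(outDir, "areas")
      dir.create(d, showWarnings = FALSE)
      utils::write.csv(data.frame(
        bin_lo = ad@binEdges[-length(ad@binEdges)],
        bin_hi = ad@binEdges[-1],
        percentage = ad@percentage, cumulative = ad@cumulative),
        file.path(d, "area_distribution.csv"), row.names = FALSE)
      cmp <- if (length(scenes) >= 2)
        compareDistributions(cellAreas(scenes[[1]]), cellAreas(scenes[[2]]))
      if (!is.null(cmp))
        jsonlite::write_json(cmp, file.path(d, "mode_comparison.json"),
                             auto_unbox = TRUE, digits = NA)
      paths$areas <- d
      list(distribution = ad, comparison = cmp)
    })
  }

  if (isTRUE(cfg$dispersion$enabled) && length(scenes) >= 1) {
    results$dispersion <- stageTry("dispersion", {
      rows <- lapply(names(scenes), function(mode) {
        sc <- scenes[[mode]]
        ct <- cellTable(sc)
        sub <- lowerQuantileCells(ct, cfg$dispersion$q)
        pf <- pitRelativeCoordinates(sub, pitCenter(sc))
        ds <- dispersionStats(pf)
        p <- clusteringPermutationTest(ct, q = cfg$dispersion$q,
                                       nPerm = cfg$dispersion$nPerm,
                                       seed = cfg$seed)
        data.frame(mode = mode, q = cfg$dispersion$q,
                   sd_AP = ds[["sd_AP"]], sd_DV = ds[["sd_DV"]],
                   clustering_p = p)
      })
      rep <- do.call(rbind, rows)
      d <- file.path(outDir, "dispersion")
      dir.create(d, showWarnings = FALSE)
      utils::write.csv(rep, file.path(d, "dispersion.csv"), row.names = FALSE)
      paths$dispersion <- d
      rep
    })
  }

  if (isTRUE(cfg$intensity$enabled) && !is.null(seg) && !is.null(myosin)) {
    results$intensity <- stageTry("intensity", {
      ip <- junctionalApicomedialRatio(measureIntensityPartition(
        myosin, seg$labels, bandWidth = cfg$intensity$bandWidth,
        pixelSize = pixelSize))
      mean_int <- vapply(ip$cell_id, function(id)
        mean(myosin[seg$labels == id]), 0)
      ip$mean_intensity_0_100 <- rescaleIntensity0100(mean_int)
      corr <- areaIntensityCorrelation(seg$cells$area,
                                       ip$mean_intensity_0_100)
      d <- file.path(outDir, "intensity")
      dir.create(d, showWarnings = FALSE)
      utils::write.csv(ip, file.path(d, "intensity_partition.csv"),
                       row.names = FALSE)
      jsonlite::write_json(corr, file.path(d, "area_intensity_correlation.json"),
                           auto_unbox = TRUE, digits = NA)
      paths$intensity <- d
      list(partition = ip, correlation = corr)
    })
  }

  if (isTRUE(cfg$circularity$enabled) && length(scenes) >= 1) {
    results$circularity <- stageTry("circularity", {
      sc <- scenes[[1]]
      tol <- cfg$circularity$simplifyTol
      if (is.na(tol)) tol <- pixelSize
      pl <- tracePlacodeBoundary(labelImage(sc), sc@placodeIds,
                                 pixelSize = pixelSize, simplifyTol = tol)
      out <- tryCatch(shiftBoundary(labelImage(sc), sc@placodeIds, "outer",
                                    pixelSize = pixelSize, simplifyTol = tol),
                      error = function(e) NULL)
      inn <- tryCatch(shiftBoundary(labelImage(sc), sc@placodeIds, "inner",
                                    pixelSize = pixelSize, simplifyTol = tol),
                      error = function(e) NULL)
      slt <- function(x, f) if (is.null(x)) numeric(0) else methods::slot(x, f)
      rep <- data.frame(
        which = c("placode", if (!is.null(out)) "outer",
                  if (!is.null(inn)) "inner"),
        perimeter = c(pl@perimeter, slt(out, "perimeter"), slt(inn, "perimeter")),
        area = c(pl@area, slt(out, "area"), slt(inn, "area")),
        circularity = c(pl@circularity, slt(out, "circularity"),
                        slt(inn, "circularity")))
      d <- file.path(outDir, "circularity")
      dir.create(d, showWarnings = FALSE)
      utils::write.csv(rep, file.path(d, "circularity.csv"), row.names = FALSE)
      paths$circularity <- d
      rep
    })
  }

  if (isTRUE(cfg$pulses$enabled)) {
    results$pulses <- stageTry("pulses", {
      pcfg <- pulsationConfig(meanInterval = cfg$pulses$meanInterval,
                              sdInterval = cfg$pulses$sdInterval,
                              frameInterval = cfg$pulses$frameInterval,
                              nFrames = cfg$pulses$nFrames)
      tr <- lapply(generatePulseTraces(pcfg, cfg$pulses$nCells,
                                       seed = cfg$seed), detectPeaks)
      st <- intervalStatistics(tr)
      d <- file.path(outDir, "pulses")
      dir.create(d, showWarnings = FALSE)
      utils::write.csv(data.frame(
        cell_id = rep(seq_along(tr),
                      vapply(tr, function(x) length(x@intervals), 0L)),
        interval = st$intervals),
        file.path(d, "intervals.csv"), row.names = FALSE)
      utils::write.csv(data.frame(
        cell_id = rep(seq_along(tr),
                      vapply(tr, function(x) length(x@eventTimes), 0L)),
        event_time = unlist(lapply(tr, function(x) x@eventTimes))),
        file.path(d, "event_times.csv"), row.names = FALSE)
      jsonlite::write_json(st[c("mean", "sd", "nCells", "nIntervals")],
                           file.path(d, "interval_stats.json"),
                           auto_unbox = TRUE, digits = NA)
      paths$pulses <- d
      st
    })
  }

  invisible(list(results = results, paths = paths))
}

#' Validate a measurement table against its documented schema
#'
#' Checks the column names and types of an exported CSV (or in-memory
#' data.frame) against the documented table schemas. Missing or wrongly
#' typed columns are violations; unknown extra columns pass with a
#' warning.
#'
#' @param table data.frame or path to a CSV file.
#' @param schema one of \code{"cells"} (per-cell table), \code{"partition"}
#'   (intensity partition), \code{"intervals"} (inter-pulse intervals) or
#'   \code{"traces"} (long-format intensity traces).
#' @return A list with \code{ok}, \code{missing}, \code{badType} and
#'   \code{extra} column names.
#' @examples
#' validateTables(data.frame(cell_id = 1, area = 2, centroid_x = 0,
#'                           centroid_y = 0), "cells")$ok
#' @export
validateTables <- function(table, schema = c("cells", "partition",
                                             "intervals", "traces")) {
  schema <- match.arg(schema)
  if (is.character(table)) table <- utils::read.csv(table)
  req <- switch(schema,
    cells = c(cell_id = "numeric", area = "numeric",
              centroid_x = "numeric", centroid_y = "numeric"),
    partition = c(cell_id = "numeric", junctional = "numeric",
                  apicomedial = "numeric"),
    intervals = c(cell_id = "numeric", interval = "numeric"),
    traces = c(time = "numeric", cell_id = "numeric",
               intensity = "numeric"))
  optional <- switch(schema,
    cells = c("depth", "boundary_cell", "placode", "dist_pit",
              "polygon_area", "true_junctional", "true_medial",
              "true_ratio"),
    partition = c("ratio", "undefined_ratio", "empty_medial", "background",
                  "mean_intensity_0_100"),
    character(0))
  missing <- setdiff(names(req), names(table))
  present <- intersect(names(req), names(table))
  badType <- present[!vapply(table[present], is.numeric, TRUE)]
  extra <- setdiff(names(table), c(names(req), optional))
  if (length(extra))
    warning("extra columns ignored: ", paste(extra, collapse = ", "))
  list(ok = !length(missing) && !length(badType),
       missing = missing, badType = badType, extra = extra)
}
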