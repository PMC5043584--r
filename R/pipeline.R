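# End-to-end workflows: segment -> summarize -> detect -> link -> motion
# analysis, with all intermediates written to disk plus a machine-readable
# provenance record, and deterministic fixture generation for the test
# suites.

.writeJSON <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Run the full speckle quantification pipeline on a movie
#'
#' Segments every frame (count/area morphometry), detects and links
#' particles into trajectories and runs the motion analysis. All
#' intermediates are written under \code{outputDir}: \code{speckles.csv},
#' \code{speckle_summary.json}, \code{tracks.csv}, \code{motion.csv},
#' \code{motion_summary.json} and a provenance record \code{run_info.json}
#' (parameters, seed, package version) sufficient to reproduce the outputs.
#' An empty movie yields empty outputs and a warning, not an error.
#'
#' @param stack an \linkS4class{ImageStack}, or a path to a TIFF stack
#'   (read with the config calibration).
#' @param config run configuration from \code{\link{runConfig}} /
#'   \code{\link{readRunConfig}}; must carry \code{pixel_size} and
#'   \code{frame_interval}.
#' @param outputDir output directory (created if needed); NULL writes
#'   nothing.
#' @param nucleusMask optional binary matrix for area fractions.
#' @return list with \code{speckles} (\linkS4class{SpeckleSet}),
#'   \code{speckleSummary}, \code{tracks}, \code{motion} (data.frame) and
#'   \code{motionSummary}.
#' @export
runSpecklePipeline <- function(stack, config, outputDir = NULL,
                               nucleusMask = NULL) {
  config <- validateRunConfig(config)
  if (is.character(stack)) {
    if (!file.exists(stack)) stop("unreadable input stack: ", stack)
    stack <- readImageStack(stack, config$pixel_size, config$frame_interval)
  }
  stopifnot(is(stack, "ImageStack"))

  segArgs <- config$segmentation
  ss <- do.call(segmentSpeckles,
                c(list(stack = stack, nucleusMask = nucleusMask), segArgs))
  speckleSummary <- summarizeSpeckles(ss)
  if (nrow(speckles(ss)) == 0L)
    warning("no speckles detected in any frame; outputs are empty")

  trkArgs <- config$tracking
  tracks <- do.call(trackSpeckles, c(list(stack = stack), trkArgs))
  motion <- do.call(analyzeMotion, c(list(tracks = tracks), config$motion))
  motionSummary <- summarizeMotion(motion)

  if (!is.null(outputDir)) {
    dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
    write.csv(speckles(ss), file.path(outputDir, "speckles.csv"),
              row.names = FALSE)
    .writeJSON(speckleSummary, file.path(outputDir, "speckle_summary.json"))
    writeTracks(tracks, file.path(outputDir, "tracks.csv"))
    write.csv(motion, file.path(outputDir, "motion.csv"), row.names = FALSE)
    ms <- motionSummary
    ms$classFractions <- as.list(ms$classFractions)
    .writeJSON(ms, file.path(outputDir, "motion_summary.json"))
    .writeJSON(list(package = "speckleQuant",
                    version = as.character(packageVersion("speckleQuant")),
                    config = config,
                    seed = config$seed,
                    n_frames = nFrames(stack)),
               file.path(outputDir, "run_info.json"))
  }
  list(speckles = ss, speckleSummary = speckleSummary, tracks = tracks,
       motion = motion, motionSummary = motionSummary)
}

.fixtureSuites <- c("smss-anchors", "frap-grid", "coloc-pairs",
                    "segmentation")

#' Generate canonical ground-truth fixture suites
#'
#' Writes deterministic synthetic fixtures (movies as multi-page TIFF,
#' traces and ground truth as CSV) plus a YAML metadata sidecar echoing all
#' generation parameters. Calling twice with the same suite and seed gives
#' byte-identical directories.
#'
#' Suites: \code{"smss-anchors"} — three short movies (static / brownian /
#' ballistic) with true trajectories; \code{"frap-grid"} — 12 FRAP traces
#' over mobile fraction {0.5, 0.8, 0.95, 1} x half-time {5, 34, 60} s;
#' \code{"coloc-pairs"} — channel pairs at planted overlap {0, 0.5, 1};
#' \code{"segmentation"} — one movie of well-separated static speckles.
#'
#' @param suite suite name.
#' @param dir output directory (created).
#' @param seed integer seed.
#' @return \code{dir}, invisibly.
#' @export
makeFixtures <- function(suite, dir, seed = 1L) {
  if (!suite %in% .fixtureSuites)
    stop("unknown suite '", suite, "'; available: ",
         paste(.fixtureSuites, collapse = ", "))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(suite = suite, seed = seed)
  if (suite == "smss-anchors") {
    models <- list(static = motionModel("static", locNoise = 0.01),
                   brownian = motionModel("brownian", D = 0.1),
                   ballistic = motionModel("ballistic", v = 0.5))
    sc <- sceneSpec(nSpeckles = 5L, imageSize = c(64L, 64L), nFrames = 50L,
                    minSeparation = 16, noise = "gaussian", noiseSd = 0.02)
    for (nm in names(models)) {
      mv <- renderSpeckleMovie(sc, models[[nm]], seed = seed)
      writeImageStack(mv$stack, file.path(dir, paste0(nm, ".tif")))
      writeTracks(mv$truth, file.path(dir, paste0(nm, "_truth.csv")))
    }
    meta$scene <- list(nSpeckles = 5, imageSize = c(64, 64), nFrames = 50,
                       pixelSize = sc@pixelSize,
                       frameInterval = sc@frameInterval)
  } else if (suite == "frap-grid") {
    grid <- expand.grid(mf = c(0.5, 0.8, 0.95, 1.0), th = c(5, 34, 60))
    for (i in seq_len(nrow(grid))) {
      p <- frapSimParams(mobileFraction = grid$mf[i], tHalf = grid$th[i])
      tr <- simulateFrapTrace(p, seed = seed + i)
      writeRoiTrace(tr, file.path(dir, sprintf("frap_mf%03d_th%02d.csv",
                                               round(100 * grid$mf[i]),
                                               grid$th[i])))
    }
    meta$grid <- list(mobileFraction = c(0.5, 0.8, 0.95, 1.0),
                      tHalf = c(5, 34, 60), noiseSd = 0.02,
                      nPrebleach = 10, nPostbleach = 290,
                      frameInterval = 0.3)
  } else if (suite == "coloc-pairs") {
    sc <- sceneSpec(imageSize = c(128L, 128L), minSeparation = 6)
    for (f in c(0, 0.5, 1)) {
      pr <- simulateColocPair(60L, f, sc, seed = seed + round(100 * f))
      writeImageStack(pr$ch1,
                      file.path(dir, sprintf("pair_f%03d_ch1.tif",
                                             round(100 * f))))
      writeImageStack(pr$ch2,
                      file.path(dir, sprintf("pair_f%03d_ch2.tif",
                                             round(100 * f))))
    }
    meta$overlapFractions <- c(0, 0.5, 1)
  } else if (suite == "segmentation") {
    sc <- sceneSpec(nSpeckles = 20L, imageSize = c(256L, 256L),
                    nFrames = 5L, minSeparation = 20, noiseSd = 0.02)
    mv <- renderSpeckleMovie(sc, motionModel("static"), seed = seed)
    writeImageStack(mv$stack, file.path(dir, "speckles.tif"))
    writeTracks(mv$truth, file.path(dir, "speckles_truth.csv"))
    meta$scene <- list(nSpeckles = 20, imageSize = c(256, 256), nFrames = 5)
  }
  yaml::write_yaml(meta, file.path(dir, "metadata.yaml"))
  invisible(dir)
}
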