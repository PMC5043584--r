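# Calibrated file I/O: multi-page TIFF stacks, track / ROI-trace / speckle
# CSVs and YAML run configuration. Intensities are stored in 16-bit TIFF
# range: values are divided by 65535 on write and restored on read.

.TIFF_SCALE <- 65535

#' Read a single-channel multi-page TIFF as an ImageStack
#'
#' @param path TIFF file.
#' @param pixelSize um/px (mandatory: TIFF carries no reliable physical
#'   calibration here).
#' @param frameInterval s.
#' @return An \linkS4class{ImageStack} with intensities on the 0..65535
#'   scale.
#' @export
readImageStack <- function(path, pixelSize, frameInterval) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1L]  # drop extra channels
    p * .TIFF_SCALE
  })
  ImageStack(pages, pixelSize, frameInterval)
}

#' Write an ImageStack as a multi-page 16-bit TIFF
#'
#' Intensities are clipped to [0, 65535] and scaled to the unit range.
#'
#' @param stack an \linkS4class{ImageStack} (or matrix).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeImageStack <- function(stack, path) {
  frames <- if (is(stack, "ImageStack"))
    lapply(seq_len(nFrames(stack)), function(i) getFrame(stack, i))
  else list(as.matrix(stack))
  frames <- lapply(frames, function(f)
    pmin(pmax(f / .TIFF_SCALE, 0), 1))
  tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read/write trajectory CSVs
#'
#' Track CSVs have columns \code{track_id, frame, x_px, y_px}.
#'
#' @param tracks list of \linkS4class{Trajectory}.
#' @param path CSV file.
#' @param pixelSize,frameInterval calibration applied on read.
#' @return \code{writeTracks}: \code{path} invisibly; \code{readTracks}: a
#'   list of \linkS4class{Trajectory}.
#' @export
writeTracks <- function(tracks, path) {
  df <- do.call(rbind, lapply(tracks, as.data.frame))
  if (is.null(df))
    df <- data.frame(track_id = integer(0), frame = integer(0),
                     x_px = numeric(0), y_px = numeric(0))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTracks
#' @export
readTracks <- function(path, pixelSize, frameInterval) {
  df <- read.csv(path)
  need <- c("track_id", "frame", "x_px", "y_px")
  if (!all(need %in% names(df)))
    stop("track CSV must have columns: ", paste(need, collapse = ", "))
  lapply(split(df, df$track_id), function(d) {
    d <- d[order(d$frame), ]
    Trajectory(d$frame, d$x_px, d$y_px, pixelSize, frameInterval,
               trackId = d$track_id[1L])
  })
}

#' Read/write photobleaching ROI trace CSVs
#'
#' Columns \code{time_s, roi1, roi2, roi3} with a header row; time is 0 at
#' the first post-bleach frame. On read, the number of pre-bleach frames is
#' taken from \code{nPrebleach}, or counted from negative times when NULL.
#'
#' @param trace a \linkS4class{RoiTrace}.
#' @param path CSV file.
#' @param nPrebleach optional pre-bleach frame count override.
#' @return \code{writeRoiTrace}: \code{path} invisibly;
#'   \code{readRoiTrace}: a \linkS4class{RoiTrace}.
#' @export
writeRoiTrace <- function(trace, path) {
  write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeRoiTrace
#' @export
readRoiTrace <- function(path, nPrebleach = NULL) {
  df <- read.csv(path)
  need <- c("time_s", "roi1", "roi2", "roi3")
  if (!all(need %in% names(df)))
    stop("ROI trace CSV must have columns: ", paste(need, collapse = ", "))
  if (is.null(nPrebleach)) {
    nPrebleach <- sum(df$time_s < 0)
    if (nPrebleach < 1L)
      stop("cannot infer pre-bleach frames (no negative times); ",
           "pass 'nPrebleach'")
  }
  roiTrace(df$time_s, df$roi1, df$roi2, df$roi3, nPrebleach)
}

#' Run configuration
#'
#' A run configuration is a named list with mandatory calibration fields
#' \code{pixel_size} (um/px) and \code{frame_interval} (s), an optional
#' \code{seed}, and optional per-module parameter blocks
#' (\code{segmentation}, \code{tracking}, \code{motion}, \code{frap},
#' \code{coloc}). It round-trips losslessly through YAML.
#'
#' @param pixel_size um/px.
#' @param frame_interval s.
#' @param seed optional integer.
#' @param segmentation,tracking,motion,frap,coloc optional named lists of
#'   module parameters (passed to the corresponding functions).
#' @return a validated run-config list.
#' @examples
#' cfg <- runConfig(pixel_size = 0.1, frame_interval = 0.05, seed = 1)
#' @export
runConfig <- function(pixel_size, frame_interval, seed = NULL,
                      segmentation = list(), tracking = list(),
                      motion = list(), frap = list(), coloc = list()) {
  cfg <- list(pixel_size = pixel_size, frame_interval = frame_interval,
              seed = seed, segmentation = segmentation, tracking = tracking,
              motion = motion, frap = frap, coloc = coloc)
  validateRunConfig(cfg)
}

#' @rdname runConfig
#' @param cfg a run-config list.
#' @export
validateRunConfig <- function(cfg) {
  for (field in c("pixel_size", "frame_interval")) {
    v <- cfg[[field]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1L || !is.finite(v) ||
        v <= 0)
      stop("run config is missing a valid '", field, "' (positive number)")
  }
  cfg
}

#' @rdname runConfig
#' @param path YAML file.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  validateRunConfig(yaml::read_yaml(path))
}

#' @rdname runConfig
#' @export
writeRunConfig <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}
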