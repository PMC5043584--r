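#' @import methods
#' @importFrom stats coef cor cov lm mad median nlminb quantile rnorm rpois
#'   runif sd setNames var
#' @importFrom utils head read.csv tail write.csv packageVersion
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

# ---------------------------------------------------------------------------
# ImageStack
# ---------------------------------------------------------------------------

#' Calibrated time-lapse image stack
#'
#' A single-channel T-frame image stack with physical calibration. Frames are
#' stored as a numeric array of dimension \code{c(ny, nx, nframes)} (rows are
#' the y axis, columns the x axis, matching what \code{tiff::readTIFF}
#' returns). Continuous pixel coordinates are 0-based: the centre of the
#' top-left pixel is (x, y) = (0, 0), with x running along columns.
#'
#' @slot frames numeric array \code{c(ny, nx, nframes)}, intensities in
#'   arbitrary units.
#' @slot pixelSize pixel size in micrometres per pixel.
#' @slot frameInterval frame interval in seconds.
#' @export
setClass("ImageStack",
  representation(frames = "array", pixelSize = "numeric",
                 frameInterval = "numeric"),
  validity = function(object) {
    if (length(dim(object@frames)) != 3L)
      return("'frames' must be a 3-D array (ny, nx, nframes)")
    if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
        object@pixelSize <= 0)
      return("'pixelSize' must be a single positive number (um/px)")
    if (length(object@frameInterval) != 1L ||
        !is.finite(object@frameInterval) || object@frameInterval <= 0)
      return("'frameInterval' must be a single positive number (s)")
    TRUE
  })

#' Construct an ImageStack
#'
#' @param frames 3-D numeric array \code{c(ny, nx, nframes)}, or a list of
#'   equally sized matrices, or a single matrix (one frame).
#' @param pixelSize micrometres per pixel.
#' @param frameInterval seconds between frames.
#' @return An \linkS4class{ImageStack}.
#' @examples
#' st <- ImageStack(array(0, c(16, 16, 3)), pixelSize = 0.1,
#'                  frameInterval = 0.05)
#' nFrames(st)
#' @export
ImageStack <- function(frames, pixelSize, frameInterval) {
  if (is.list(frames))
    frames <- array(unlist(frames),
                    c(nrow(frames[[1L]]), ncol(frames[[1L]]), length(frames)))
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1L))
  new("ImageStack", frames = frames, pixelSize = as.numeric(pixelSize),
      frameInterval = as.numeric(frameInterval))
}

#' @describeIn ImageStack number of frames
#' @param x,object an \code{ImageStack}
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @export
setMethod("nFrames", "ImageStack", function(x) dim(x@frames)[3L])

#' Physical calibration accessors
#'
#' @param x an object carrying calibration (\linkS4class{ImageStack} or
#'   \linkS4class{Trajectory}).
#' @return A single numeric: micrometres per pixel (\code{pixelSize}) or
#'   seconds per frame (\code{frameInterval}).
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname pixelSize
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))

#' @rdname pixelSize
#' @export
setMethod("pixelSize", "ImageStack", function(x) x@pixelSize)

#' @rdname pixelSize
#' @export
setMethod("frameInterval", "ImageStack", function(x) x@frameInterval)

#' Extract one frame of an ImageStack as a matrix
#' @param x an \linkS4class{ImageStack}
#' @param i frame index (1-based)
#' @return numeric matrix \code{c(ny, nx)}
#' @export
getFrame <- function(x, i) {
  stopifnot(is(x, "ImageStack"), i >= 1L, i <= nFrames(x))
  x@frames[, , i]
}

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@frames)
  cat(sprintf("ImageStack: %d x %d px, %d frame(s)\n", d[2L], d[1L], d[3L]))
  cat(sprintf("  pixelSize: %g um/px, frameInterval: %g s\n",
              object@pixelSize, object@frameInterval))
})

# ---------------------------------------------------------------------------
# MotionModel
# ---------------------------------------------------------------------------

.motionKinds <- c("static", "brownian", "confined", "directed", "ballistic")

#' Parametric motion model for a diffusing speckle
#'
#' Describes the true motion of a simulated particle: static, free Brownian,
#' confined (restricted) Brownian within a reflecting circular corral,
#' directed Brownian (diffusion plus constant drift along a random direction)
#' or ballistic (pure drift). Localization noise is added independently per
#' frame on top of the true positions.
#'
#' @slot kind one of \code{"static"}, \code{"brownian"}, \code{"confined"},
#'   \code{"directed"}, \code{"ballistic"}.
#' @slot D diffusion coefficient, um^2/s (>= 0).
#' @slot v drift speed, um/s (>= 0).
#' @slot corralRadius corral radius in um (confined motion only).
#' @slot locNoise localization noise s.d. per axis, um (>= 0).
#' @export
setClass("MotionModel",
  representation(kind = "character", D = "numeric", v = "numeric",
                 corralRadius = "numeric", locNoise = "numeric"),
  validity = function(object) {
    k <- object@kind
    if (length(k) != 1L || !k %in% .motionKinds)
      return(sprintf("'kind' must be one of: %s",
                     paste(.motionKinds, collapse = ", ")))
    if (object@D < 0 || object@v < 0 || object@locNoise < 0)
      return("'D', 'v' and 'locNoise' must be >= 0")
    if (k == "static" && (object@D != 0 || object@v != 0))
      return("static motion requires D = 0 and v = 0")
    if (k == "brownian" && object@v != 0)
      return("brownian motion requires v = 0")
    if (k == "ballistic" && (object@D != 0 || object@v <= 0))
      return("ballistic motion requires D = 0 and v > 0")
    if (k == "confined" &&
        (object@D <= 0 || !is.finite(object@corralRadius) ||
         object@corralRadius <= 0))
      return("confined motion requires D > 0 and corralRadius > 0")
    if (k == "directed" && object@v <= 0)
      return("directed motion requires v > 0")
    TRUE
  })

#' @rdname MotionModel-class
#' @param kind motion class (see slots).
#' @param D diffusion coefficient (um^2/s).
#' @param v drift speed (um/s).
#' @param corralRadius corral radius (um), confined motion only.
#' @param locNoise localization noise s.d. (um).
#' @return A \linkS4class{MotionModel}.
#' @examples
#' motionModel("brownian", D = 0.1)
#' motionModel("confined", D = 0.1, corralRadius = 0.2)
#' @export
motionModel <- function(kind = c("static", "brownian", "confined", "directed",
                                 "ballistic"),
                        D = 0, v = 0, corralRadius = NA_real_, locNoise = 0) {
  kind <- match.arg(kind)
  new("MotionModel", kind = kind, D = as.numeric(D), v = as.numeric(v),
      corralRadius = as.numeric(corralRadius), locNoise = as.numeric(locNoise))
}

setMethod("show", "MotionModel", function(object) {
  cat(sprintf("MotionModel '%s': D = %g um^2/s, v = %g um/s", object@kind,
              object@D, object@v))
  if (object@kind == "confined")
    cat(sprintf(", corral = %g um", object@corralRadius))
  cat(sprintf(", locNoise = %g um\n", object@locNoise))
})

# ---------------------------------------------------------------------------
# Trajectory
# ---------------------------------------------------------------------------

#' A single linked speckle trajectory
#'
#' Ordered (frame, x, y) positions of one particle in 0-based pixel
#' coordinates, with physical calibration. Frames are strictly increasing;
#' gaps are allowed (tracks linked with gap closing).
#'
#' @slot trackId identifier.
#' @slot frames integer frame indices (strictly increasing, 1-based).
#' @slot x,y positions in pixels (0-based continuous coordinates).
#' @slot pixelSize um/px.
#' @slot frameInterval s.
#' @export
setClass("Trajectory",
  representation(trackId = "integer", frames = "integer", x = "numeric",
                 y = "numeric", pixelSize = "numeric",
                 frameInterval = "numeric"),
  validity = function(object) {
    n <- length(object@frames)
    if (length(object@x) != n || length(object@y) != n)
      return("'frames', 'x' and 'y' must have equal length")
    if (n >= 2L && any(diff(object@frames) <= 0L))
      return("'frames' must be strictly increasing")
    if (object@pixelSize <= 0 || object@frameInterval <= 0)
      return("calibration must be positive")
    TRUE
  })

#' @rdname Trajectory-class
#' @param frames integer frame indices.
#' @param x,y pixel coordinates.
#' @param pixelSize um/px.
#' @param frameInterval s.
#' @param trackId integer id.
#' @return A \linkS4class{Trajectory}.
#' @export
Trajectory <- function(frames, x, y, pixelSize, frameInterval, trackId = 1L) {
  new("Trajectory", trackId = as.integer(trackId),
      frames = as.integer(frames), x = as.numeric(x), y = as.numeric(y),
      pixelSize = as.numeric(pixelSize),
      frameInterval = as.numeric(frameInterval))
}

#' @rdname pixelSize
#' @export
setMethod("pixelSize", "Trajectory", function(x) x@pixelSize)

#' @rdname pixelSize
#' @export
setMethod("frameInterval", "Trajectory", function(x) x@frameInterval)

#' Number of points in a trajectory
#' @param x a \linkS4class{Trajectory}
#' @export
setMethod("length", "Trajectory", function(x) length(x@frames))

#' Positions of a trajectory as a matrix
#' @param traj a \linkS4class{Trajectory}
#' @param units \code{"px"} or \code{"um"}
#' @return two-column matrix (x, y)
#' @export
positions <- function(traj, units = c("px", "um")) {
  units <- match.arg(units)
  m <- cbind(x = traj@x, y = traj@y)
  if (units == "um") m <- m * traj@pixelSize
  m
}

#' @export
#' @describeIn Trajectory-class coerce to data.frame with columns
#'   \code{track_id, frame, x_px, y_px}
#' @param x a \code{Trajectory}
#' @param ... unused
setMethod("as.data.frame", "Trajectory", function(x, ...) {
  data.frame(track_id = x@trackId, frame = x@frames, x_px = x@x, y_px = x@y)
})

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory #%d: %d points, frames %d..%d (%g um/px, %g s)\n",
              object@trackId, length(object@frames),
              if (length(object@frames)) min(object@frames) else NA_integer_,
              if (length(object@frames)) max(object@frames) else NA_integer_,
              object@pixelSize, object@frameInterval))
})

# ---------------------------------------------------------------------------
# SceneSpec
# ---------------------------------------------------------------------------

#' Synthetic scene description for rendering speckle movies
#'
#' Defines the imaging geometry used by \code{\link{renderSpeckleMovie}} and
#' \code{\link{simulateColocPair}}: diffraction-limited speckles rendered as
#' 2-D Gaussian spots inside an elliptical nuclear mask, on a constant
#' background, with optional photon noise applied last.
#'
#' @slot nSpeckles number of speckles.
#' @slot speckleSigma Gaussian spot s.d. in um.
#' @slot nucleusCentre (x, y) centre of the nucleus ellipse, px.
#' @slot nucleusAxes (a, b) ellipse semi-axes, px.
#' @slot backgroundLevel constant background intensity (a.u.).
#' @slot amplitude peak spot amplitude above background (a.u.).
#' @slot noise one of \code{"none"}, \code{"gaussian"}, \code{"poisson"}.
#'   Gaussian noise has s.d. proportional to the local intensity
#'   (\code{noiseSd} is the relative s.d.); Poisson treats intensities as
#'   photon counts.
#' @slot noiseSd relative s.d. for Gaussian noise.
#' @slot pixelSize um/px.
#' @slot frameInterval s.
#' @slot nFrames frames to render.
#' @slot imageSize (nx, ny) image size in px.
#' @slot minSeparation minimum distance between planted spot centres, px
#'   (0 = unconstrained).
#' @export
setClass("SceneSpec",
  representation(nSpeckles = "integer", speckleSigma = "numeric",
                 nucleusCentre = "numeric", nucleusAxes = "numeric",
                 backgroundLevel = "numeric", amplitude = "numeric",
                 noise = "character", noiseSd = "numeric",
                 pixelSize = "numeric", frameInterval = "numeric",
                 nFrames = "integer", imageSize = "integer",
                 minSeparation = "numeric"),
  validity = function(object) {
    if (object@nSpeckles < 0L) return("'nSpeckles' must be >= 0")
    if (object@speckleSigma <= 0) return("'speckleSigma' must be > 0")
    if (!object@noise %in% c("none", "gaussian", "poisson"))
      return("'noise' must be 'none', 'gaussian' or 'poisson'")
    if (length(object@nucleusCentre) != 2L || length(object@nucleusAxes) != 2L)
      return("'nucleusCentre' and 'nucleusAxes' must have length 2")
    if (any(object@nucleusAxes <= 0)) return("'nucleusAxes' must be > 0")
    if (object@pixelSize <= 0 || object@frameInterval <= 0)
      return("calibration must be positive")
    if (object@nFrames < 1L) return("'nFrames' must be >= 1")
    if (length(object@imageSize) != 2L || any(object@imageSize < 8L))
      return("'imageSize' must be two integers >= 8")
    TRUE
  })

#' @rdname SceneSpec-class
#' @param nSpeckles,speckleSigma,nucleusCentre,nucleusAxes see slots.
#' @param backgroundLevel,amplitude,noise,noiseSd see slots.
#' @param pixelSize,frameInterval,nFrames,imageSize,minSeparation see slots.
#' @return A \linkS4class{SceneSpec}.
#' @examples
#' sceneSpec(nSpeckles = 20)
#' @export
sceneSpec <- function(nSpeckles = 64L, speckleSigma = 0.1,
                      imageSize = c(256L, 256L),
                      nucleusCentre = imageSize / 2,
                      nucleusAxes = imageSize * 0.4,
                      backgroundLevel = 10, amplitude = 200,
                      noise = c("gaussian", "none", "poisson"),
                      noiseSd = 0.05, pixelSize = 0.1, frameInterval = 0.05,
                      nFrames = 1L, minSeparation = 0) {
  noise <- match.arg(noise)
  new("SceneSpec", nSpeckles = as.integer(nSpeckles),
      speckleSigma = as.numeric(speckleSigma),
      nucleusCentre = as.numeric(nucleusCentre),
      nucleusAxes = as.numeric(nucleusAxes),
      backgroundLevel = as.numeric(backgroundLevel),
      amplitude = as.numeric(amplitude), noise = noise,
      noiseSd = as.numeric(noiseSd), pixelSize = as.numeric(pixelSize),
      frameInterval = as.numeric(frameInterval), nFrames = as.integer(nFrames),
      imageSize = as.integer(imageSize),
      minSeparation = as.numeric(minSeparation))
}

setMethod("show", "SceneSpec", function(object) {
  cat(sprintf(paste0("SceneSpec: %d speckle(s), sigma %g um, %dx%d px, ",
                     "%d frame(s), noise '%s'\n"),
              object@nSpeckles, object@speckleSigma, object@imageSize[1L],
              object@imageSize[2L], object@nFrames, object@noise))
})

# ---------------------------------------------------------------------------
# FrapSimParams
# ---------------------------------------------------------------------------

#' Ground-truth parameters for a simulated FRAP experiment
#'
#' The bleached-region signal recovers as a single exponential toward a
#' plateau set by the mobile fraction: after full-scale normalization the
#' noiseless recovery is \code{F(t) = Mf * (1 - exp(-c t))} with
#' \code{c = log(2) / tHalf}. Both the bleached and the control region are
#' additionally attenuated by a per-frame multiplicative acquisition-bleach
#' factor, and a constant background offset is added to every ROI.
#'
#' @slot mobileFraction fraction of molecules free to exchange, in [0, 1].
#' @slot tHalf recovery half-time, s (> 0).
#' @slot bleachDepth fraction of signal removed by the bleach pulse, (0, 1].
#' @slot acqBleachRate per-frame multiplicative acquisition-bleach decay
#'   (signal is multiplied by \code{(1 - rate)^frame}).
#' @slot nPrebleach number of pre-bleach frames.
#' @slot frameInterval s.
#' @slot noiseSd relative (multiplicative) intensity noise s.d.
#' @export
setClass("FrapSimParams",
  representation(mobileFraction = "numeric", tHalf = "numeric",
                 bleachDepth = "numeric", acqBleachRate = "numeric",
                 nPrebleach = "integer", frameInterval = "numeric",
                 noiseSd = "numeric"),
  validity = function(object) {
    if (object@mobileFraction < 0 || object@mobileFraction > 1)
      return("'mobileFraction' must be in [0, 1]")
    if (object@tHalf <= 0) return("'tHalf' must be > 0")
    if (object@bleachDepth <= 0 || object@bleachDepth > 1)
      return("'bleachDepth' must be in (0, 1]")
    if (object@acqBleachRate < 0 || object@acqBleachRate >= 1)
      return("'acqBleachRate' must be in [0, 1)")
    if (object@nPrebleach < 1L) return("'nPrebleach' must be >= 1")
    if (object@frameInterval <= 0) return("'frameInterval' must be > 0")
    if (object@noiseSd < 0) return("'noiseSd' must be >= 0")
    TRUE
  })

#' @rdname FrapSimParams-class
#' @param mobileFraction,tHalf,bleachDepth,acqBleachRate see slots.
#' @param nPrebleach,frameInterval,noiseSd see slots.
#' @return A \linkS4class{FrapSimParams}.
#' @examples
#' frapSimParams(mobileFraction = 0.95, tHalf = 34)
#' @export
frapSimParams <- function(mobileFraction = 0.95, tHalf = 34,
                          bleachDepth = 0.8, acqBleachRate = 0.001,
                          nPrebleach = 10L, frameInterval = 0.3,
                          noiseSd = 0.02) {
  new("FrapSimParams", mobileFraction = as.numeric(mobileFraction),
      tHalf = as.numeric(tHalf), bleachDepth = as.numeric(bleachDepth),
      acqBleachRate = as.numeric(acqBleachRate),
      nPrebleach = as.integer(nPrebleach),
      frameInterval = as.numeric(frameInterval), noiseSd = as.numeric(noiseSd))
}

setMethod("show", "FrapSimParams", function(object) {
  cat(sprintf(paste0("FrapSimParams: Mf = %g, tHalf = %g s, bleachDepth = %g,",
                     " acqBleach = %g/frame, %d prebleach @ %g s, noise %g\n"),
              object@mobileFraction, object@tHalf, object@bleachDepth,
              object@acqBleachRate, object@nPrebleach, object@frameInterval,
              object@noiseSd))
})

# ---------------------------------------------------------------------------
# RoiTrace
# ---------------------------------------------------------------------------

#' Photobleaching ROI intensity trace
#'
#' Raw fluorescence intensities over time for the bleached region (ROI1), a
#' non-bleached acquisition-control region (ROI2) and a background region
#' (ROI3). Time is 0 at the first post-bleach frame; pre-bleach frames have
#' negative times.
#'
#' @slot time time in s, uniform grid.
#' @slot roiBleach ROI1 intensities (a.u.).
#' @slot roiControl ROI2 intensities (a.u.).
#' @slot roiBackground ROI3 intensities (a.u.).
#' @slot nPrebleach number of pre-bleach frames.
#' @export
setClass("RoiTrace",
  representation(time = "numeric", roiBleach = "numeric",
                 roiControl = "numeric", roiBackground = "numeric",
                 nPrebleach = "integer"),
  validity = function(object) {
    n <- length(object@time)
    if (length(object@roiBleach) != n || length(object@roiControl) != n ||
        length(object@roiBackground) != n)
      return("all ROI series must have the same length as 'time'")
    if (object@nPrebleach < 1L || object@nPrebleach >= n)
      return("'nPrebleach' must be >= 1 and < series length")
    TRUE
  })

#' @rdname RoiTrace-class
#' @param time,roiBleach,roiControl,roiBackground,nPrebleach see slots.
#' @return A \linkS4class{RoiTrace}.
#' @export
roiTrace <- function(time, roiBleach, roiControl, roiBackground,
                     nPrebleach = 10L) {
  new("RoiTrace", time = as.numeric(time), roiBleach = as.numeric(roiBleach),
      roiControl = as.numeric(roiControl),
      roiBackground = as.numeric(roiBackground),
      nPrebleach = as.integer(nPrebleach))
}

#' @export
#' @describeIn RoiTrace-class coerce to a data.frame with columns
#'   \code{time_s, roi1, roi2, roi3}
#' @param x a \code{RoiTrace}
#' @param ... unused
setMethod("as.data.frame", "RoiTrace", function(x, ...) {
  data.frame(time_s = x@time, roi1 = x@roiBleach, roi2 = x@roiControl,
             roi3 = x@roiBackground)
})

setMethod("show", "RoiTrace", function(object) {
  cat(sprintf("RoiTrace: %d frames (%d pre-bleach), t = %g..%g s\n",
              length(object@time), object@nPrebleach, min(object@time),
              max(object@time)))
})

# ---------------------------------------------------------------------------
# FrapFit
# ---------------------------------------------------------------------------

#' Single-exponential photobleaching fit
#'
#' Result of fitting \code{f(t) = b + (a - b) * exp(-c t)} to a normalized
#' FRAP recovery (or FLIP decay) series. \code{a} is the intercept at t = 0,
#' \code{b} the value at infinity and \code{c} (slot \code{rate}) the rate
#' constant; the half-time is \code{log(2) / c}. For a full-scale normalized
#' FRAP curve the mobile fraction is the fitted plateau \code{b} (raw value
#' preserved; clip for summaries with \code{pmin(pmax(., 0), 1)}).
#'
#' @slot a fitted intercept.
#' @slot b fitted plateau.
#' @slot rate rate constant c (1/s).
#' @slot mobileFraction the raw fitted plateau b (FRAP fits; NA for FLIP).
#' @slot tHalf log(2)/c in s.
#' @slot rss residual sum of squares.
#' @slot converged logical; when FALSE the parameters are NA.
#' @slot nPoints number of fitted points.
#' @slot kind "recovery" (FRAP) or "decay" (FLIP).
#' @export
setClass("FrapFit",
  representation(a = "numeric", b = "numeric", rate = "numeric",
                 mobileFraction = "numeric", tHalf = "numeric",
                 rss = "numeric", converged = "logical", nPoints = "integer",
                 kind = "character"))

#' Mobile fraction and half-time accessors
#' @param x a \linkS4class{FrapFit}
#' @return a single numeric
#' @export
setGeneric("mobileFraction", function(x) standardGeneric("mobileFraction"))

#' @rdname mobileFraction
#' @export
setGeneric("halfTime", function(x) standardGeneric("halfTime"))

#' @rdname mobileFraction
#' @export
setMethod("mobileFraction", "FrapFit", function(x) x@mobileFraction)

#' @rdname mobileFraction
#' @export
setMethod("halfTime", "FrapFit", function(x) x@tHalf)

setMethod("show", "FrapFit", function(object) {
  if (!object@converged) {
    cat(sprintf("FrapFit (%s): NOT converged (%d points)\n", object@kind,
                object@nPoints))
  } else {
    cat(sprintf(paste0("FrapFit (%s): a = %.4g, b = %.4g, c = %.4g 1/s; ",
                       "tHalf = %.4g s"), object@kind, object@a, object@b,
                object@rate, object@tHalf))
    if (object@kind == "recovery")
      cat(sprintf(", mobile fraction = %.4g", object@mobileFraction))
    cat(sprintf(" (rss %.3g, n = %d)\n", object@rss, object@nPoints))
  }
})

# ---------------------------------------------------------------------------
# ColocResult
# ---------------------------------------------------------------------------

#' Costes/Manders co-localization result
#'
#' Automatic Costes thresholds for a two-channel image pair and the
#' thresholded Manders coefficients: \code{tM1} is the fraction of
#' above-threshold channel-1 intensity found where channel 2 is also above
#' threshold, and conversely for \code{tM2}. The single-condition Manders
#' variants \code{M1}/\code{M2} (no threshold on the channel being summed)
#' are retained alongside.
#'
#' @slot pearsonGlobal global Pearson correlation of the two channels.
#' @slot threshold1,threshold2 Costes thresholds.
#' @slot tM1,tM2 thresholded Manders coefficients in [0, 1] (NA when a
#'   channel has no above-threshold signal).
#' @slot M1,M2 single-condition Manders coefficients.
#' @slot slope,intercept orthogonal-regression line ch2 = slope*ch1 +
#'   intercept used for the threshold scan.
#' @slot nPixels number of pixels analysed.
#' @slot warn character flag: "" or a short warning ("anticorrelated",
#'   "no_threshold_found").
#' @export
setClass("ColocResult",
  representation(pearsonGlobal = "numeric", threshold1 = "numeric",
                 threshold2 = "numeric", tM1 = "numeric", tM2 = "numeric",
                 M1 = "numeric", M2 = "numeric", slope = "numeric",
                 intercept = "numeric", nPixels = "integer",
                 warn = "character"))

setMethod("show", "ColocResult", function(object) {
  cat(sprintf("ColocResult: %d pixels, global Pearson r = %.3f\n",
              object@nPixels, object@pearsonGlobal))
  cat(sprintf("  Costes thresholds: T1 = %.4g, T2 = %.4g\n",
              object@threshold1, object@threshold2))
  cat(sprintf("  tM1 = %.3f (%.1f%%), tM2 = %.3f (%.1f%%)\n", object@tM1,
              100 * object@tM1, object@tM2, 100 * object@tM2))
  if (nzchar(object@warn)) cat("  warning:", object@warn, "\n")
})

# ---------------------------------------------------------------------------
# SpeckleSet
# ---------------------------------------------------------------------------

#' Per-frame labelled speckle detections
#'
#' Segmentation result for an image stack: one row per speckle per frame,
#' with 0-based intensity-weighted centroids (computed on the original,
#' unprocessed frame), pixel and physical areas and mean intensity.
#'
#' @slot speckles data.frame with columns \code{frame, label, x_px, y_px,
#'   area_px, area_um2, mean_intensity}.
#' @slot pixelSize um/px.
#' @slot nFrames number of frames segmented (frames with zero speckles
#'   contribute no rows but still count).
#' @slot nucleusMask optional binary matrix marking the nucleus.
#' @export
setClass("SpeckleSet",
  representation(speckles = "data.frame", pixelSize = "numeric",
                 nFrames = "integer", nucleusMask = "matrixOrNULL"),
  validity = function(object) {
    need <- c("frame", "label", "x_px", "y_px", "area_px", "area_um2",
              "mean_intensity")
    if (!all(need %in% names(object@speckles)))
      return(sprintf("'speckles' must have columns: %s",
                     paste(need, collapse = ", ")))
    if (object@pixelSize <= 0) return("'pixelSize' must be > 0")
    if (nrow(object@speckles) &&
        anyDuplicated(object@speckles[c("frame", "label")]))
      return("labels must be unique within a frame")
    TRUE
  })

#' @rdname pixelSize
#' @export
setMethod("pixelSize", "SpeckleSet", function(x) x@pixelSize)

#' Speckle table accessor
#' @param x a \linkS4class{SpeckleSet}
#' @return the per-speckle data.frame
#' @export
speckles <- function(x) {
  stopifnot(is(x, "SpeckleSet"))
  x@speckles
}

setMethod("show", "SpeckleSet", function(object) {
  cat(sprintf("SpeckleSet: %d speckle(s) across %d frame(s) (%g um/px)\n",
              nrow(object@speckles), object@nFrames, object@pixelSize))
  if (!is.null(object@nucleusMask))
    cat(sprintf("  nucleus mask: %d px\n", sum(object@nucleusMask > 0)))
})
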