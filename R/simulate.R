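# Synthetic ground-truth generators: trajectories, speckle movies,
# photobleaching traces and two-channel co-localization pairs. The defaults
# mirror the acquisition conditions of the speckle experiments this package
# quantifies (about one frame per 50 ms, 0.1 um/px, diffraction-limited
# spots ~0.1 um s.d.).

#' Simulate one particle trajectory under a parametric motion model
#'
#' Positions are generated in micrometres and stored as calibrated pixel
#' coordinates. Brownian steps are i.i.d. Gaussian with per-axis variance
#' \code{2 D dt}; confined motion applies a reflecting circular boundary of
#' radius \code{corralRadius} about the start point; directed motion adds
#' \code{v dt} drift along a fixed random direction; ballistic motion is
#' pure drift. Localization noise (i.i.d. Gaussian per frame, per axis) is
#' added after the true path is generated.
#'
#' @param model a \linkS4class{MotionModel}.
#' @param nSteps number of positions (>= 2).
#' @param dt time step in s (> 0).
#' @param seed optional integer seed; identical (model, nSteps, dt, seed)
#'   give bit-identical output.
#' @param pixelSize um/px used to express positions in pixels.
#' @param origin starting position (x, y) in px.
#' @param trackId integer id for the returned trajectory.
#' @return A \linkS4class{Trajectory} of \code{nSteps} positions at frames
#'   \code{1..nSteps}.
#' @examples
#' tr <- simulateTrajectory(motionModel("brownian", D = 0.1), 100, 0.05,
#'                          seed = 1)
#' length(tr)
#' @export
simulateTrajectory <- function(model, nSteps, dt, seed = NULL,
                               pixelSize = 0.1, origin = c(0, 0),
                               trackId = 1L) {
  stopifnot(is(model, "MotionModel"))
  if (!is.finite(dt) || dt <= 0) stop("'dt' must be > 0")
  nSteps <- as.integer(nSteps)
  if (is.na(nSteps) || nSteps < 2L) stop("'nSteps' must be >= 2")
  withSeed(seed, {
    # true path in um, relative to origin
    xy <- matrix(0, nSteps, 2L)
    if (model@kind %in% c("brownian", "confined", "directed")) {
      steps <- matrix(rnorm(2L * (nSteps - 1L), sd = sqrt(2 * model@D * dt)),
                      nSteps - 1L, 2L)
    } else {
      steps <- matrix(0, nSteps - 1L, 2L)
    }
    if (model@kind %in% c("directed", "ballistic")) {
      th <- runif(1, 0, 2 * pi)
      steps <- sweep(steps, 2L, model@v * dt * c(cos(th), sin(th)), "+")
    }
    if (model@kind == "confined") {
      R <- model@corralRadius
      p <- c(0, 0)
      for (i in seq_len(nSteps - 1L)) {
        p <- p + steps[i, ]
        r <- sqrt(sum(p^2))
        if (r > R) p <- p * (2 * R - r) / r  # radial reflection
        xy[i + 1L, ] <- p
      }
    } else if (nSteps > 1L) {
      xy[-1L, ] <- apply(steps, 2L, cumsum)
    }
    if (model@locNoise > 0)
      xy <- xy + matrix(rnorm(2L * nSteps, sd = model@locNoise), nSteps, 2L)
    Trajectory(frames = seq_len(nSteps),
               x = origin[1L] + xy[, 1L] / pixelSize,
               y = origin[2L] + xy[, 2L] / pixelSize,
               pixelSize = pixelSize, frameInterval = dt, trackId = trackId)
  })
}

#' Render a synthetic speckle movie with ground-truth trajectories
#'
#' Each speckle is rendered per frame as a 2-D Gaussian of s.d.
#' \code{speckleSigma} on a constant background; spot centres follow
#' independent trajectories simulated from \code{model} (confined corrals
#' are centred on each speckle's initial position). All planted centres lie
#' inside the nucleus ellipse; photon noise is applied last.
#'
#' @param scene a \linkS4class{SceneSpec}.
#' @param model a \linkS4class{MotionModel} shared by all speckles.
#' @param seed optional integer seed (deterministic output).
#' @return A list with elements \code{stack} (\linkS4class{ImageStack}),
#'   \code{truth} (list of \linkS4class{Trajectory}) and
#'   \code{nucleusMask} (binary matrix).
#' @examples
#' sc <- sceneSpec(nSpeckles = 5L, imageSize = c(64L, 64L), nFrames = 2L)
#' mv <- renderSpeckleMovie(sc, motionModel("static"), seed = 1)
#' nFrames(mv$stack)
#' @export
renderSpeckleMovie <- function(scene, model, seed = NULL) {
  stopifnot(is(scene, "SceneSpec"), is(model, "MotionModel"))
  if (scene@speckleSigma <= 0) stop("'speckleSigma' must be > 0")
  withSeed(seed, {
    nx <- scene@imageSize[1L]; ny <- scene@imageSize[2L]
    sigmaPx <- scene@speckleSigma / scene@pixelSize
    n <- scene@nSpeckles
    trajs <- list()
    if (n > 0L) {
      starts <- samplePointsInEllipse(n, scene@nucleusCentre,
                                      scene@nucleusAxes,
                                      scene@minSeparation)
      trajs <- lapply(seq_len(n), function(i) {
        if (scene@nFrames == 1L)
          Trajectory(1L, starts[i, 1L], starts[i, 2L], scene@pixelSize,
                     scene@frameInterval, trackId = i)
        else
          simulateTrajectory(model, scene@nFrames, scene@frameInterval,
                             seed = NULL, pixelSize = scene@pixelSize,
                             origin = starts[i, ], trackId = i)
      })
    }
    frames <- array(scene@backgroundLevel, c(ny, nx, scene@nFrames))
    for (t in seq_len(scene@nFrames)) {
      img <- frames[, , t]
      for (tr in trajs)
        img <- addGaussianSpot(img, tr@x[t], tr@y[t], scene@amplitude,
                               sigmaPx)
      frames[, , t] <- applySceneNoise(img, scene)
    }
    list(stack = ImageStack(frames, scene@pixelSize, scene@frameInterval),
         truth = trajs,
         nucleusMask = ellipseMask(scene@imageSize, scene@nucleusCentre,
                                   scene@nucleusAxes))
  })
}

#' Simulate a raw FRAP ROI trace
#'
#' Generates the three raw ROI series of a FRAP experiment. ROI1 (bleached
#' region) sits at a constant pre-bleach level, drops by \code{bleachDepth}
#' at the bleach, then recovers as a single exponential with rate
#' \code{c = log(2)/tHalf} toward the plateau set by \code{mobileFraction}.
#' ROI1 and ROI2 share the per-frame multiplicative acquisition-bleach decay
#' and a constant background offset (ROI3). Noise is multiplicative,
#' relative s.d. \code{noiseSd}, applied to all three series.
#'
#' The default protocol is 10 pre-bleach and 290 post-bleach frames at
#' 300 ms.
#'
#' @param params a \linkS4class{FrapSimParams}.
#' @param nPostbleach number of post-bleach frames (>= 10).
#' @param seed optional integer seed.
#' @param signalLevel pre-bleach ROI1 plateau above background (a.u.).
#' @param controlLevel ROI2 level above background (a.u.).
#' @param backgroundLevel ROI3 level (a.u.).
#' @return A \linkS4class{RoiTrace}; time is 0 at the first post-bleach
#'   frame.
#' @examples
#' tr <- simulateFrapTrace(frapSimParams(0.95, 34), seed = 1)
#' tr
#' @export
simulateFrapTrace <- function(params, nPostbleach = 290L, seed = NULL,
                              signalLevel = 100, controlLevel = 80,
                              backgroundLevel = 5) {
  stopifnot(is(params, "FrapSimParams"))
  nPostbleach <- as.integer(nPostbleach)
  if (is.na(nPostbleach) || nPostbleach < 10L)
    stop("'nPostbleach' must be >= 10")
  withSeed(seed, {
    npre <- params@nPrebleach
    ntot <- npre + nPostbleach
    fr <- 0:(ntot - 1L)
    dt <- params@frameInterval
    decay <- (1 - params@acqBleachRate)^fr
    cc <- log(2) / params@tHalf
    tpost <- (0:(nPostbleach - 1L)) * dt
    bd <- params@bleachDepth
    rec <- (1 - bd) + bd * params@mobileFraction * (1 - exp(-cc * tpost))
    sig1 <- c(rep(1, npre), rec) * signalLevel * decay
    sig2 <- rep(controlLevel, ntot) * decay
    noisy <- function(x)
      if (params@noiseSd > 0)
        x * (1 + rnorm(ntot, sd = params@noiseSd)) else x
    roiTrace(time = (fr - npre) * dt,
             roiBleach = noisy(sig1 + backgroundLevel),
             roiControl = noisy(sig2 + backgroundLevel),
             roiBackground = noisy(rep(backgroundLevel, ntot)),
             nPrebleach = npre)
  })
}

#' Simulate a raw FLIP ROI trace
#'
#' In a FLIP experiment one region is bleached repeatedly and the monitored
#' (non-bleached) region, here ROI2, drains as a single exponential toward a
#' floor. ROI1 holds the directly bleached region (fast decay; not used by
#' the FLIP fit) and ROI3 a constant background.
#'
#' @param tHalf half-time of the monitored-region fluorescence loss, s.
#' @param floorLevel fractional fluorescence remaining at infinity, in
#'   [0, 1).
#' @param nPrebleach pre-bleach frames.
#' @param nPostbleach post-bleach frames.
#' @param frameInterval s per frame.
#' @param noiseSd relative multiplicative noise s.d.
#' @param seed optional integer seed.
#' @param signalLevel,backgroundLevel raw intensity scales (a.u.).
#' @return A \linkS4class{RoiTrace}.
#' @examples
#' tr <- simulateFlipTrace(tHalf = 208, seed = 1)  # 3.47 min
#' @export
simulateFlipTrace <- function(tHalf, floorLevel = 0.05, nPrebleach = 10L,
                              nPostbleach = 450L, frameInterval = 2,
                              noiseSd = 0.02, seed = NULL, signalLevel = 100,
                              backgroundLevel = 5) {
  if (!is.finite(tHalf) || tHalf <= 0) stop("'tHalf' must be > 0")
  if (floorLevel < 0 || floorLevel >= 1)
    stop("'floorLevel' must be in [0, 1)")
  withSeed(seed, {
    npre <- as.integer(nPrebleach)
    ntot <- npre + as.integer(nPostbleach)
    fr <- 0:(ntot - 1L)
    cc <- log(2) / tHalf
    tpost <- (0:(nPostbleach - 1L)) * frameInterval
    mon <- c(rep(1, npre), floorLevel + (1 - floorLevel) * exp(-cc * tpost))
    ble <- c(rep(1, npre), exp(-tpost / (2 * frameInterval)))
    noisy <- function(x)
      if (noiseSd > 0) x * (1 + rnorm(ntot, sd = noiseSd)) else x
    roiTrace(time = (fr - npre) * frameInterval,
             roiBleach = noisy(ble * signalLevel + backgroundLevel),
             roiControl = noisy(mon * signalLevel + backgroundLevel),
             roiBackground = noisy(rep(backgroundLevel, ntot)),
             nPrebleach = npre)
  })
}

#' Simulate a two-channel image pair with a planted overlap fraction
#'
#' A fraction \code{overlapFraction} of spot centres is shared between the
#' two channels; the remaining centres are placed independently inside the
#' nucleus ellipse. Both channels are rendered with the scene's spot model
#' and noise, so the true co-localized fraction of spot signal is known.
#'
#' @param nSpots spots per channel.
#' @param overlapFraction fraction in [0, 1] of shared spot centres.
#' @param scene a \linkS4class{SceneSpec} (its \code{nSpeckles} and
#'   \code{nFrames} are ignored; \code{minSeparation} is applied jointly to
#'   all distinct centres of both channels).
#' @param seed optional integer seed.
#' @return list with \code{ch1}, \code{ch2} (matrices), \code{trueOverlap},
#'   \code{centres1}, \code{centres2} (two-column matrices, px) and
#'   \code{nucleusMask}.
#' @examples
#' pr <- simulateColocPair(50, 0.5, sceneSpec(imageSize = c(128L, 128L)),
#'                         seed = 1)
#' pr$trueOverlap
#' @export
simulateColocPair <- function(nSpots, overlapFraction, scene, seed = NULL) {
  stopifnot(is(scene, "SceneSpec"))
  if (!is.finite(overlapFraction) || overlapFraction < 0 ||
      overlapFraction > 1)
    stop("'overlapFraction' must be in [0, 1]")
  nSpots <- as.integer(nSpots)
  withSeed(seed, {
    nShared <- round(overlapFraction * nSpots)
    nTotal <- nShared + 2L * (nSpots - nShared)
    pts <- if (nTotal > 0L)
      samplePointsInEllipse(nTotal, scene@nucleusCentre, scene@nucleusAxes,
                            scene@minSeparation)
    else matrix(numeric(0), 0L, 2L)
    shared <- pts[seq_len(nShared), , drop = FALSE]
    only1 <- pts[nShared + seq_len(nSpots - nShared), , drop = FALSE]
    only2 <- pts[nShared + (nSpots - nShared) + seq_len(nSpots - nShared),
                 , drop = FALSE]
    c1 <- rbind(shared, only1)
    c2 <- rbind(shared, only2)
    render <- function(centres) {
      img <- matrix(scene@backgroundLevel, scene@imageSize[2L],
                    scene@imageSize[1L])
      sigmaPx <- scene@speckleSigma / scene@pixelSize
      for (i in seq_len(nrow(centres)))
        img <- addGaussianSpot(img, centres[i, 1L], centres[i, 2L],
                               scene@amplitude, sigmaPx)
      applySceneNoise(img, scene)
    }
    list(ch1 = render(c1), ch2 = render(c2),
         trueOverlap = overlapFraction, centres1 = c1, centres2 = c2,
         nucleusMask = ellipseMask(scene@imageSize, scene@nucleusCentre,
                                   scene@nucleusAxes))
  })
}
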