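# Speckle segmentation and morphometry. The per-frame recipe: subtract the
# local background (rolling-ball, radius 5 px by default), threshold with
# Li's minimum cross-entropy method (dark background), split touching
# objects with a watershed on the distance transform, fill holes, discard
# objects below the minimum area, and measure every retained object on the
# original unprocessed frame.

#' Li's minimum cross-entropy threshold
#'
#' Iterative threshold selection minimizing the cross entropy between the
#' image and its binarized version (Li & Tam, 1998). Intensities are shifted
#' to be strictly positive before iterating; the returned threshold is on
#' the original scale.
#'
#' @param x numeric vector or matrix of intensities.
#' @param tol convergence tolerance as a fraction of the intensity range.
#' @param maxIter maximum iterations.
#' @return The threshold, or \code{NA} if the image is degenerate (fewer
#'   than 2 distinct values) or the iteration fails to converge.
#' @examples
#' liThreshold(c(rep(1, 90), rep(10, 10)))
#' @export
liThreshold <- function(x, tol = 1e-4, maxIter = 100L) {
  v <- as.numeric(x)
  v <- v[is.finite(v)]
  rng <- range(v)
  if (length(v) < 2L || rng[2L] <= rng[1L]) return(NA_real_)
  shift <- rng[1L] - 1e-6 * (rng[2L] - rng[1L]) - 1e-12
  v <- v - shift
  t0 <- mean(v)
  eps <- tol * (rng[2L] - rng[1L])
  for (i in seq_len(maxIter)) {
    lo <- v[v <= t0]; hi <- v[v > t0]
    if (!length(lo) || !length(hi)) return(NA_real_)
    mb <- mean(lo); mf <- mean(hi)
    denom <- log(mf) - log(mb)
    if (!is.finite(denom) || denom == 0) return(NA_real_)
    t1 <- (mf - mb) / denom
    if (!is.finite(t1)) return(NA_real_)
    if (abs(t1 - t0) < eps) return(t1 + shift)
    t0 <- t1
  }
  NA_real_
}

# Rolling-ball-style background: greyscale morphological opening with a
# disc of the given radius. The alternative is a median filter of the same
# radius.
subtractBackground <- function(img, radius,
                               method = c("rolling_ball", "median")) {
  method <- match.arg(method)
  if (radius < 1L) return(img)
  if (method == "rolling_ball") {
    brush <- EBImage::makeBrush(2L * radius + 1L, shape = "disc")
    bg <- EBImage::opening(img, brush)
  } else {
    rng <- range(img)
    if (rng[2L] <= rng[1L]) return(img - img)
    scaled <- (img - rng[1L]) / (rng[2L] - rng[1L])
    bg <- as.matrix(EBImage::medianFilter(scaled, radius)) *
      (rng[2L] - rng[1L]) + rng[1L]
  }
  res <- img - as.matrix(bg)
  res[res < 0] <- 0
  res
}

# Threshold one background-subtracted frame; Li with Otsu fallback.
.thresholdFrame <- function(sub) {
  rng <- range(sub)
  if (rng[2L] <= rng[1L]) return(NA_real_)
  th <- liThreshold(sub)
  if (is.na(th)) {
    warning("Li threshold did not converge; falling back to Otsu")
    th <- EBImage::otsu(EBImage::Image(sub), range = rng)
  }
  th
}

# Label a binary mask, optionally splitting touching objects with a
# watershed, then fill holes. The watershed runs on the lightly smoothed
# background-subtracted intensity restricted to the mask, so touching
# spots separate at intensity saddles; the merge tolerance adapts to the
# dynamic range above the threshold so that noise-induced maxima inside a
# single spot do not oversplit it. (A watershed on the distance transform
# cannot split overlapping Gaussian spots: their joint mask has no waist.)
.labelMask <- function(mask, sub, th, useWatershed) {
  m <- EBImage::Image(mask)
  lab <- if (useWatershed) {
    topo <- as.matrix(EBImage::gblur(EBImage::Image(sub), sigma = 1))
    tol <- 0.2 * (max(topo[mask > 0]) - th)
    if (!is.finite(tol) || tol <= 0)
      EBImage::bwlabel(m)
    else
      EBImage::watershed(EBImage::Image(topo * (mask > 0)),
                         tolerance = tol, ext = 1L)
  } else {
    EBImage::bwlabel(m)
  }
  as.matrix(EBImage::fillHull(lab))
}

# Measure labelled objects on the original frame: area, intensity-weighted
# centroid (0-based), mean intensity. Drops labels with area < minAreaPx.
.measureLabels <- function(lab, original, minAreaPx, pixelSize) {
  idx <- which(lab > 0L)
  empty <- data.frame(label = integer(0), x_px = numeric(0),
                      y_px = numeric(0), area_px = integer(0),
                      area_um2 = numeric(0), mean_intensity = numeric(0))
  if (!length(idx)) return(empty)
  lv <- lab[idx]
  area <- tabulate(lv)
  keep <- which(area >= minAreaPx)
  if (!length(keep)) return(empty)
  ny <- nrow(lab)
  ys <- (idx - 1L) %% ny          # 0-based row = y
  xs <- (idx - 1L) %/% ny         # 0-based col = x
  w <- original[idx]
  sw <- rowsum(w, lv)[, 1L]
  swx <- rowsum(w * xs, lv)[, 1L]
  swy <- rowsum(w * ys, lv)[, 1L]
  labsPresent <- as.integer(rownames(rowsum(w, lv)))
  ord <- match(keep, labsPresent)
  data.frame(label = seq_along(keep),
             x_px = swx[ord] / sw[ord],
             y_px = swy[ord] / sw[ord],
             area_px = area[keep],
             area_um2 = area[keep] * pixelSize^2,
             mean_intensity = sw[ord] / area[keep])
}

#' Segment speckles in every frame of an image stack
#'
#' Per frame: subtract the local background, apply Li's threshold (Otsu
#' fallback on degenerate frames, with a warning), split touching objects
#' with an intensity watershed restricted to the mask, fill holes, and
#' keep connected components of at least \code{minAreaPx} pixels.
#' Measurements (intensity-weighted centroid, mean intensity) are taken on
#' the original unprocessed frame. Frames that are empty or constant yield
#' zero speckles rather than an error.
#'
#' @param stack an \linkS4class{ImageStack} (or a single matrix, treated as
#'   a one-frame stack with the given calibration).
#' @param bgRadius background-subtraction radius in px.
#' @param minAreaPx minimum object area in px.
#' @param bgMethod \code{"rolling_ball"} (greyscale opening) or
#'   \code{"median"}.
#' @param useWatershed apply the watershed split (disable to merge touching
#'   objects).
#' @param nucleusMask optional binary matrix; detections outside are
#'   discarded and the mask is carried into the result for area fractions.
#' @param pixelSize,frameInterval calibration used when \code{stack} is a
#'   bare matrix.
#' @return A \linkS4class{SpeckleSet}.
#' @examples
#' sc <- sceneSpec(nSpeckles = 5L, imageSize = c(64L, 64L), noise = "none",
#'                 minSeparation = 12)
#' mv <- renderSpeckleMovie(sc, motionModel("static"), seed = 1)
#' ss <- segmentSpeckles(mv$stack)
#' nrow(speckles(ss))
#' @export
segmentSpeckles <- function(stack, bgRadius = 5L, minAreaPx = 10L,
                            bgMethod = c("rolling_ball", "median"),
                            useWatershed = TRUE, nucleusMask = NULL,
                            pixelSize = 0.1, frameInterval = 0.05) {
  bgMethod <- match.arg(bgMethod)
  if (is.matrix(stack))
    stack <- ImageStack(stack, pixelSize, frameInterval)
  stopifnot(is(stack, "ImageStack"))
  res <- vector("list", nFrames(stack))
  for (t in seq_len(nFrames(stack))) {
    frame <- getFrame(stack, t)
    sub <- subtractBackground(frame, bgRadius, bgMethod)
    th <- .thresholdFrame(sub)
    if (is.na(th)) next
    mask <- (sub > th) * 1
    if (!is.null(nucleusMask)) mask <- mask * (nucleusMask > 0)
    if (!any(mask > 0)) next
    lab <- .labelMask(mask, sub, th, useWatershed)
    tab <- .measureLabels(lab, frame, minAreaPx, pixelSize(stack))
    if (nrow(tab)) res[[t]] <- cbind(frame = t, tab)
  }
  tabs <- res[!vapply(res, is.null, logical(1))]
  speckles <- if (length(tabs)) do.call(rbind, tabs) else
    data.frame(frame = integer(0), label = integer(0), x_px = numeric(0),
               y_px = numeric(0), area_px = integer(0), area_um2 = numeric(0),
               mean_intensity = numeric(0))
  rownames(speckles) <- NULL
  new("SpeckleSet", speckles = speckles, pixelSize = pixelSize(stack),
      nFrames = nFrames(stack), nucleusMask = nucleusMask)
}

#' Summarize a SpeckleSet across frames
#'
#' Arithmetic means over frames of the per-frame speckle count and speckle
#' area, plus the fraction of the nucleus area covered by speckles (total
#' speckle area / nucleus area, averaged over frames). The fraction is
#' \code{NA} when no nucleus mask is available, never silently zero.
#'
#' @param x a \linkS4class{SpeckleSet}.
#' @return list with \code{meanCountPerFrame}, \code{meanAreaUm2} (NA when
#'   no speckles at all) and \code{fractionNucleusArea}.
#' @export
summarizeSpeckles <- function(x) {
  stopifnot(is(x, "SpeckleSet"))
  sp <- x@speckles
  counts <- tabulate(sp$frame, nbins = x@nFrames)
  meanCount <- if (x@nFrames) mean(counts) else 0
  meanArea <- if (nrow(sp)) mean(sp$area_um2) else NA_real_
  frac <- NA_real_
  if (!is.null(x@nucleusMask)) {
    nucArea <- sum(x@nucleusMask > 0)
    if (nucArea > 0) {
      perFrame <- rowsum(sp$area_px, sp$frame)
      tot <- numeric(x@nFrames)
      tot[as.integer(rownames(perFrame))] <- perFrame[, 1L]
      frac <- mean(tot / nucArea)
    }
  }
  list(meanCountPerFrame = meanCount, meanAreaUm2 = meanArea,
       fractionNucleusArea = frac)
}
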