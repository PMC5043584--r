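# Particle detection and frame-to-frame linking. Defaults follow the
# tracking parameters used for the speckle movies: detection radius 5 px,
# brightest 5% of pixels as candidates, discrimination cutoff 1, link range
# 1 frame, maximum displacement 5 px.

#' Detect diffraction-limited particles in one frame
#'
#' The frame is restored by boxcar smoothing over a disc of the given
#' radius; local maxima of the restored image lying in its upper
#' \code{percentile} of intensity become candidates. Each candidate is
#' refined to an intensity-weighted sub-pixel centroid within the disc (on
#' the raw frame after subtracting the local window minimum), and its
#' intensity moments m0 (integrated intensity) and m2 (radius of gyration,
#' px^2) are recorded. Candidates whose discrimination score falls below
#' \code{cutoff} are removed; the score is the restored peak height above
#' the image median, in units of five robust standard deviations of the
#' restored image, so score 1 marks a peak five robust s.d. above
#' background.
#'
#' @param frame numeric matrix (rows = y).
#' @param radiusPx detection radius in px (>= 1).
#' @param percentile percentage of brightest restored pixels eligible as
#'   candidates, in (0, 100].
#' @param cutoff minimum discrimination score.
#' @return data.frame with columns \code{x, y} (0-based px), \code{m0, m2,
#'   score}, ordered by (x, y); zero rows for a flat frame.
#' @examples
#' img <- matrix(10, 64, 64)
#' img <- speckleQuant:::addGaussianSpot(img, 30, 20, 200, 2)
#' detectParticles(img)
#' @export
detectParticles <- function(frame, radiusPx = 5L, percentile = 5,
                            cutoff = 1) {
  stopifnot(is.matrix(frame))
  radiusPx <- as.integer(radiusPx)
  if (radiusPx < 1L) stop("'radiusPx' must be >= 1")
  if (percentile <= 0 || percentile > 100)
    stop("'percentile' must be in (0, 100]")
  empty <- data.frame(x = numeric(0), y = numeric(0), m0 = numeric(0),
                      m2 = numeric(0), score = numeric(0))
  rng <- range(frame)
  if (!is.finite(rng[1L]) || rng[2L] <= rng[1L]) return(empty)

  brush <- EBImage::makeBrush(2L * radiusPx + 1L, shape = "disc")
  kern <- brush / sum(brush)
  sm <- as.matrix(EBImage::filter2(frame, kern))
  dil <- as.matrix(EBImage::dilate(EBImage::Image(sm), brush))
  thr <- quantile(sm, 1 - percentile / 100)
  smMed <- median(sm)
  smMad <- mad(sm)
  if (smMad == 0) smMad <- sd(sm)
  peaks <- which(sm >= dil - 1e-12 & sm >= thr & sm > smMed)
  if (!length(peaks)) return(empty)

  ny <- nrow(frame); nx <- ncol(frame)
  py <- (peaks - 1L) %% ny + 1L
  px <- (peaks - 1L) %/% ny + 1L
  disc <- which(brush > 0, arr.ind = TRUE) - (radiusPx + 1L)  # offsets
  out <- vector("list", length(peaks))
  for (i in seq_along(peaks)) {
    rr <- py[i] + disc[, 1L]
    cc <- px[i] + disc[, 2L]
    ok <- rr >= 1L & rr <= ny & cc >= 1L & cc <= nx
    rr <- rr[ok]; cc <- cc[ok]
    w <- frame[cbind(rr, cc)]
    w <- w - min(w)
    m0 <- sum(w)
    if (m0 <= 0) next
    xc <- sum(w * (cc - 1L)) / m0
    yc <- sum(w * (rr - 1L)) / m0
    m2 <- sum(w * ((cc - 1L - xc)^2 + (rr - 1L - yc)^2)) / m0
    score <- (sm[peaks[i]] - smMed) / (5 * smMad)
    out[[i]] <- c(xc, yc, m0, m2, score)
  }
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) return(empty)
  det <- data.frame(x = out[, 1L], y = out[, 2L], m0 = out[, 3L],
                    m2 = out[, 4L], score = out[, 5L])
  det <- det[det$score >= cutoff, , drop = FALSE]
  # merge duplicate refined positions from plateau maxima of the same spot
  if (nrow(det) > 1L) {
    o <- order(det$x, det$y)
    det <- det[o, , drop = FALSE]
    keep <- rep(TRUE, nrow(det))
    for (i in seq_len(nrow(det) - 1L)) {
      if (!keep[i]) next
      j <- which(keep & seq_len(nrow(det)) > i)
      d2 <- (det$x[j] - det$x[i])^2 + (det$y[j] - det$y[i])^2
      keep[j[d2 < (radiusPx / 2)^2]] <- FALSE
    }
    det <- det[keep, , drop = FALSE]
  }
  det <- det[order(det$x, det$y), , drop = FALSE]
  rownames(det) <- NULL
  det
}

# Optimal bipartite assignment between two point sets, gated at maxDisp.
# Maximizes match count, then minimizes total squared displacement.
# Returns an integer vector: for each row of 'b', the matched index in 'a'
# (NA if unmatched).
.assignPoints <- function(ax, ay, bx, by, maxDisp,
                          method = c("optimal", "greedy")) {
  method <- match.arg(method)
  n1 <- length(ax); n2 <- length(bx)
  match2 <- rep(NA_integer_, n2)
  if (!n1 || !n2) return(match2)
  d2 <- outer(ax, bx, "-")^2 + outer(ay, by, "-")^2
  gate <- maxDisp^2
  if (method == "greedy") {
    repeat {
      m <- which.min(d2)
      if (!length(m) || d2[m] > gate || !is.finite(d2[m])) break
      i <- (m - 1L) %% n1 + 1L
      j <- (m - 1L) %/% n1 + 1L
      match2[j] <- i
      d2[i, ] <- Inf
      d2[, j] <- Inf
    }
    return(match2)
  }
  ed <- which(d2 <= gate, arr.ind = TRUE)
  if (!nrow(ed)) return(match2)
  C <- (n1 + n2 + 1) * gate + 1
  w <- C - d2[ed]
  edges <- as.vector(t(cbind(ed[, 1L], n1 + ed[, 2L])))
  g <- igraph::make_bipartite_graph(c(rep(FALSE, n1), rep(TRUE, n2)),
                                    edges = edges, directed = FALSE)
  mm <- igraph::max_bipartite_match(g, weights = w)$matching
  for (j in seq_len(n2)) {
    v <- mm[n1 + j]
    if (!is.na(v)) match2[j] <- as.integer(v)
  }
  match2
}

#' Link per-frame detections into trajectories
#'
#' Consecutive-frame assignment minimizing total squared displacement among
#' candidate pairs within \code{maxDisplacementPx} (optimal bipartite
#' matching; a greedy nearest-neighbour variant is available). Unmatched
#' detections start new tracks; tracks not extended within
#' \code{linkRange} frames terminate. Detections are sorted by (x, y)
#' within each frame before matching, so linking is invariant to detection
#' order.
#'
#' @param detections list of per-frame data.frames with columns \code{x, y}
#'   (one entry per frame, in frame order; empty data.frames allowed).
#' @param linkRange maximum frame gap across which a track may be extended
#'   (default 1 = consecutive frames only).
#' @param maxDisplacementPx gating radius in px.
#' @param method \code{"optimal"} or \code{"greedy"}.
#' @param pixelSize,frameInterval calibration stamped onto the returned
#'   trajectories.
#' @return list of \linkS4class{Trajectory}, ordered by start frame then
#'   start position.
#' @examples
#' det <- lapply(0:9, function(f) data.frame(x = f * 1.0, y = 0))
#' tr <- linkParticles(det, pixelSize = 0.1, frameInterval = 0.05)
#' length(tr[[1]])
#' @export
linkParticles <- function(detections, linkRange = 1L, maxDisplacementPx = 5,
                          method = c("optimal", "greedy"), pixelSize = 0.1,
                          frameInterval = 0.05) {
  method <- match.arg(method)
  linkRange <- as.integer(linkRange)
  if (linkRange < 1L) stop("'linkRange' must be >= 1")
  if (maxDisplacementPx <= 0) stop("'maxDisplacementPx' must be > 0")
  nF <- length(detections)
  tracks <- list()   # each: list(frames, x, y, lastFrame)
  active <- integer(0)
  for (f in seq_len(nF)) {
    det <- detections[[f]]
    if (is.null(det) || !nrow(det)) {
      active <- active[vapply(tracks[active], function(tr)
        f - tr$lastFrame < linkRange, logical(1))]
      next
    }
    det <- det[order(det$x, det$y), , drop = FALSE]
    n2 <- nrow(det)
    if (length(active)) {
      ax <- vapply(tracks[active], function(tr) tr$x[length(tr$x)],
                   numeric(1))
      ay <- vapply(tracks[active], function(tr) tr$y[length(tr$y)],
                   numeric(1))
      mt <- .assignPoints(ax, ay, det$x, det$y, maxDisplacementPx, method)
    } else {
      mt <- rep(NA_integer_, n2)
    }
    newActive <- integer(0)
    for (j in seq_len(n2)) {
      if (!is.na(mt[j])) {
        id <- active[mt[j]]
        tracks[[id]]$frames <- c(tracks[[id]]$frames, f)
        tracks[[id]]$x <- c(tracks[[id]]$x, det$x[j])
        tracks[[id]]$y <- c(tracks[[id]]$y, det$y[j])
        tracks[[id]]$lastFrame <- f
        newActive <- c(newActive, id)
      } else {
        tracks[[length(tracks) + 1L]] <-
          list(frames = f, x = det$x[j], y = det$y[j], lastFrame = f)
        newActive <- c(newActive, length(tracks))
      }
    }
    # tracks missed this frame stay active while within linkRange
    missed <- setdiff(active, newActive)
    missed <- missed[vapply(tracks[missed], function(tr)
      f - tr$lastFrame < linkRange, logical(1))]
    active <- c(newActive, missed)
  }
  lapply(seq_along(tracks), function(i) {
    tr <- tracks[[i]]
    Trajectory(frames = tr$frames, x = tr$x, y = tr$y,
               pixelSize = pixelSize, frameInterval = frameInterval,
               trackId = i)
  })
}

#' Detect and link particles across an image stack
#'
#' Convenience wrapper: \code{\link{detectParticles}} on every frame, then
#' \code{\link{linkParticles}}.
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param radiusPx,percentile,cutoff see \code{\link{detectParticles}}.
#' @param linkRange,maxDisplacementPx,method see
#'   \code{\link{linkParticles}}.
#' @return list of \linkS4class{Trajectory}.
#' @export
trackSpeckles <- function(stack, radiusPx = 5L, percentile = 5, cutoff = 1,
                          linkRange = 1L, maxDisplacementPx = 5,
                          method = c("optimal", "greedy")) {
  stopifnot(is(stack, "ImageStack"))
  det <- lapply(seq_len(nFrames(stack)), function(t)
    detectParticles(getFrame(stack, t), radiusPx, percentile, cutoff))
  linkParticles(det, linkRange, maxDisplacementPx, match.arg(method),
                pixelSize = pixelSize(stack),
                frameInterval = frameInterval(stack))
}
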