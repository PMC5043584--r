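# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random stream. seed = NULL runs `expr` unmodified.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Uniform sampling of n points inside an ellipse (0-based px coordinates),
# optionally with a minimum pairwise separation (simple rejection).
samplePointsInEllipse <- function(n, centre, axes, minSeparation = 0,
                                  maxTries = 20000L) {
  pts <- matrix(NA_real_, n, 2L)
  k <- 0L
  tries <- 0L
  while (k < n) {
    tries <- tries + 1L
    if (tries > maxTries)
      stop("could not place ", n, " points with minSeparation = ",
           minSeparation, " inside the nucleus ellipse")
    u <- sqrt(runif(1))
    th <- runif(1, 0, 2 * pi)
    p <- centre + u * c(axes[1L] * cos(th), axes[2L] * sin(th))
    if (minSeparation > 0 && k > 0L) {
      d2 <- (pts[seq_len(k), 1L] - p[1L])^2 + (pts[seq_len(k), 2L] - p[2L])^2
      if (min(d2) < minSeparation^2) next
    }
    k <- k + 1L
    pts[k, ] <- p
  }
  pts
}

insideEllipse <- function(x, y, centre, axes) {
  ((x - centre[1L]) / axes[1L])^2 + ((y - centre[2L]) / axes[2L])^2 <= 1
}

# Binary mask of an ellipse for an image of size c(nx, ny); matrix is
# c(ny, nx) with rows = y.
ellipseMask <- function(imageSize, centre, axes) {
  nx <- imageSize[1L]; ny <- imageSize[2L]
  xs <- matrix(rep(0:(nx - 1L), each = ny), ny, nx)
  ys <- matrix(rep(0:(ny - 1L), nx), ny, nx)
  (insideEllipse(xs, ys, centre, axes)) * 1
}

# Add one 2-D Gaussian spot (amplitude A, s.d. sigma px) at 0-based (x0, y0)
# to image matrix img (rows = y). Rendered on a +-4 sigma window.
addGaussianSpot <- function(img, x0, y0, A, sigma) {
  ny <- nrow(img); nx <- ncol(img)
  r <- ceiling(4 * sigma)
  clo <- max(1L, floor(x0) + 1L - r); chi <- min(nx, floor(x0) + 1L + r)
  rlo <- max(1L, floor(y0) + 1L - r); rhi <- min(ny, floor(y0) + 1L + r)
  if (clo > chi || rlo > rhi) return(img)
  xs <- (clo:chi) - 1L
  ys <- (rlo:rhi) - 1L
  gx <- exp(-((xs - x0)^2) / (2 * sigma^2))
  gy <- exp(-((ys - y0)^2) / (2 * sigma^2))
  img[rlo:rhi, clo:chi] <- img[rlo:rhi, clo:chi] + A * outer(gy, gx)
  img
}

# Apply the scene's photon-noise model to an image (noise applied last).
applySceneNoise <- function(img, scene) {
  switch(scene@noise,
         none = img,
         gaussian = img * (1 + matrix(rnorm(length(img), sd = scene@noiseSd),
                                      nrow(img), ncol(img))),
         poisson = matrix(rpois(length(img), lambda = pmax(img, 0)),
                          nrow(img), ncol(img)))
}

# Slope of a least-squares line y ~ x (intercept free); x must vary.
lsSlope <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sum((x - mx)^2)
}
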