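# Independent oracles and small utilities shared across the test files.
# These deliberately avoid the package's own code paths.

# Ensemble mean squared displacement at a set of frame lags, computed
# directly from a list of position matrices (um).
oracleMSD <- function(posList, lags) {
  vapply(lags, function(d) {
    mean(unlist(lapply(posList, function(p) {
      n <- nrow(p)
      dx <- p[(1 + d):n, 1] - p[1:(n - d), 1]
      dy <- p[(1 + d):n, 2] - p[1:(n - d), 2]
      dx^2 + dy^2
    })))
  }, numeric(1))
}

# Greedy nearest-neighbour matching of detections to planted positions.
# 'matched' counts truths matched within 'tol' px; 'spurious' counts
# detections farther than 'spuriousTol' px from every planted position
# (i.e. detections that correspond to no real object at all).
matchToTruth <- function(det, truth, tol, spuriousTol = 2) {
  used <- rep(FALSE, nrow(det))
  matched <- 0L
  dists <- numeric(0)
  for (i in seq_len(nrow(truth))) {
    if (!nrow(det)) break
    d2 <- (det$x - truth[i, 1])^2 + (det$y - truth[i, 2])^2
    d2[used] <- Inf
    j <- which.min(d2)
    if (is.finite(d2[j]) && d2[j] <= tol^2) {
      used[j] <- TRUE
      matched <- matched + 1L
      dists <- c(dists, sqrt(d2[j]))
    }
  }
  spurious <- 0L
  for (j in seq_len(nrow(det))) {
    d2 <- (truth[, 1] - det$x[j])^2 + (truth[, 2] - det$y[j])^2
    if (min(d2) > spuriousTol^2) spurious <- spurious + 1L
  }
  list(matched = matched, spurious = spurious, dists = dists)
}

# Brute-force Costes threshold oracle: orthogonal regression line from the
# eigendecomposition of the standardized covariance (mapped back to raw
# units), then an exhaustive scan over all distinct channel-1 values,
# keeping every candidate whose below-threshold Pearson correlation is <= 0
# and reporting the maximum such T1.
oracleCostes <- function(ch1, ch2) {
  v1 <- as.vector(ch1)
  v2 <- as.vector(ch2)
  S <- cov(cbind(scale(v1), scale(v2)))
  e <- eigen(S)
  vec <- e$vectors[, 1]
  m <- (vec[2] / vec[1]) * sd(v2) / sd(v1)
  q <- mean(v2) - m * mean(v1)
  cand <- sort(unique(v1), decreasing = TRUE)
  sat <- c()
  for (tt in cand) {
    t2 <- m * tt + q
    below <- v1 < tt & v2 < t2
    if (sum(below) >= 2) {
      b1 <- v1[below]; b2 <- v2[below]
      if (sd(b1) > 0 && sd(b2) > 0 && cor(b1, b2) <= 0)
        sat <- c(sat, tt)
    }
  }
  if (!length(sat)) return(list(T1 = min(v1), found = FALSE))
  list(T1 = max(sat), found = TRUE)
}

# Quick scene for planted-spot tests: well-separated bright Gaussians.
plantedScene <- function(nSpots = 20L, imageSize = c(256L, 256L),
                         noiseSd = 0.05, minSeparation = 20,
                         nFrames = 1L, noise = "gaussian") {
  sceneSpec(nSpeckles = nSpots, imageSize = imageSize, noise = noise,
            noiseSd = noiseSd, minSeparation = minSeparation,
            nFrames = nFrames)
}

trajFromMatrix <- function(p, pixelSize = 0.1, frameInterval = 0.05) {
  Trajectory(seq_len(nrow(p)), p[, 1], p[, 2], pixelSize, frameInterval)
}
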