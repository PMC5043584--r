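# Costes automatic thresholding and Manders co-localization coefficients
# for two-channel images.

# Orthogonal regression ch2 = m * ch1 + q, computed on standardized
# intensities and mapped back (equivalently, reduced major axis:
# m = sign(cov) * sd2/sd1). Standardizing makes the line equivariant under
# per-channel intensity scaling, which the Manders coefficients inherit;
# raw-unit total least squares does not have this property and is unstable
# for weakly correlated channels. OLS available as a config switch.
.colocLine <- function(v1, v2, regression = c("orthogonal", "ols")) {
  regression <- match.arg(regression)
  if (regression == "ols") {
    m <- lsSlope(v1, v2)
  } else {
    s12 <- cov(v1, v2)
    m <- sqrt(var(v2) / var(v1))
    if (s12 < 0) m <- -m
  }
  q <- mean(v2) - m * mean(v1)
  list(slope = m, intercept = q)
}

#' Costes automatic threshold for a two-channel image pair
#'
#' Orthogonal regression of channel 2 on channel 1 — computed on
#' standardized intensities and mapped back, so the line (and everything
#' downstream) is equivariant under per-channel intensity scaling — gives
#' the line \code{ch2 = m ch1 + q}. Starting from the channel-1 maximum, the
#' candidate threshold T1 is lowered stepwise through the sorted distinct
#' channel-1 intensities with T2 = m T1 + q; the selected pair is the
#' highest (T1, T2) for which the Pearson correlation of the pixels with
#' \code{ch1 < T1 & ch2 < T2} satisfies the stopping criterion. The default
#' criterion, \code{"nonsignificant"}, stops as soon as the below-threshold
#' correlation is no longer significantly positive
#' (\eqn{r \le 1.96/\sqrt{n - 3}} for n below-threshold pixels); this makes
#' the scan robust to sampling noise — for truly independent channels the
#' correlation fluctuates around zero and a strict non-positivity rule
#' would walk arbitrarily far into the intensity distribution before a
#' chance crossing. \code{"nonpositive"} is the canonical strict rule
#' (\eqn{r \le 0}) and \code{"fraction"} stops below \code{rFraction} times
#' the global correlation. The scan over distinct values is deterministic
#' for any bit depth. If the criterion already holds at the intensity
#' maximum the channels carry no positive correlation to threshold:
#' thresholds are reported at the channel maxima with a warning flag. If it
#' never holds (e.g. identical channels) the thresholds land at the scan
#' floor, the channel-1 minimum.
#'
#' @param ch1,ch2 numeric matrices of equal shape.
#' @param mask optional binary matrix; only pixels inside are analysed.
#' @param criterion \code{"nonsignificant"} (default),
#'   \code{"nonpositive"} (original strict rule) or \code{"fraction"}.
#' @param rFraction threshold on \code{r_below / max(r_global, 0)} for
#'   \code{criterion = "fraction"}.
#' @param regression \code{"orthogonal"} (on standardized intensities;
#'   equivalent to reduced major axis) or \code{"ols"}.
#' @return list with \code{T1}, \code{T2}, \code{slope}, \code{intercept},
#'   \code{pearsonGlobal}, \code{warn} ("" | "anticorrelated" |
#'   "no_threshold_found").
#' @examples
#' set.seed(1)
#' a <- matrix(runif(256), 16, 16); b <- a + matrix(rnorm(256, 0, .05), 16)
#' costesThreshold(a, b)$T1
#' @export
costesThreshold <- function(ch1, ch2, mask = NULL,
                            criterion = c("nonsignificant", "nonpositive",
                                          "fraction"),
                            rFraction = 0.05,
                            regression = c("orthogonal", "ols")) {
  criterion <- match.arg(criterion)
  regression <- match.arg(regression)
  stopifnot(is.matrix(ch1), is.matrix(ch2), all(dim(ch1) == dim(ch2)))
  sel <- if (is.null(mask)) rep(TRUE, length(ch1)) else as.vector(mask > 0)
  v1 <- as.vector(ch1)[sel]
  v2 <- as.vector(ch2)[sel]
  if (length(unique(v1)) < 2L || length(unique(v2)) < 2L)
    stop("need >= 2 distinct intensities per channel within the mask")
  ln <- .colocLine(v1, v2, regression)
  m <- ln$slope; q <- ln$intercept
  if (!is.finite(m))
    stop("degenerate regression line (vertical); cannot scan thresholds")
  rGlobal <- cor(v1, v2)
  # a non-positive regression slope means the channels share no positive
  # correlation to threshold: report the channel maxima directly
  if (m <= 0) {
    return(list(T1 = max(v1), T2 = max(v2), slope = m, intercept = q,
                pearsonGlobal = rGlobal, warn = "anticorrelated"))
  }
  # stopping bound on the below-threshold correlation; for
  # "nonsignificant" it depends on the below-pixel count and is computed
  # per candidate, with at least 10 pixels required for the test to have
  # any power
  minBelow <- if (criterion == "nonsignificant") 10L else 2L
  rBound <- function(nBelow) {
    switch(criterion,
           nonsignificant = 1.96 / sqrt(max(nBelow - 3, 1)),
           nonpositive = 0,
           fraction = rFraction * max(rGlobal, 0))
  }

  cand <- sort(unique(v1), decreasing = TRUE)
  # Pixels leave the below-threshold set monotonically as T1 decreases:
  # pixel i exits at the first candidate k with cand[k] <= v1[i] or
  # m*cand[k] + q <= v2[i].
  exitK <- rep(length(cand) + 1L, length(v1))
  # exit via ch1: first cand <= v1  (cand descending)
  k1 <- length(cand) + 1L - findInterval(v1, rev(cand))
  # k1 gives index of first candidate <= v1[i]
  exitK <- pmin(exitK, k1)
  tStar <- (v2 - q) / m  # exit via ch2 when cand <= tStar
  k2 <- length(cand) + 1L - findInterval(tStar, rev(cand))
  exitK <- pmin(exitK, k2)
  found <- NA_integer_
  {
    ord <- order(exitK)
    n <- length(v1)
    sx <- sum(v1); sy <- sum(v2)
    sxx <- sum(v1^2); syy <- sum(v2^2); sxy <- sum(v1 * v2)
    cnt <- n
    pos <- 1L
    for (k in seq_along(cand)) {
      while (pos <= n && exitK[ord[pos]] <= k) {
        i <- ord[pos]
        sx <- sx - v1[i]; sy <- sy - v2[i]
        sxx <- sxx - v1[i]^2; syy <- syy - v2[i]^2; sxy <- sxy - v1[i] * v2[i]
        cnt <- cnt - 1L
        pos <- pos + 1L
      }
      if (cnt < minBelow) next
      vx <- sxx - sx^2 / cnt
      vy <- syy - sy^2 / cnt
      cxy <- sxy - sx * sy / cnt
      if (vx <= 1e-12 * max(sxx, 1) || vy <= 1e-12 * max(syy, 1)) next
      r <- cxy / sqrt(vx * vy)
      if (r <= rBound(cnt)) { found <- k; break }
    }
  }
  warn <- ""
  if (is.na(found)) {
    T1 <- min(v1)
    warn <- "no_threshold_found"
  } else {
    T1 <- cand[found]
    if (found == 1L) warn <- "anticorrelated"
  }
  T2 <- m * T1 + q
  T2 <- min(max(T2, min(v2)), max(v2))
  list(T1 = T1, T2 = T2, slope = m, intercept = q, pearsonGlobal = rGlobal,
       warn = warn)
}

#' Manders co-localization coefficients at given thresholds
#'
#' Thresholded convention (the default report):
#' \code{tM1 = sum(ch1[ch1 > T1 & ch2 > T2]) / sum(ch1[ch1 > T1])} and
#' symmetrically for tM2. The single-condition variants
#' \code{M1 = sum(ch1[ch2 > T2]) / sum(ch1)} (and M2) are returned
#' alongside. A coefficient whose denominator has no above-threshold signal
#' is NA (flagged), never silently 0.
#'
#' @param ch1,ch2 numeric matrices of equal shape.
#' @param T1,T2 channel thresholds.
#' @param mask optional binary matrix.
#' @return list with \code{tM1, tM2, M1, M2} and \code{undefined}
#'   (character vector naming any undefined coefficients).
#' @examples
#' a <- matrix(c(0, 5, 5, 0), 2); b <- matrix(c(0, 5, 0, 5), 2)
#' mandersCoefficients(a, b, 1, 1)
#' @export
mandersCoefficients <- function(ch1, ch2, T1, T2, mask = NULL) {
  stopifnot(is.matrix(ch1), is.matrix(ch2), all(dim(ch1) == dim(ch2)))
  sel <- if (is.null(mask)) rep(TRUE, length(ch1)) else as.vector(mask > 0)
  v1 <- as.vector(ch1)[sel]
  v2 <- as.vector(ch2)[sel]
  a1 <- v1 > T1
  a2 <- v2 > T2
  undef <- character(0)
  den1 <- sum(v1[a1]); den2 <- sum(v2[a2])
  tM1 <- if (den1 > 0) sum(v1[a1 & a2]) / den1 else
    { undef <- c(undef, "tM1"); NA_real_ }
  tM2 <- if (den2 > 0) sum(v2[a1 & a2]) / den2 else
    { undef <- c(undef, "tM2"); NA_real_ }
  M1 <- if (sum(v1) > 0) sum(v1[a2]) / sum(v1) else
    { undef <- c(undef, "M1"); NA_real_ }
  M2 <- if (sum(v2) > 0) sum(v2[a1]) / sum(v2) else
    { undef <- c(undef, "M2"); NA_real_ }
  list(tM1 = tM1, tM2 = tM2, M1 = M1, M2 = M2, undefined = undef)
}

#' Full co-localization analysis of a channel pair
#'
#' Optional per-channel rolling-ball background subtraction, Costes
#' automatic thresholding, then thresholded Manders coefficients.
#'
#' @param ch1,ch2 numeric matrices of equal shape.
#' @param mask optional binary nucleus mask.
#' @param bgRadius1,bgRadius2 optional background-subtraction radii (px)
#'   applied per channel before analysis (NULL = none).
#' @param ... passed to \code{\link{costesThreshold}}.
#' @return A \linkS4class{ColocResult}.
#' @examples
#' pr <- simulateColocPair(30, 0.5, sceneSpec(imageSize = c(96L, 96L)),
#'                         seed = 1)
#' colocalize(pr$ch1, pr$ch2, mask = pr$nucleusMask)
#' @export
colocalize <- function(ch1, ch2, mask = NULL, bgRadius1 = NULL,
                       bgRadius2 = NULL, ...) {
  if (!is.null(bgRadius1)) ch1 <- subtractBackground(ch1, bgRadius1)
  if (!is.null(bgRadius2)) ch2 <- subtractBackground(ch2, bgRadius2)
  ct <- costesThreshold(ch1, ch2, mask, ...)
  mc <- mandersCoefficients(ch1, ch2, ct$T1, ct$T2, mask)
  nPix <- if (is.null(mask)) length(ch1) else sum(mask > 0)
  new("ColocResult", pearsonGlobal = ct$pearsonGlobal,
      threshold1 = ct$T1, threshold2 = ct$T2, tM1 = mc$tM1, tM2 = mc$tM2,
      M1 = mc$M1, M2 = mc$M2, slope = ct$slope, intercept = ct$intercept,
      nPixels = as.integer(nPix), warn = ct$warn)
}
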