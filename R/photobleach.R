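# FRAP / FLIP trace processing: background subtraction, pre-bleach
# normalization, acquisition-bleach correction by ratioing against the
# control region, full-scale normalization, and one-component exponential
# fitting for mobile fraction and half-time.

#' Normalize a FRAP ROI trace
#'
#' The processing chain: (i) subtract the time-averaged background (ROI3)
#' from the bleached (ROI1) and control (ROI2) series; (ii) divide each by
#' its own pre-bleach mean; (iii) form the ratio \code{R(t) = ROI1/ROI2},
#' which cancels, exactly, any multiplicative acquisition bleaching shared
#' by the two regions; (iv) full-scale normalize with the first post-bleach
#' value \code{Rp}: \code{F(t) = (R(t) - Rp) / (1 - Rp)}, so F = 0 at the
#' first post-bleach frame and F = 1 at complete recovery. Time is 0 at the
#' first post-bleach frame. Set \code{fullScale = FALSE} to stop at the
#' plain ratio R(t).
#'
#' @param trace a \linkS4class{RoiTrace}.
#' @param fullScale apply step (iv).
#' @return data.frame with columns \code{time} (s, from 0) and \code{F}
#'   (post-bleach frames only), with attributes \code{Rp} and
#'   \code{prebleach} (the pre-bleach R values).
#' @examples
#' tr <- simulateFrapTrace(frapSimParams(noiseSd = 0), seed = 1)
#' f <- normalizeFrap(tr)
#' round(tail(f$F, 1), 2)
#' @export
normalizeFrap <- function(trace, fullScale = TRUE) {
  stopifnot(is(trace, "RoiTrace"))
  npre <- trace@nPrebleach
  bg <- mean(trace@roiBackground)
  r1 <- trace@roiBleach - bg
  r2 <- trace@roiControl - bg
  if (any(r2 <= 0))
    stop("control ROI has zero/negative background-subtracted intensity")
  pre <- seq_len(npre)
  pre1 <- mean(r1[pre]); pre2 <- mean(r2[pre])
  if (pre1 <= 0) stop("bleached ROI has non-positive pre-bleach mean")
  R <- (r1 / pre1) / (r2 / pre2)
  post <- (npre + 1L):length(R)
  Rp <- R[post[1L]]
  out <- if (fullScale) {
    if (Rp >= 1) stop("no detectable bleach: first post-bleach value >= 1")
    data.frame(time = trace@time[post], F = (R[post] - Rp) / (1 - Rp))
  } else {
    data.frame(time = trace@time[post], F = R[post])
  }
  attr(out, "Rp") <- Rp
  attr(out, "prebleach") <- R[pre]
  out
}

# Single-exponential least-squares fit of f(t) = b + (a - b) exp(-c t)
# with multi-start initialization. Returns list(a, b, rate, rss, converged).
.fitExp <- function(tt, yy) {
  n <- length(yy)
  tailMean <- mean(yy[max(1L, n - max(9L, floor(n / 10))):n])
  a0 <- yy[1L]
  mid <- a0 + (tailMean - a0) / 2
  iMid <- if (tailMean >= a0) which(yy >= mid)[1L] else which(yy <= mid)[1L]
  tMid <- if (!is.na(iMid) && tt[iMid] > 0) tt[iMid] else
    max(tt[2L], diff(range(tt)) / 10)
  c0 <- log(2) / tMid
  starts <- list(c(a0, tailMean, c0),
                 c(a0, tailMean, c0 / 3),
                 c(a0, tailMean, c0 * 3),
                 c(a0, max(yy), c0),
                 c(mean(yy), tailMean, log(2) / diff(range(tt))))
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(yy ~ b + (a - b) * exp(-cr * tt),
                        start = list(a = s[1L], b = s[2L], cr = s[3L]),
                        lower = c(-Inf, -Inf, 1e-8),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(residuals(fit)^2)
    if (is.null(best) || rss < best$rss)
      best <- c(as.list(coef(fit)), list(rss = rss))
  }
  if (is.null(best))
    return(list(a = NA_real_, b = NA_real_, rate = NA_real_, rss = NA_real_,
                converged = FALSE))
  # honest convergence: a rate at its lower bound, or an amplitude buried in
  # the residual noise, means there is no resolvable exponential
  noiseScale <- sqrt(best$rss / n)
  conv <- best$cr > 2e-8 && abs(best$a - best$b) > 2 * noiseScale
  list(a = best$a, b = best$b, rate = best$cr, rss = best$rss,
       converged = conv)
}

#' Fit a single-exponential recovery to a normalized FRAP curve
#'
#' Least-squares fit of \code{f(t) = b + (a - b) exp(-c t)} where \code{a}
#' is the intercept, \code{b} the plateau at infinity and \code{c} the rate
#' constant. On a full-scale normalized curve the mobile fraction is the
#' fitted plateau \code{b}; the half-time is \code{log(2)/c}. Multi-start
#' initialization; the convergence flag is honest — a fit driven to the
#' rate lower bound (no resolvable recovery, e.g. pure noise around a
#' constant) reports \code{converged = FALSE} with NA parameters.
#'
#' @param x either a \linkS4class{RoiTrace} (normalized internally via
#'   \code{\link{normalizeFrap}}) or a data.frame with columns \code{time}
#'   and \code{F} (>= 10 post-bleach points).
#' @param fullScale passed to \code{\link{normalizeFrap}} when \code{x} is
#'   a trace.
#' @return A \linkS4class{FrapFit} (kind "recovery").
#' @examples
#' tr <- simulateFrapTrace(frapSimParams(0.95, 34), seed = 1)
#' fitFrap(tr)
#' @export
fitFrap <- function(x, fullScale = TRUE) {
  if (is(x, "RoiTrace")) x <- normalizeFrap(x, fullScale)
  stopifnot(is.data.frame(x), all(c("time", "F") %in% names(x)))
  if (nrow(x) < 10L) stop("need >= 10 post-bleach points")
  f <- .fitExp(x$time, x$F)
  if (!f$converged)
    return(new("FrapFit", a = NA_real_, b = NA_real_, rate = NA_real_,
               mobileFraction = NA_real_, tHalf = NA_real_, rss = f$rss,
               converged = FALSE, nPoints = nrow(x), kind = "recovery"))
  new("FrapFit", a = f$a, b = f$b, rate = f$rate, mobileFraction = f$b,
      tHalf = log(2) / f$rate, rss = f$rss, converged = TRUE,
      nPoints = nrow(x), kind = "recovery")
}

#' Fit a single-exponential decay to a FLIP trace
#'
#' The monitored (non-bleached) region of a FLIP experiment, ROI2, is
#' background subtracted (time-averaged ROI3), normalized to its pre-bleach
#' mean, and fitted post-bleach with a one-component exponential decay
#' toward a free floor: \code{f(t) = b + (a - b) exp(-c t)}. The half-time
#' of fluorescence loss is \code{log(2)/c}.
#'
#' @param trace a \linkS4class{RoiTrace}; the monitored series is
#'   \code{roiControl}.
#' @return A \linkS4class{FrapFit} (kind "decay"; \code{mobileFraction} is
#'   NA).
#' @examples
#' tr <- simulateFlipTrace(tHalf = 60, noiseSd = 0, seed = 1)
#' halfTime(fitFlip(tr))
#' @export
fitFlip <- function(trace) {
  stopifnot(is(trace, "RoiTrace"))
  npre <- trace@nPrebleach
  bg <- mean(trace@roiBackground)
  v <- trace@roiControl - bg
  pre <- mean(v[seq_len(npre)])
  if (pre <= 0) stop("monitored ROI has non-positive pre-bleach mean")
  v <- v / pre
  post <- (npre + 1L):length(v)
  tt <- trace@time[post]
  yy <- v[post]
  if (length(yy) < 10L) stop("need >= 10 post-bleach points")
  f <- .fitExp(tt, yy)
  if (!f$converged)
    return(new("FrapFit", a = NA_real_, b = NA_real_, rate = NA_real_,
               mobileFraction = NA_real_, tHalf = NA_real_, rss = f$rss,
               converged = FALSE, nPoints = length(yy), kind = "decay"))
  new("FrapFit", a = f$a, b = f$b, rate = f$rate,
      mobileFraction = NA_real_, tHalf = log(2) / f$rate, rss = f$rss,
      converged = TRUE, nPoints = length(yy), kind = "decay")
}
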