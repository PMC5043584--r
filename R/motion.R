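# Per-trajectory kinematics: speed, displacement-moment scaling exponents
# (the moment scaling spectrum), its slope (SMSS) and motion-class
# assignment. The SMSS slope beta characterizes the diffusion mode: 0 for a
# static object, 0.5 for free Brownian diffusion, 1 for ballistic motion;
# intermediate values indicate restricted (confined) or directed Brownian
# motion.

.defaultOrders <- seq(0, 6, by = 0.5)

.defaultThresholds <- c(static = 0.05, restricted = 0.45, brownian = 0.55,
                        directed = 0.9)

#' Mean step speed of a trajectory
#'
#' Mean frame-to-frame displacement magnitude divided by the elapsed time,
#' in um/s. For gapped tracks each displacement is divided by its own time
#' gap before averaging. The net speed (net displacement over total time)
#' is available via \code{netSpeed}.
#'
#' @param traj a \linkS4class{Trajectory} with >= 2 points and positive
#'   calibration.
#' @return speed in um/s.
#' @examples
#' tr <- simulateTrajectory(motionModel("ballistic", v = 2), 100, 0.05,
#'                          seed = 1)
#' computeSpeed(tr)  # 2 um/s
#' @export
computeSpeed <- function(traj) {
  stopifnot(is(traj, "Trajectory"))
  if (length(traj) < 2L) stop("trajectory needs >= 2 points")
  if (traj@pixelSize <= 0 || traj@frameInterval <= 0)
    stop("trajectory calibration missing: speed would be px/frame")
  p <- positions(traj, "um")
  d <- sqrt(diff(p[, 1L])^2 + diff(p[, 2L])^2)
  dtv <- diff(traj@frames) * traj@frameInterval
  mean(d / dtv)
}

#' @rdname computeSpeed
#' @export
netSpeed <- function(traj) {
  stopifnot(is(traj, "Trajectory"))
  if (length(traj) < 2L) stop("trajectory needs >= 2 points")
  p <- positions(traj, "um")
  n <- nrow(p)
  tt <- (traj@frames[n] - traj@frames[1L]) * traj@frameInterval
  sqrt(sum((p[n, ] - p[1L, ])^2)) / tt
}

#' Displacement-moment scaling exponents of a trajectory
#'
#' For each moment order \eqn{\nu} the time-averaged displacement moment
#' \eqn{\mu_\nu(\delta t) = \langle |r(t+\delta t) - r(t)|^\nu \rangle_t}
#' is computed for lags \eqn{\delta t} from 1 frame up to
#' \code{maxLagFraction} of the trajectory length (at least
#' \code{minLags}), and the scaling exponent \eqn{\gamma_\nu} is the slope
#' of the least-squares fit of \eqn{\log \mu_\nu} versus
#' \eqn{\log \delta t}. Lags with \eqn{\mu_\nu = 0} are excluded;
#' \eqn{\gamma_0 = 0} by construction.
#'
#' Lags are restricted to a small fraction of the track because sample
#' moments of high order collapse at lags where few effectively independent
#' displacement pairs remain, which biases the exponents (and hence the
#' SMSS) downward.
#'
#' @param traj a \linkS4class{Trajectory}; gapped tracks are not supported
#'   here (MSS needs a uniform frame grid).
#' @param orders moment orders \eqn{\nu}.
#' @param maxLagFraction maximum lag as a fraction of the track length.
#' @param minLags lower bound on the number of lags fitted.
#' @param minPoints minimum trajectory length (default 20).
#' @return list with \code{orders}, \code{gamma} (named vector, NA when
#'   undefined), \code{lags}, \code{mu} (lags x orders matrix) and
#'   \code{ok} (FALSE when fewer than 3 usable lags made the MSS
#'   undefined).
#' @examples
#' tr <- simulateTrajectory(motionModel("brownian", D = 0.1), 200, 0.05,
#'                          seed = 1)
#' round(computeMSS(tr)$gamma[["2"]], 2)  # ~1: MSD linear in lag
#' @export
computeMSS <- function(traj, orders = .defaultOrders, maxLagFraction = 0.05,
                       minLags = 5L, minPoints = 20L) {
  stopifnot(is(traj, "Trajectory"))
  n <- length(traj)
  if (n < minPoints)
    stop("trajectory too short for MSS (", n, " < ", minPoints, " points)")
  if (any(diff(traj@frames) != 1L))
    stop("MSS requires a gap-free trajectory")
  orders <- sort(unique(as.numeric(orders)))
  p <- positions(traj, "um")
  maxLag <- min(n - 2L, max(as.integer(minLags),
                            floor(maxLagFraction * n)))
  lags <- seq_len(maxLag)
  mu <- matrix(NA_real_, length(lags), length(orders),
               dimnames = list(NULL, orders))
  for (i in seq_along(lags)) {
    d <- lags[i]
    dx <- p[(1L + d):n, 1L] - p[1L:(n - d), 1L]
    dy <- p[(1L + d):n, 2L] - p[1L:(n - d), 2L]
    r2 <- dx * dx + dy * dy
    if (all(r2 == 0)) { mu[i, ] <- ifelse(orders == 0, 1, 0); next }
    ld <- 0.5 * log(r2)
    ld[!is.finite(ld)] <- -745  # |dr| = 0 contributes exp(nu * -745) ~ 0
    mu[i, ] <- colMeans(exp(outer(ld, orders)))
  }
  lx <- log(lags)
  gamma <- vapply(seq_along(orders), function(k) {
    m <- mu[, k]
    use <- is.finite(m) & m > 0
    if (sum(use) < 3L || var(lx[use]) == 0) return(NA_real_)
    lsSlope(lx[use], log(m[use]))
  }, numeric(1))
  names(gamma) <- orders
  if (0 %in% orders) gamma[orders == 0] <- 0
  ok <- sum(!is.na(gamma)) >= 3L
  list(orders = orders, gamma = gamma, lags = lags, mu = mu, ok = ok)
}

#' Slope of the moment scaling spectrum (SMSS)
#'
#' Least-squares slope (free intercept) of the scaling exponents
#' \eqn{\gamma_\nu} against the moment orders \eqn{\nu}. The raw slope is
#' preserved; the reported value is clamped to [0, 1], the physical range
#' between static and ballistic motion.
#'
#' @param mss result of \code{\link{computeMSS}}, or a named numeric vector
#'   of gamma values (names = orders).
#' @return list with \code{beta} (clamped), \code{betaRaw} and \code{ok}.
#' @examples
#' computeSMSS(c("0" = 0, "1" = 0.5, "2" = 1))$beta  # 0.5, Brownian
#' @export
computeSMSS <- function(mss) {
  if (is.list(mss)) {
    gamma <- mss$gamma
    orders <- mss$orders
  } else {
    gamma <- mss
    orders <- as.numeric(names(gamma))
  }
  use <- is.finite(gamma)
  if (sum(use) < 3L || var(orders[use]) == 0)
    return(list(beta = NA_real_, betaRaw = NA_real_, ok = FALSE))
  raw <- lsSlope(orders[use], gamma[use])
  list(beta = min(max(raw, 0), 1), betaRaw = raw, ok = TRUE)
}

#' Classify motion from the SMSS slope
#'
#' Default bins are symmetric around the analytic anchors 0 (static), 0.5
#' (Brownian) and 1 (ballistic): static \eqn{\beta < 0.05}; restricted
#' Brownian \eqn{0.05 \le \beta < 0.45}; Brownian
#' \eqn{0.45 \le \beta \le 0.55}; directed \eqn{0.55 < \beta < 0.9};
#' ballistic \eqn{\beta \ge 0.9}.
#'
#' @param beta SMSS slope (vectorized).
#' @param thresholds named increasing vector with elements \code{static},
#'   \code{restricted}, \code{brownian}, \code{directed}: the upper edges
#'   of the first four classes.
#' @return factor with levels \code{static, restricted_brownian, brownian,
#'   directed, ballistic} (NA for undefined beta).
#' @examples
#' classifyMotion(c(0, 0.12, 0.5, 0.7, 1))
#' @export
classifyMotion <- function(beta, thresholds = .defaultThresholds) {
  need <- c("static", "restricted", "brownian", "directed")
  if (!all(need %in% names(thresholds)))
    stop("'thresholds' must name: ", paste(need, collapse = ", "))
  th <- as.numeric(thresholds[need])
  if (any(diff(th) <= 0) || any(!is.finite(th)))
    stop("'thresholds' must be strictly increasing and finite")
  lev <- c("static", "restricted_brownian", "brownian", "directed",
           "ballistic")
  cls <- ifelse(beta < th[1L], 1L,
         ifelse(beta < th[2L], 2L,
         ifelse(beta <= th[3L], 3L,
         ifelse(beta < th[4L], 4L, 5L))))
  factor(lev[cls], levels = lev)
}

#' Full motion analysis of a set of trajectories
#'
#' Computes per-track speed, MSS exponents, SMSS slope and motion class.
#' Tracks shorter than \code{minPoints} or with frame gaps are flagged
#' (\code{mss_ok = FALSE}, NA results), never fabricated.
#'
#' @param tracks list of \linkS4class{Trajectory}.
#' @param orders,maxLagFraction,minLags,minPoints passed to
#'   \code{\link{computeMSS}}.
#' @param thresholds passed to \code{\link{classifyMotion}}.
#' @return data.frame with one row per track: \code{track_id, n_points,
#'   speed_um_s, net_speed_um_s, smss, smss_raw, motion_class, mss_ok} and
#'   one \code{gamma_<nu>} column per order.
#' @export
analyzeMotion <- function(tracks, orders = .defaultOrders,
                          maxLagFraction = 0.05, minLags = 5L,
                          minPoints = 20L,
                          thresholds = .defaultThresholds) {
  rows <- lapply(tracks, function(tr) {
    n <- length(tr)
    sp <- if (n >= 2L) computeSpeed(tr) else NA_real_
    nsp <- if (n >= 2L) netSpeed(tr) else NA_real_
    gamma <- setNames(rep(NA_real_, length(orders)), orders)
    beta <- betaRaw <- NA_real_
    ok <- FALSE
    if (n >= minPoints && all(diff(tr@frames) == 1L)) {
      mss <- computeMSS(tr, orders, maxLagFraction, minLags, minPoints)
      gamma <- mss$gamma
      if (mss$ok) {
        sm <- computeSMSS(mss)
        beta <- sm$beta; betaRaw <- sm$betaRaw; ok <- sm$ok
      }
    }
    out <- data.frame(track_id = tr@trackId, n_points = n, speed_um_s = sp,
                      net_speed_um_s = nsp, smss = beta, smss_raw = betaRaw,
                      mss_ok = ok)
    gm <- as.data.frame(as.list(gamma))
    names(gm) <- paste0("gamma_", sub("\\.", "_", format(orders)))
    cbind(out, gm)
  })
  if (!length(rows)) {
    res <- data.frame(track_id = integer(0), n_points = integer(0),
                      speed_um_s = numeric(0), net_speed_um_s = numeric(0),
                      smss = numeric(0), smss_raw = numeric(0),
                      mss_ok = logical(0))
    for (nu in orders)
      res[[paste0("gamma_", sub("\\.", "_", format(nu)))]] <- numeric(0)
  } else {
    res <- do.call(rbind, rows)
  }
  res$motion_class <- classifyMotion(res$smss, thresholds)
  rownames(res) <- NULL
  res
}

#' Condition-level summary of a motion analysis
#'
#' @param x data.frame from \code{\link{analyzeMotion}}.
#' @return list with mean/sd of speed and SMSS (over tracks with a defined
#'   MSS) and the motion-class fractions.
#' @export
summarizeMotion <- function(x) {
  ok <- x$mss_ok %in% TRUE
  list(nTracks = nrow(x), nAnalyzed = sum(ok),
       meanSpeed = if (nrow(x)) mean(x$speed_um_s, na.rm = TRUE)
                   else NA_real_,
       sdSpeed = sd(x$speed_um_s, na.rm = TRUE),
       meanSMSS = mean(x$smss[ok]), sdSMSS = sd(x$smss[ok]),
       classFractions = if (any(ok))
         table(x$motion_class[ok]) / sum(ok) else table(x$motion_class[0]))
}
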