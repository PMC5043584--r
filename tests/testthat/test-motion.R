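# Speed, moment-scaling-spectrum exponents, SMSS slope and motion
# classification against analytic limits.

test_that("speed follows its closed forms", {
  st <- simulateTrajectory(motionModel("static"), 50, 0.05, seed = 1)
  expect_equal(computeSpeed(st), 0)

  bl <- simulateTrajectory(motionModel("ballistic", v = 2), 50, 0.05,
                           seed = 1)
  expect_equal(computeSpeed(bl), 2, tolerance = 1e-12)
  expect_equal(netSpeed(bl), 2, tolerance = 1e-12)

  # 2-D Brownian mean step length is sqrt(pi * D * dt)
  D <- 0.1; dt <- 0.05
  sp <- vapply(1:50, function(s)
    computeSpeed(simulateTrajectory(motionModel("brownian", D = D), 1000,
                                    dt, seed = 300 + s)), numeric(1))
  expect_equal(mean(sp), sqrt(pi * D * dt) / dt, tolerance = 0.03)
})

test_that("missing calibration raises instead of returning px/frame", {
  tr <- simulateTrajectory(motionModel("static"), 30, 0.05, seed = 2)
  expect_error(Trajectory(1:2, c(0, 1), c(0, 0), pixelSize = -1,
                          frameInterval = 0.05), "calibration")
  expect_error(computeSpeed(Trajectory(1L, 0, 0, 0.1, 0.05)), ">= 2")
  expect_silent(computeSpeed(tr))
})

test_that("MSS exponents hit the analytic limits", {
  bl <- simulateTrajectory(motionModel("ballistic", v = 1), 200, 0.05,
                           seed = 3)
  g <- computeMSS(bl)$gamma
  expect_equal(unname(g[["1"]]), 1, tolerance = 1e-6)
  expect_equal(unname(g[["2"]]), 2, tolerance = 1e-6)
  expect_equal(unname(g[["0"]]), 0)

  st <- simulateTrajectory(motionModel("static", locNoise = 0.01), 500,
                           0.05, seed = 4)
  gs <- computeMSS(st)$gamma
  expect_true(all(abs(gs[names(gs) != "0"]) < 0.15))

  # Brownian ensemble: gamma_2 (the MSD exponent) ~ 1
  g2 <- vapply(1:200, function(s) {
    tr <- simulateTrajectory(motionModel("brownian", D = 0.1), 500, 0.05,
                             seed = 400 + s)
    computeMSS(tr)$gamma[["2"]]
  }, numeric(1))
  expect_equal(mean(g2), 1, tolerance = 0.03)

  expect_error(computeMSS(simulateTrajectory(motionModel("static"), 10,
                                             0.05, seed = 1)),
               "too short")
})

test_that("SMSS slope reproduces its defining limits", {
  orders <- seq(0, 6, 0.5)
  expect_equal(computeSMSS(setNames(orders, orders))$beta, 1)
  expect_equal(computeSMSS(setNames(orders / 2, orders))$beta, 0.5)
  expect_equal(computeSMSS(setNames(orders * 0, orders))$beta, 0)
  # raw value preserved when outside [0, 1]
  sm <- computeSMSS(setNames(orders * 1.2, orders))
  expect_equal(sm$beta, 1)
  expect_equal(sm$betaRaw, 1.2, tolerance = 1e-12)
  expect_false(computeSMSS(c("1" = NA_real_, "2" = NA_real_))$ok)
})

test_that("confined motion lands strictly between static and Brownian", {
  betas <- vapply(1:100, function(s) {
    tr <- simulateTrajectory(motionModel("confined", D = 0.1,
                                         corralRadius = 0.2), 1000, 0.05,
                             seed = 500 + s)
    computeSMSS(computeMSS(tr))$beta
  }, numeric(1))
  expect_gt(mean(betas), 0.05)
  expect_lt(mean(betas), 0.45)
})

test_that("classification bins match the documented defaults", {
  expect_equal(as.character(classifyMotion(c(0, 0.12, 0.5, 0.7, 0.95))),
               c("static", "restricted_brownian", "brownian", "directed",
                 "ballistic"))
  expect_equal(as.character(classifyMotion(0.45)), "brownian")
  expect_equal(as.character(classifyMotion(0.05)), "restricted_brownian")
  expect_error(classifyMotion(0.3, c(static = 0.5, restricted = 0.2,
                                     brownian = 0.6, directed = 0.9)),
               "increasing")
})

test_that("gamma and SMSS are scale-equivariant and time-reversal
           invariant", {
  tr <- simulateTrajectory(motionModel("brownian", D = 0.1), 300, 0.05,
                           seed = 6)
  mss <- computeMSS(tr)
  sm <- computeSMSS(mss)

  scaled <- Trajectory(tr@frames, tr@x * 3, tr@y * 3, tr@pixelSize,
                       tr@frameInterval)
  mssS <- computeMSS(scaled)
  expect_equal(mssS$gamma, mss$gamma, tolerance = 1e-10)
  expect_equal(computeSpeed(scaled), 3 * computeSpeed(tr),
               tolerance = 1e-10)

  rev <- Trajectory(tr@frames, rev(tr@x), rev(tr@y), tr@pixelSize,
                    tr@frameInterval)
  expect_equal(computeMSS(rev)$mu, mss$mu, tolerance = 1e-12)
  expect_equal(computeSMSS(computeMSS(rev))$beta, sm$beta,
               tolerance = 1e-12)
})

test_that("mean SMSS orders confined < brownian < directed at matched D", {
  beta <- function(kind, ...) mean(vapply(1:40, function(s)
    computeSMSS(computeMSS(simulateTrajectory(motionModel(kind, ...), 500,
                                              0.05, seed = 600 + s)))$beta,
    numeric(1)))
  bConf <- beta("confined", D = 0.1, corralRadius = 0.2)
  bBrown <- beta("brownian", D = 0.1)
  bDir <- beta("directed", D = 0.1, v = 1.5)
  expect_lt(bConf, bBrown)
  expect_lt(bBrown, bDir)
})

test_that("analyzeMotion flags short or gapped tracks honestly", {
  short <- Trajectory(1:5, 1:5, 1:5, 0.1, 0.05)
  gapped <- Trajectory(c(1:20, 22:41), rnorm(40), rnorm(40), 0.1, 0.05)
  good <- simulateTrajectory(motionModel("brownian", D = 0.1), 100, 0.05,
                             seed = 7)
  res <- analyzeMotion(list(short, gapped, good))
  expect_equal(res$mss_ok, c(FALSE, FALSE, TRUE))
  expect_true(is.na(res$smss[1]) && is.na(res$smss[2]))
  expect_false(is.na(res$smss[3]))
  sm <- summarizeMotion(res)
  expect_equal(sm$nAnalyzed, 1L)
})
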