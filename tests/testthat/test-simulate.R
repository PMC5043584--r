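# Synthetic trajectory, movie, photobleach-trace and channel-pair
# generators against analytic ground truth.

test_that("simulation is deterministic in the seed and rejects bad input", {
  m <- motionModel("brownian", D = 0.1)
  a <- simulateTrajectory(m, 50, 0.05, seed = 7)
  b <- simulateTrajectory(m, 50, 0.05, seed = 7)
  expect_identical(positions(a), positions(b))
  expect_false(isTRUE(all.equal(positions(a),
                                positions(simulateTrajectory(m, 50, 0.05,
                                                             seed = 8)))))
  expect_error(simulateTrajectory(m, 1, 0.05), "nSteps")
  expect_error(simulateTrajectory(m, 10, 0), "dt")
  expect_error(motionModel("ballistic", v = 0), "ballistic")
  expect_error(motionModel("static", D = 1), "static")
  expect_error(motionModel("confined", D = 0.1), "confined")
})

test_that("static and ballistic trajectories follow their closed forms", {
  st <- simulateTrajectory(motionModel("static"), 100, 0.05, seed = 1)
  expect_true(all(positions(st) == positions(st)[rep(1, 100), ]))

  bl <- simulateTrajectory(motionModel("ballistic", v = 2), 100, 0.05,
                           seed = 1)
  p <- positions(bl, "um")
  steps <- sqrt(diff(p[, 1])^2 + diff(p[, 2])^2)
  expect_equal(steps, rep(0.1, 99), tolerance = 1e-12)
})

test_that("Brownian ensemble MSD matches 4*D*dt per lag within 5%", {
  D <- 0.1; dt <- 0.05
  posList <- lapply(1:100, function(s)
    positions(simulateTrajectory(motionModel("brownian", D = D), 1000, dt,
                                 seed = 100 + s), "um"))
  lags <- c(1, 2, 5, 10)
  msd <- oracleMSD(posList, lags)
  expect_equal(msd / (lags * dt), rep(4 * D, length(lags)),
               tolerance = 0.05)
})

test_that("MSD regression recovers slope 4D and the localization-noise
           intercept", {
  # with i.i.d. per-axis noise of s.d. sigma the 2-D MSD gains a constant
  # 4*sigma^2 (two axes, two independent frames)
  D <- 0.05; dt <- 0.05; sigma <- 0.02
  m <- motionModel("brownian", D = D, locNoise = sigma)
  posList <- lapply(1:100, function(s)
    positions(simulateTrajectory(m, 1000, dt, seed = 200 + s), "um"))
  lags <- 1:10
  msd <- oracleMSD(posList, lags)
  fit <- lm(msd ~ I(lags * dt))
  expect_equal(unname(coef(fit)[2]), 4 * D, tolerance = 0.05)
  expect_equal(unname(coef(fit)[1]), 4 * sigma^2, tolerance = 0.25)
})

test_that("confined trajectories never leave the corral before noise", {
  m <- motionModel("confined", D = 0.1, corralRadius = 0.2)
  for (s in 1:20) {
    p <- positions(simulateTrajectory(m, 500, 0.05, seed = s), "um")
    r <- sqrt((p[, 1] - p[1, 1])^2 + (p[, 2] - p[1, 2])^2)
    expect_lte(max(r), 0.2 + 1e-12)
  }
})

test_that("rendered movies honour the scene contract", {
  scFlat <- sceneSpec(nSpeckles = 0L, imageSize = c(64L, 64L),
                      nFrames = 3L, noise = "none")
  mv <- renderSpeckleMovie(scFlat, motionModel("static"), seed = 1)
  expect_true(all(mv$stack@frames == scFlat@backgroundLevel))

  sc <- sceneSpec(nSpeckles = 20L, imageSize = c(128L, 128L), nFrames = 4L,
                  noise = "none", minSeparation = 10)
  mv2 <- renderSpeckleMovie(sc, motionModel("static"), seed = 2)
  expect_identical(getFrame(mv2$stack, 1), getFrame(mv2$stack, 4))
  expect_length(mv2$truth, 20L)
  # all planted centres inside the nucleus ellipse
  for (tr in mv2$truth)
    expect_true(all(speckleQuant:::insideEllipse(tr@x, tr@y,
                                                 sc@nucleusCentre,
                                                 sc@nucleusAxes)))
  expect_error(renderSpeckleMovie(sceneSpec(speckleSigma = -1),
                                  motionModel("static")), "speckleSigma")
})

test_that("noiseless FRAP traces encode the planted recovery exactly", {
  # full recovery: F reaches exactly 0.5 at t = tHalf
  p <- frapSimParams(mobileFraction = 1, tHalf = 1, noiseSd = 0,
                     acqBleachRate = 0, frameInterval = 0.25)
  f <- normalizeFrap(simulateFrapTrace(p, nPostbleach = 40))
  expect_equal(f$F[f$time == 1], 0.5, tolerance = 1e-12)

  # immobile pool: post-bleach trace flat at the bleach floor
  p0 <- frapSimParams(mobileFraction = 0, tHalf = 10, noiseSd = 0)
  f0 <- normalizeFrap(simulateFrapTrace(p0, nPostbleach = 50))
  expect_true(all(abs(f0$F) < 1e-12))

  # noiseless normalized plateau equals the mobile fraction
  for (mf in c(0.25, 0.6, 0.95)) {
    pm <- frapSimParams(mobileFraction = mf, tHalf = 2, noiseSd = 0)
    fm <- normalizeFrap(simulateFrapTrace(pm, nPostbleach = 200))
    expect_equal(tail(fm$F, 1), mf, tolerance = 1e-6)
  }
  expect_error(frapSimParams(mobileFraction = 1.4), "mobileFraction")
  expect_error(frapSimParams(tHalf = -1), "tHalf")
})

test_that("co-localization pairs plant the requested overlap", {
  sc <- sceneSpec(imageSize = c(96L, 96L), noise = "none")
  pr1 <- simulateColocPair(30, 1, sc, seed = 3)
  expect_identical(pr1$ch1, pr1$ch2)  # identical rendering at f = 1

  pr0 <- simulateColocPair(30, 0, sceneSpec(imageSize = c(128L, 128L),
                                            noise = "none",
                                            minSeparation = 6), seed = 4)
  expect_equal(nrow(pr0$centres1), 30L)
  # no shared centres at f = 0
  expect_false(any(duplicated(rbind(pr0$centres1, pr0$centres2))))
  expect_error(simulateColocPair(10, 1.5, sc), "overlapFraction")
})
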