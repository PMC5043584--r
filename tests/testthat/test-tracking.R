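# Particle detection and frame-to-frame linking against planted truth.

test_that("a flat frame yields no detections", {
  expect_equal(nrow(detectParticles(matrix(5, 64, 64))), 0L)
})

test_that("a single planted Gaussian is located to sub-pixel accuracy", {
  img <- matrix(10, 64, 64)
  img <- speckleQuant:::addGaussianSpot(img, 30.3, 20.7, 200, 2)
  det <- detectParticles(img)
  expect_equal(nrow(det), 1L)
  expect_lt(abs(det$x - 30.3), 0.1)
  expect_lt(abs(det$y - 20.7), 0.1)
})

test_that("detection recovers planted spots at SNR 10 with no spurious
           hits", {
  sc <- plantedScene(nSpots = 50L, imageSize = c(512L, 512L),
                     noiseSd = 200 / (10 * 210), minSeparation = 24)
  mv <- renderSpeckleMovie(sc, motionModel("static"), seed = 21)
  det <- detectParticles(getFrame(mv$stack, 1))
  truth <- cbind(vapply(mv$truth, function(t) t@x[1], numeric(1)),
                 vapply(mv$truth, function(t) t@y[1], numeric(1)))
  m <- matchToTruth(det, truth, tol = 0.5)
  expect_gte(m$matched, 49L)
  expect_equal(m$spurious, 0L)
})

test_that("a drifting particle is linked into a single exact track", {
  det <- lapply(1:100, function(f)
    data.frame(x = 10 + (f - 1) * 1.0, y = 20 + (f - 1) * 0.5))
  tracks <- linkParticles(det, maxDisplacementPx = 5)
  expect_length(tracks, 1L)
  tr <- tracks[[1]]
  expect_identical(tr@frames, 1:100)
  expect_equal(tr@x, 10 + (0:99) * 1.0)
  expect_equal(tr@y, 20 + (0:99) * 0.5)
})

test_that("two distant static particles never swap identity", {
  det <- lapply(1:50, function(f) data.frame(x = c(10, 30), y = c(10, 10)))
  tracks <- linkParticles(det, maxDisplacementPx = 5)
  expect_length(tracks, 2L)
  for (tr in tracks) {
    expect_length(tr, 50L)
    expect_equal(length(unique(tr@x)), 1L)
  }
})

test_that("a jump beyond the gate terminates the track and starts a new
           one", {
  det <- lapply(1:20, function(f)
    data.frame(x = if (f <= 10) 10 else 20, y = 5))
  tracks <- linkParticles(det, maxDisplacementPx = 5)
  expect_length(tracks, 2L)
  expect_identical(tracks[[1]]@frames, 1:10)
  expect_identical(tracks[[2]]@frames, 11:20)
})

test_that("linking is invariant to detection order within a frame", {
  set.seed(22)
  base <- lapply(1:20, function(f) {
    data.frame(x = c(10, 25, 40) + rnorm(3, sd = 0.5),
               y = c(10, 12, 14) + rnorm(3, sd = 0.5))
  })
  shuffled <- lapply(base, function(d) d[sample(nrow(d)), , drop = FALSE])
  t1 <- linkParticles(base, maxDisplacementPx = 5)
  t2 <- linkParticles(shuffled, maxDisplacementPx = 5)
  expect_equal(length(t1), length(t2))
  key <- function(tr) paste(round(tr@x, 9), round(tr@y, 9), collapse = ";")
  expect_setequal(vapply(t1, key, character(1)),
                  vapply(t2, key, character(1)))
})

test_that("track count never exceeds detections and each detection is used
           at most once", {
  set.seed(23)
  det <- lapply(1:15, function(f)
    data.frame(x = runif(5, 0, 50), y = runif(5, 0, 50)))
  tracks <- linkParticles(det, maxDisplacementPx = 5)
  nDet <- sum(vapply(det, nrow, integer(1)))
  nUsed <- sum(vapply(tracks, length, integer(1)))
  expect_lte(length(tracks), nDet)
  expect_equal(nUsed, nDet)  # every detection belongs to exactly one track
})

test_that("optimal assignment beats greedy on a crossing configuration", {
  # two particles approach: optimal matching minimizes total squared
  # displacement; both methods must remain deterministic
  det <- list(data.frame(x = c(0, 4), y = c(0, 0)),
              data.frame(x = c(1, 3), y = c(0, 0)))
  opt <- linkParticles(det, maxDisplacementPx = 5, method = "optimal")
  gre <- linkParticles(det, maxDisplacementPx = 5, method = "greedy")
  cost <- function(tracks) sum(vapply(tracks, function(tr)
    if (length(tr) == 2) (diff(tr@x))^2 + (diff(tr@y))^2 else 0,
    numeric(1)))
  expect_lte(cost(opt), cost(gre))
  expect_length(opt, 2L)
})

test_that("end-to-end detection+linking recovers a moving planted spot", {
  sc <- sceneSpec(nSpeckles = 1L, imageSize = c(64L, 64L), nFrames = 30L,
                  noise = "none")
  mv <- renderSpeckleMovie(sc, motionModel("brownian", D = 0.05),
                           seed = 24)
  tracks <- trackSpeckles(mv$stack)
  expect_length(tracks, 1L)
  expect_length(tracks[[1]], 30L)
  truth <- mv$truth[[1]]
  expect_lt(max(abs(tracks[[1]]@x - truth@x)), 0.5)
  expect_lt(max(abs(tracks[[1]]@y - truth@y)), 0.5)
})
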