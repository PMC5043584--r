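# Speckle segmentation: Li threshold, watershed splitting, size filter and
# per-frame morphometry against planted ground truth.

test_that("Li threshold separates a bimodal population and handles
           degenerate input", {
  x <- c(rnorm(500, 10, 1), rnorm(100, 50, 2))
  th <- liThreshold(x)
  expect_gt(th, 15)
  expect_lt(th, 45)
  expect_true(is.na(liThreshold(rep(3, 100))))
})

test_that("a flat or constant frame yields zero speckles, not an error", {
  st <- ImageStack(matrix(7, 64, 64), pixelSize = 0.1,
                   frameInterval = 0.05)
  ss <- segmentSpeckles(st)
  expect_equal(nrow(speckles(ss)), 0L)
  sm <- summarizeSpeckles(ss)
  expect_equal(sm$meanCountPerFrame, 0)
  expect_true(is.na(sm$meanAreaUm2))
  expect_true(is.na(sm$fractionNucleusArea))
})

test_that("well-separated planted spots are all recovered with accurate
           centroids", {
  sc <- plantedScene(nSpots = 20L, noiseSd = 0.05, minSeparation = 20)
  mv <- renderSpeckleMovie(sc, motionModel("static"), seed = 11)
  ss <- segmentSpeckles(mv$stack)
  sp <- speckles(ss)
  expect_equal(nrow(sp), 20L)
  truth <- cbind(vapply(mv$truth, function(t) t@x[1], numeric(1)),
                 vapply(mv$truth, function(t) t@y[1], numeric(1)))
  m <- matchToTruth(data.frame(x = sp$x_px, y = sp$y_px), truth, tol = 1)
  expect_equal(m$matched, 20L)
  expect_equal(m$spurious, 0L)
})

test_that("watershed splits touching blobs; disabling it merges them", {
  img <- matrix(0, 64, 64)
  sigma <- 2
  img <- speckleQuant:::addGaussianSpot(img, 28, 32, 100, sigma)
  img <- speckleQuant:::addGaussianSpot(img, 28 + 3 * sigma, 32, 100, sigma)
  st <- ImageStack(img, 0.1, 0.05)
  nWith <- nrow(speckles(segmentSpeckles(st, minAreaPx = 5)))
  nWithout <- nrow(speckles(segmentSpeckles(st, minAreaPx = 5,
                                            useWatershed = FALSE)))
  expect_equal(nWith, 2L)
  expect_equal(nWithout, 1L)
})

test_that("hole filling is idempotent on the labelled mask", {
  mask <- matrix(0L, 32, 32)
  mask[8:24, 8:24] <- 1L
  mask[14:18, 14:18] <- 0L  # a hole
  once <- as.matrix(EBImage::fillHull(EBImage::Image(mask)))
  twice <- as.matrix(EBImage::fillHull(EBImage::Image(once)))
  expect_identical(once, twice)
  expect_true(all(once[14:18, 14:18] == 1))
})

test_that("raising the minimum area never increases the speckle count", {
  sc <- plantedScene(nSpots = 15L, noiseSd = 0.05, minSeparation = 18)
  mv <- renderSpeckleMovie(sc, motionModel("static"), seed = 12)
  counts <- vapply(c(1L, 5L, 10L, 20L, 50L), function(a)
    nrow(speckles(segmentSpeckles(mv$stack, minAreaPx = a))), integer(1))
  expect_true(all(diff(counts) <= 0L))
})

test_that("planted-count recovery holds across SNR levels", {
  # peak SNR = amplitude / (noiseSd * (background + amplitude))
  snrToNoise <- function(snr, A = 200, bg = 10) A / (snr * (A + bg))
  for (snr in c(10, 20)) {
    sc <- plantedScene(nSpots = 20L, noiseSd = snrToNoise(snr),
                       minSeparation = 20)
    mv <- renderSpeckleMovie(sc, motionModel("static"), seed = 40 + snr)
    expect_equal(nrow(speckles(segmentSpeckles(mv$stack))), 20L)
  }
  # SNR 5: allow a one-spot miss but no gross failure
  sc5 <- plantedScene(nSpots = 20L, noiseSd = snrToNoise(5),
                      minSeparation = 20)
  mv5 <- renderSpeckleMovie(sc5, motionModel("static"), seed = 45)
  expect_gte(nrow(speckles(segmentSpeckles(mv5$stack))), 19L)
})

test_that("summaries do the stated arithmetic", {
  # one 10-px speckle at 0.1 um/px -> 0.1 um^2
  img <- matrix(0, 64, 64)
  img[30:34, 31:32] <- 100  # 5x2 = 10 px block
  ss <- segmentSpeckles(ImageStack(img, 0.1, 0.05), bgRadius = 3L)
  sp <- speckles(ss)
  expect_equal(nrow(sp), 1L)
  expect_equal(sp$area_px, 10L)
  expect_equal(sp$area_um2, 0.1, tolerance = 1e-12)

  # planted area fraction ~3% of the nucleus from hard discs
  nuc <- speckleQuant:::ellipseMask(c(256L, 256L), c(128, 128), c(100, 80))
  nucArea <- sum(nuc)
  img2 <- matrix(5, 256, 256)
  rDisc <- 4
  nDisc <- round(0.03 * nucArea / (pi * rDisc^2))
  set.seed(13)
  ctr <- speckleQuant:::samplePointsInEllipse(nDisc, c(128, 128),
                                              c(90, 70),
                                              minSeparation = 14)
  xs <- matrix(rep(0:255, each = 256), 256, 256)
  ys <- matrix(rep(0:255, 256), 256, 256)
  for (i in seq_len(nDisc)) {
    d2 <- (xs - ctr[i, 1])^2 + (ys - ctr[i, 2])^2
    img2[d2 <= rDisc^2] <- 100
  }
  ss2 <- segmentSpeckles(ImageStack(img2, 0.1, 0.05), bgRadius = 5L,
                         nucleusMask = nuc)
  frac <- summarizeSpeckles(ss2)$fractionNucleusArea
  expect_equal(frac, 0.03, tolerance = 0.25)
})
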