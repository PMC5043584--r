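# Costes automatic threshold and Manders coefficients.

test_that("identical channels keep below-threshold correlation positive to
           the scan floor", {
  set.seed(51)
  a <- matrix(runif(400, 1, 10), 20, 20)
  ct <- costesThreshold(a, a)
  expect_equal(ct$T1, min(a))
  expect_equal(ct$warn, "no_threshold_found")
  mc <- mandersCoefficients(a, a, ct$T1, ct$T2)
  expect_equal(mc$tM1, 1)
  expect_equal(mc$tM2, 1)
})

test_that("independent noise channels give near-zero Pearson and Manders", {
  tms <- vapply(1:20, function(s) {
    set.seed(900 + s)
    a <- matrix(rnorm(64 * 64, 100, 10), 64)
    b <- matrix(rnorm(64 * 64, 100, 10), 64)
    ct <- costesThreshold(a, b)
    mc <- mandersCoefficients(a, b, ct$T1, ct$T2)
    c(ct$pearsonGlobal, ifelse(is.na(mc$tM1), 0, mc$tM1))
  }, numeric(2))
  expect_lt(max(abs(tms[1, ])), 0.1)   # global r ~ 0
  expect_lt(mean(tms[2, ]), 0.1)       # tM ~ 0
})

test_that("anti-correlated channels flag and threshold at the maxima", {
  set.seed(52)
  a <- matrix(runif(256, 0, 10), 16, 16)
  b <- 10 - a + matrix(rnorm(256, 0, 0.1), 16, 16)
  ct <- costesThreshold(a, b)
  expect_equal(ct$warn, "anticorrelated")
  expect_equal(ct$T1, max(a))
})

test_that("Manders coefficients follow their definitions", {
  a <- matrix(c(0, 5, 5, 0, 0, 0, 0, 0, 0), 3)
  b <- matrix(c(0, 5, 0, 0, 0, 0, 5, 0, 0), 3)
  # one shared above-threshold pixel out of two in each channel
  mc <- mandersCoefficients(a, b, 1, 1)
  expect_equal(mc$tM1, 0.5)
  expect_equal(mc$tM2, 0.5)

  # spatially disjoint spots
  d1 <- matrix(0, 4, 4); d1[1, 1] <- 9
  d2 <- matrix(0, 4, 4); d2[4, 4] <- 9
  mc2 <- mandersCoefficients(d1, d2, 1, 1)
  expect_equal(mc2$tM1, 0)
  expect_equal(mc2$tM2, 0)

  # no above-threshold signal -> NA, flagged
  mc3 <- mandersCoefficients(d1, d2, 100, 1)
  expect_true(is.na(mc3$tM1))
  expect_true("tM1" %in% mc3$undefined)
})

test_that("thresholded Manders is invariant to intensity scaling of a
           channel", {
  pr <- simulateColocPair(40, 0.5, sceneSpec(imageSize = c(96L, 96L),
                                             minSeparation = 6), seed = 53)
  r1 <- colocalize(pr$ch1, pr$ch2)
  r2 <- colocalize(pr$ch1 * 4.2, pr$ch2)
  expect_equal(r2@tM1, r1@tM1, tolerance = 1e-10)
  expect_equal(r2@tM2, r1@tM2, tolerance = 1e-10)
})

test_that("channel swap exchanges the two Manders coefficients", {
  pr <- simulateColocPair(40, 0.4, sceneSpec(imageSize = c(96L, 96L),
                                             minSeparation = 6), seed = 54)
  r12 <- colocalize(pr$ch1, pr$ch2)
  r21 <- colocalize(pr$ch2, pr$ch1)
  expect_equal(r21@tM1, r12@tM2, tolerance = 0.05)
  expect_equal(r21@tM2, r12@tM1, tolerance = 0.05)
})

test_that("the threshold scan equals the brute-force oracle on small
           discrete images", {
  for (s in 1:20) {
    set.seed(1000 + s)
    a <- matrix(sample(0:7, 256, replace = TRUE), 16, 16)
    shared <- matrix(sample(0:7, 256, replace = TRUE), 16, 16)
    b <- pmin(shared + sample(0:2, 256, replace = TRUE), 7)
    a <- a + shared  # induce correlation
    if (length(unique(as.vector(a))) < 2 ||
        length(unique(as.vector(b))) < 2) next
    got <- costesThreshold(a, b, criterion = "nonpositive")
    want <- oracleCostes(a, b)
    expect_identical(got$T1, want$T1)
  }
})

test_that("planted overlap 0.5 is recovered within 0.1", {
  tm <- vapply(1:20, function(s) {
    pr <- simulateColocPair(100, 0.5,
                            sceneSpec(imageSize = c(192L, 192L),
                                      minSeparation = 5), seed = 1100 + s)
    r <- colocalize(pr$ch1, pr$ch2, mask = pr$nucleusMask)
    c(r@tM1, r@tM2)
  }, numeric(2))
  expect_lt(abs(mean(tm[1, ]) - 0.5), 0.1)
  expect_lt(abs(mean(tm[2, ]) - 0.5), 0.1)
})

test_that("degenerate input is rejected", {
  expect_error(costesThreshold(matrix(1, 4, 4), matrix(1:16, 4, 4)),
               "distinct")
  expect_error(mandersCoefficients(matrix(1, 2, 2), matrix(1, 3, 3), 0, 0))
})
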