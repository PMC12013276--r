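test_that("threshold estimation matches hand arithmetic and floors at 1", {
  # constant stack: mean = SD = 0, threshold floored at 1
  const <- imageStack(array(7, dim = c(4, 4, 5)))
  roi <- matrix(TRUE, 4, 4)
  expect_equal(estimateThreshold(const, roi = roi), 1)

  # two frames whose ROI |dI| are {0, 1, 2, 3}: mean 1.5, population SD
  # sqrt(1.25), so k = 2 gives 1.5 + 2 * 1.118... = 3.73606...
  f1 <- matrix(10, 2, 2)
  f2 <- matrix(c(10, 11, 12, 13), 2, 2)
  s <- imageStack(list(f1, f2))
  expect_equal(estimateThreshold(s, roi = matrix(TRUE, 2, 2),
                                 nInitialPairs = 1, k = 2),
               1.5 + 2 * sqrt(1.25), tolerance = 1e-12)

  expect_error(estimateThreshold(s, roi = matrix(FALSE, 2, 2)),
               "at least one pixel")
})

test_that("threshold on Gaussian static background follows the half-normal form", {
  # |dI| of two noisy frames is half-normal: mean 1.128 sigma, SD 0.853
  # sigma (sigma = per-frame noise), so k = 5 puts the threshold near
  # 5.39 sigma
  set.seed(5)
  sigma <- 4
  frames <- array(rnorm(64 * 64 * 12, 100, sigma), dim = c(64, 64, 12))
  s <- imageStack(frames)
  thr <- estimateThreshold(s, roi = matrix(TRUE, 64, 64),
                           nInitialPairs = 10, k = 5)
  expect_equal(thr, 5.39 * sigma, tolerance = 0.05)
})

test_that("activity counting matches the stated examples", {
  f1 <- matrix(10, 2, 2)
  f2 <- f1; f2[1, 2] <- 20
  s <- imageStack(list(f1, f2))
  expect_equal(activityCounts(computeActivity(s, threshold = 5)), 1)

  # identical frames give zero activity
  expect_equal(activityCounts(computeActivity(imageStack(list(f1, f1)), 3)),
               0)

  # strict ">": changes exactly at the threshold do not count
  f3 <- f1 + 7
  expect_equal(activityCounts(computeActivity(imageStack(list(f1, f3)), 7)),
               0)
  expect_equal(activityCounts(computeActivity(imageStack(list(f1, f3)),
                                              6.999)), 4)
})

test_that("activity counting equals the per-pixel double-loop oracle", {
  set.seed(33)
  for (i in 1:25) {
    s <- randomSmallStack()
    thr <- sample(c(0L, 1L, 5L, 50L, 128L, 255L), 1)
    act <- computeActivity(s, thr)
    expected <- vapply(seq_len(nFrames(s) - 1L), function(k) {
      bruteForcePairCount(getFrame(s, k), getFrame(s, k + 1L), thr)
    }, integer(1))
    expect_identical(as.integer(activityCounts(act)), expected)
  }
})

test_that("reversing the frame order leaves counts unchanged", {
  set.seed(34)
  for (i in 1:10) {
    s <- randomSmallStack()
    rev <- imageStack(s@frames[, , rev(seq_len(nFrames(s))), drop = FALSE])
    expect_identical(activityCounts(computeActivity(s, 10)),
                     rev(activityCounts(computeActivity(rev, 10))))
  }
})

test_that("cumulation sums counts and converts 30 s pairs to hours", {
  f <- matrix(0, 2, 2)
  s <- imageStack(list(f, f, f, f))  # 3 pairs
  act <- computeActivity(s, 1)
  act@counts <- c(1, 2, 3)
  cu <- cumulateActivity(act, scale = 1)
  expect_equal(caValues(cu), c(1, 3, 6))
  expect_equal(activityTimes(cu), c(1, 2, 3) / 120)

  z <- computeActivity(s, 1)
  expect_equal(caValues(cumulateActivity(z)), c(0, 0, 0))
  expect_error(cumulateActivity(act, scale = 0), "positive")

  # monotone for any counts
  set.seed(35)
  act@counts <- sample(0:4, 3, replace = TRUE)
  expect_true(all(diff(caValues(cumulateActivity(act))) >= 0))

  # default frame interval is 30 s
  expect_equal(frameInterval(imageStack(list(f, f))), 30)
})

test_that("auto-thresholded static noise keeps mean activity below 5e-4 per pixel", {
  set.seed(36)
  for (sigma in c(1.5, 4)) {
    frames <- array(rnorm(48 * 48 * 40, 120, sigma), dim = c(48, 48, 40))
    s <- imageStack(frames)
    thr <- estimateThreshold(s, nInitialPairs = 10, k = 5)
    act <- computeActivity(s, thr)
    expect_lte(mean(activityCounts(act)), 5e-4 * 48 * 48)
  }
})
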