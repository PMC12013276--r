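test_that("noise-off sampling is the model itself and seeds are reproducible", {
  p <- twoPhaseParams(88.9, 500, 4.6, 9.3, 60, 3)
  grid <- seq(0, 200, by = 0.5)
  sim <- sampleCurve(p, grid)
  expect_equal(caValues(sim$curve), twoPhaseCA(p, grid))

  a <- sampleCurve(p, grid, incrementCV = 0.1, seed = 99)
  b <- sampleCurve(p, grid, incrementCV = 0.1, seed = 99)
  expect_identical(caValues(a$curve), caValues(b$curve))
  c <- sampleCurve(p, grid, incrementCV = 0.1, seed = 100)
  expect_false(identical(caValues(a$curve), caValues(c$curve)))

  # noisy curves remain valid nondecreasing CA
  expect_true(all(diff(caValues(a$curve)) >= 0))
  expect_error(sampleCurve(p, numeric(0)), "non-empty")
})

test_that("an inoculum-only curve with Table-2-like NGM kinetics yields zero colonization", {
  p <- twoPhaseParams(cIA = 88.9, cCA = 0, tx = 4.6, tp = 9.3,
                      tc = 300, tg = 5)
  sim <- sampleCurve(p, seq(0, 200, by = 0.5))
  fit <- fitTwoPhase(sim$curve)
  expect_equal(relativeColonization(fit), 0)
  expect_true(tcCensored(fit))
  expect_gte(paramVector(fit)[["tc"]], 200)
})

test_that("scene fields map to nominal parameters", {
  sc <- sceneSpec(excystationDelayMean = 3, explorationDecay = 2.5,
                  colonizationHalfTime = 10, colonizationGrowthTime = 1.2)
  p <- sceneToParams(sc)
  expect_equal(p@tx, 3)
  expect_equal(p@tp, 2.5)
  expect_equal(p@tc, 10)
  expect_equal(p@tg, 1.2)

  sc0 <- sceneSpec(nColonizers = 0L)
  expect_equal(sceneToParams(sc0)@cCA, 0)
})

test_that("an empty noiseless scene renders constant frames with zero activity", {
  sc <- sceneSpec(frameShape = c(32L, 32L), nFrames = 20L, nCysts = 0L,
                  nColonizers = 0L, pixelSigma = 0)
  sim <- renderStack(sc, seed = 1)
  act <- computeActivity(sim$stack, threshold = 0)
  expect_true(all(activityCounts(act) == 0))
  expect_equal(sim$truth$perFrameActive, rep(0L, 20))
})

test_that("a single fast trophozoite changes at most twice its disc area per pair", {
  r <- 3
  sc <- sceneSpec(frameShape = c(64L, 64L), nFrames = 40L, nCysts = 1L,
                  nColonizers = 0L, pixelSigma = 0, trophozoiteRadius = r,
                  cystRadius = r, stepSigma = 4 * r,
                  excystationDelayMean = 0.001, explorationDecay = 0.001,
                  exploreDuration = 1)
  sim <- renderStack(sc, seed = 3)
  discArea <- sum(outer((-r):r, (-r):r,
                        function(dx, dy) dx^2 + dy^2 <= r^2))
  counts <- activityCounts(computeActivity(sim$stack, threshold = 0))
  moving <- sim$truth$perFrameActive[-1] == 1
  expect_true(all(counts <= 2 * discArea))
  # with steps >= 2r most pairs show two disjoint discs' worth of change
  expect_gt(mean(counts[moving] > 0), 0.9)
})

test_that("rendered ground truth is a pure function of (scene, seed)", {
  sc <- sceneSpec(frameShape = c(48L, 48L), nFrames = 30L, nCysts = 5L,
                  nColonizers = 4L, colonizationHalfTime = 0.1,
                  colonizationGrowthTime = 0.05)
  a <- renderStack(sc, seed = 11)
  b <- renderStack(sc, seed = 11)
  expect_identical(a$truth$excystationTimes, b$truth$excystationTimes)
  expect_identical(a$truth$recruitmentTimes, b$truth$recruitmentTimes)
  expect_identical(a$stack@frames, b$stack@frames)
  expect_true(all(a$truth$excystationTimes >= sc@excystationDelayMean))
})

test_that("nominal amplitude prediction bounds the rendered per-pair change", {
  sc <- sceneSpec(frameShape = c(48L, 48L), nFrames = 30L, nCysts = 3L,
                  nColonizers = 0L, pixelSigma = 0,
                  excystationDelayMean = 0.001, explorationDecay = 0.01,
                  exploreDuration = 0.5)
  sim <- renderStack(sc, seed = 7)
  r <- sc@trophozoiteRadius
  discArea <- sum(outer((-r):r, (-r):r,
                        function(dx, dy) dx^2 + dy^2 <= r^2))
  counts <- activityCounts(computeActivity(sim$stack, threshold = 0))
  nActive <- pmax(sim$truth$perFrameActive[-1],
                  sim$truth$perFrameActive[-sc@nFrames])
  expect_true(all(counts <= nActive * 2 * discArea + 2 * discArea))
})
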