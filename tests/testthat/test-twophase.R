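test_that("model evaluation matches hand-computed values", {
  # zero amplitudes give zero everywhere
  p0 <- twoPhaseParams(0, 0, 1, 1, 1, 1)
  expect_equal(twoPhaseCA(p0, c(0, 1, 10, 1e5)), rep(0, 4))

  # direct hand evaluation: at t = tc the logistic term is cCA/2
  p <- twoPhaseParams(cIA = 100, cCA = 200, tx = 4, tp = 10, tc = 50, tg = 2)
  expect_equal(twoPhaseCA(p, 50), 100 * (1 - exp(-4.6)) + 100,
               tolerance = 1e-12)
  expect_equal(twoPhaseCA(p, 50), 198.995, tolerance = 1e-5)

  # asymptote cIA + cCA
  p2 <- twoPhaseParams(60.3, 100, 4.6, 9.3, 50, 2)
  expect_equal(twoPhaseCA(p2, 1e5), 160.3, tolerance = 1e-8)

  # inoculum term defined as 0 before the excystation delay
  expect_equal(twoPhaseCA(p, 0), 200 * plogis(-25))
  expect_lt(twoPhaseCA(p, 3.999), twoPhaseCA(p, 4.001))

  expect_error(twoPhaseCA(p, NA_real_), "finite")
  expect_error(twoPhaseCA(p, -1), "nonnegative")
  expect_error(twoPhaseParams(-1, 0, 1, 1, 1, 1), "nonnegative")
  expect_error(twoPhaseParams(1, 1, 1, 0, 1, 1), "positive")
})

test_that("model is nondecreasing and bounded for random parameter draws", {
  set.seed(11)
  tt <- seq(0, 300, length.out = 1500)
  for (i in 1:25) {
    p <- randomParams()
    y <- twoPhaseCA(p, tt)
    expect_true(all(diff(y) >= -1e-10))
    expect_true(all(y >= 0))
    expect_true(all(y < p@cIA + p@cCA + 1e-9))
  }
})

test_that("CA at t = tc approaches cIA + cCA/2 when phases are separated", {
  p <- twoPhaseParams(100, 500, tx = 2, tp = 4, tc = 150, tg = 3)
  # tc >> tx + 5 tp, so the inoculum term has saturated
  expect_equal(twoPhaseCA(p, 150), 100 + 250, tolerance = 0.01)
})

test_that("activity rate matches closed forms and integrates to the model", {
  p0 <- twoPhaseParams(0, 0, 1, 1, 1, 1)
  expect_equal(twoPhaseRate(p0, seq(0, 100, 5)), rep(0, 21))

  # inoculum rate at onset is cIA/tp; logistic tail negligible when tc >> tx
  p <- twoPhaseParams(100, 200, tx = 4, tp = 10, tc = 150, tg = 2)
  expect_equal(twoPhaseRate(p, 4), 10, tolerance = 1e-6)
  # logistic rate peaks at t = tc with value cCA/(4 tg)
  pSep <- twoPhaseParams(0, 200, 4, 10, 50, 2)
  expect_equal(twoPhaseRate(pSep, 50), 200 / 8, tolerance = 1e-12)

  set.seed(12)
  for (i in 1:5) {
    pr <- randomParams()
    tt <- seq(0, 250, by = 0.01)
    rate <- twoPhaseRate(pr, tt)
    expect_true(all(rate >= 0))
    # trapezoid integral of the rate reproduces CA(T) - CA(0)
    integ <- cumsum(c(0, (rate[-1] + rate[-length(rate)]) / 2 * diff(tt)))
    ca <- twoPhaseCA(pr, tt) - twoPhaseCA(pr, 0)
    expect_lt(max(abs(integ - ca)) / max(ca), 1e-3)
  }
})

test_that("relative colonization follows cCA/(cCA + cIA) with 0/0 -> 0", {
  expect_equal(relativeColonization(
    twoPhaseParams(69.1, 276.4, 3.5, 9, 47, 3.4)), 0.8)
  expect_equal(relativeColonization(twoPhaseParams(50, 0, 1, 1, 1, 1)), 0)
  expect_equal(relativeColonization(twoPhaseParams(0, 50, 1, 1, 1, 1)), 1)
  expect_equal(relativeColonization(twoPhaseParams(0, 0, 1, 1, 1, 1)), 0)
})

test_that("noiseless curves round-trip through the fit", {
  set.seed(21)
  grid <- seq(0, 200, by = 0.5)
  for (i in 1:5) {
    p <- randomParams()
    fit <- fitTwoPhase(sampleCurve(p, grid)$curve)
    err <- abs(paramVector(rawParams(fit)) - paramVector(p)) /
      paramVector(p)
    expect_lt(max(err), 1e-3)
    expect_true(converged(fit))
    expect_gt(fit@rSquared, 0.999)
    expect_gte(fit@rSquared, 0)
    expect_lte(fit@rSquared, 1)
  }
})

test_that("degenerate and invalid curves are handled as specified", {
  grid <- seq(0, 200, by = 2)
  zero <- caCurve(grid, rep(0, length(grid)))
  fz <- fitTwoPhase(zero)
  expect_false(converged(fz))
  expect_true(colonizationAbsent(fz))
  expect_equal(relativeColonization(fz), 0)
  expect_equal(paramVector(fz)[["cIA"]], 0)

  expect_error(fitTwoPhase(caCurve(1:10, 1:10)), "at least 20")

  # a numerical dip (within the class tolerance) warns and is clipped
  ca <- twoPhaseCA(twoPhaseParams(100, 0, 4, 9, 300, 5), grid)
  ca[30] <- ca[31] - 5e-10
  ca[29] <- ca[31]  # ca[30] now dips below its predecessor
  dip <- caCurve(grid, ca)
  expect_warning(fitTwoPhase(dip), "clipping")
})

test_that("a generating tc beyond the window is never reported uncensored inside it", {
  set.seed(31)
  grid <- seq(0, 200, by = 0.5)
  for (i in 1:8) {
    p <- twoPhaseParams(runif(1, 30, 400), runif(1, 100, 2000),
                        runif(1, 1, 8), runif(1, 3, 15),
                        runif(1, 250, 380), runif(1, 1, 10))
    fit <- fitTwoPhase(sampleCurve(p, grid)$curve)
    if (tcCensored(fit)) {
      expect_gte(paramVector(fit)[["tc"]], 200)
    } else {
      expect_gte(paramVector(fit)[["tc"]], 0.95 * 200)
    }
  }
})

test_that("implausible ordering tc <= tx is flagged", {
  grid <- seq(0, 200, by = 0.5)
  # colonization-like rise placed before the (late, tiny) inoculum phase
  p <- twoPhaseParams(40, 800, tx = 60, tp = 8, tc = 20, tg = 3)
  fit <- fitTwoPhase(sampleCurve(p, grid)$curve)
  if (!colonizationAbsent(fit) &&
      paramVector(fit)[["tc"]] <= paramVector(fit)[["tx"]])
    expect_true("tc<=tx" %in% fit@notes)
  expect_s4_class(fit, "TwoPhaseFit")
})
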