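makeFit <- function(cIA, cCA, tx = 4, tp = 9, tc = 52, tg = 3,
                    censored = FALSE, wend = 200) {
  raw <- twoPhaseParams(cIA, cCA, tx, tp, tc, tg)
  rep <- if (censored) twoPhaseParams(cIA, 0, tx, tp, wend, wend) else raw
  tot <- cIA + cCA
  new("TwoPhaseFit", params = rep, rawParams = raw,
      tcCensored = censored, colonizationAbsent = censored,
      windowEnd = wend,
      relativeColonization = if (censored || tot == 0) 0 else cCA / tot,
      rmse = 1, rSquared = 0.99, nPoints = 400L, converged = TRUE,
      boundsHit = character(0), notes = character(0))
}

test_that("aggregation reproduces hand arithmetic and censoring counts", {
  fits <- lapply(c(50, 52, 54), function(tc) makeFit(100, 400, tc = tc))
  s <- aggregateFits(fits, "ens")
  tcRow <- s[s$metric == "tc", ]
  expect_equal(tcRow$mean, 52)
  expect_equal(tcRow$disp, 2)  # sample SD
  expect_equal(tcRow$n, 3)
  expect_equal(tcRow$nCensored, 0)

  # SEM option divides by sqrt(n)
  sem <- aggregateFits(fits, "ens", dispersion = "SEM")
  expect_equal(sem[sem$metric == "tc", "disp"], 2 / sqrt(3))

  # single replicate: zero dispersion with a small-n flag
  s1 <- aggregateFits(fits[1], "solo")
  expect_true(all(s1$disp == 0))
  expect_true(all(s1$smallN))

  # four replicates report N = 4
  s4 <- aggregateFits(rep(fits, length.out = 4), "quad")
  expect_true(all(s4$n == 4))

  # all-censored condition renders as ">window"
  cens <- lapply(1:3, function(i) makeFit(90, 0, censored = TRUE))
  sc <- aggregateFits(cens, "NGM")
  expect_match(sc[sc$metric == "tc", "display"], "^>200")
  expect_equal(sc[sc$metric == "tc", "nCensored"], 3)
  expect_equal(sc[sc$metric == "relColonization", "mean"], 0)

  # order invariance over replicates
  s2 <- aggregateFits(fits[c(3, 1, 2)], "ens")
  expect_equal(s2$mean, s$mean)
  expect_equal(s2$disp, s$disp)

  expect_error(aggregateFits(list(), "x"), "at least one")
})

test_that("clearly separated groups get disjoint letters, agreeing with a permutation oracle", {
  set.seed(41)
  x <- c(-1, 0, 1)
  y <- c(99, 100, 101)
  cc <- compareConditions(list(a = x, b = y), metric = "m")
  expect_false(grepl(cc$letters[1], cc$letters[2], fixed = TRUE))
  expect_lt(attr(cc, "pMatrix")["a", "b"], 0.05)
  # permutation oracle needs n = 4 per group to resolve p < 0.05 at all
  # (2/choose(6,3) = 0.1 is the n = 3 floor)
  x4 <- c(x, 0.5); y4 <- c(y, 100.5)
  cc4 <- compareConditions(list(a = x4, b = y4), metric = "m")
  expect_lt(attr(cc4, "pMatrix")["a", "b"], 0.05)
  expect_lt(permutationP(x4, y4), 0.05 + 1e-9)
})

test_that("identical groups share one letter with a degenerate-variance warning", {
  expect_warning(
    cc <- compareConditions(list(a = c(1, 1), b = c(1, 1), c = c(1, 1)),
                            metric = "m"),
    "zero variance")
  expect_true(all(cc$letters == "a"))
})

test_that("letters exactly reproduce the pairwise significance matrix", {
  set.seed(42)
  for (i in 1:30) {
    k <- sample(3:5, 1)
    vals <- lapply(seq_len(k), function(g) {
      rnorm(sample(3:5, 1), mean = sample(0:3, 1), sd = 1)
    })
    names(vals) <- paste0("g", seq_len(k))
    cc <- compareConditions(vals, metric = "m")
    expect_true(lettersMatchSignificance(cc))
    expect_true(all(nchar(cc$letters) >= 1))
  }
})

test_that("input validation catches unusable designs", {
  expect_error(compareConditions(list(a = 1:3), "m"), "at least 2 conditions")
  expect_error(compareConditions(list(a = 1:3, b = 2), "m"),
               "at least 2 replicates")
})
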