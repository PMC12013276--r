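#' Sample a noisy cumulative activity curve from known parameters
#'
#' Forward-simulates CA(t) on a time grid from a [TwoPhaseParams-class]
#' ground truth. Per-interval increments are the exact integrals of the model
#' rate (i.e. differences of [twoPhaseCA()]), perturbed as
#' `max(0, Normal(mu_i, (incrementCV * mu_i)^2))` and cumulated. With
#' `incrementCV = 0` the output equals [twoPhaseCA()] on the grid exactly;
#' identical seeds give identical output.
#'
#' @param params a [TwoPhaseParams-class] (the ground truth).
#' @param grid strictly increasing times (h), nonnegative.
#' @param incrementCV coefficient of variation applied to each increment
#'   (default 0 = noiseless).
#' @param seed integer seed for the increment noise (ignored when
#'   `incrementCV = 0`).
#' @return A list with elements `curve` (a
#'   [CumulativeActivityCurve-class]) and `truth` (list with `trueParams`,
#'   `incrementCV`, `seed`).
#' @examples
#' p <- twoPhaseParams(88.9, 0, 4.6, 9.3, 300, 5)  # inoculum phase only
#' sim <- sampleCurve(p, seq(0, 200, by = 0.5))
#' relativeColonization(fitTwoPhase(sim$curve))    # 0
#' @export
sampleCurve <- function(params, grid, incrementCV = 0, seed = 1L) {
  stopifnot(is(params, "TwoPhaseParams"), incrementCV >= 0)
  if (!length(grid)) stop("grid must be non-empty")
  if (is.unsorted(grid, strictly = TRUE))
    stop("grid must be strictly increasing")
  if (any(grid < 0)) stop("grid times must be nonnegative")
  base <- twoPhaseCA(params, grid)
  if (incrementCV > 0) {
    inc <- diff(c(0, base))  # inc[1] integrates the rate over 0..t1
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(as.integer(seed))
    inc <- pmax(0, stats::rnorm(length(inc), mean = inc,
                                sd = incrementCV * inc))
    ca <- cumsum(inc)
  } else {
    ca <- base
  }
  list(curve = caCurve(grid, ca),
       truth = list(trueParams = params, incrementCV = incrementCV,
                    seed = as.integer(seed)))
}

# integer-pixel disc offsets for a radius
.discOffsets <- function(r) {
  r <- max(1, round(r))
  g <- expand.grid(dx = -r:r, dy = -r:r)
  g[g$dx^2 + g$dy^2 <= r^2, , drop = FALSE]
}

# draw a disc (value = level) into matrix m at integer center (row, col)
.drawDisc <- function(m, row, col, off, level) {
  rr <- row + off$dx
  cc <- col + off$dy
  ok <- rr >= 1 & rr <= nrow(m) & cc >= 1 & cc <= ncol(m)
  m[cbind(rr[ok], cc[ok])] <- level
  m
}

#' Nominal two-phase parameters implied by a scene
#'
#' Maps generator settings to the two-phase model parameters they should
#' induce: the time constants are taken directly from the scene fields
#' (nominal), while the amplitudes are approximate geometric predictions
#' proportional to object counts times disc area times the number of motile
#' frames per bout (a moving disc can change at most twice its area per
#' frame pair).
#'
#' @param scene a [SceneSpec-class].
#' @return A [TwoPhaseParams-class]. `cCA` is 0 when `nColonizers = 0`.
#' @export
sceneToParams <- function(scene) {
  stopifnot(is(scene, "SceneSpec"))
  area <- nrow(.discOffsets(scene@trophozoiteRadius))
  boutFrames <- max(1, round(scene@exploreDuration * 3600 /
                               scene@frameInterval))
  perObject <- 2 * area * boutFrames
  twoPhaseParams(cIA = scene@nCysts * perObject,
                 cCA = scene@nColonizers * perObject,
                 tx = scene@excystationDelayMean,
                 tp = scene@explorationDecay,
                 tc = scene@colonizationHalfTime,
                 tg = scene@colonizationGrowthTime)
}

#' Render a synthetic time-lapse image stack of an amoeba microcosm
#'
#' Emulates the recordings the activity pipeline consumes. Inoculum amoebae
#' start as static high-contrast cyst discs in a band on one side of the
#' frame; each excysts at a shifted-exponential time (shift
#' `excystationDelayMean`, exponential mean `explorationDecay`), performs a
#' Gaussian random walk of per-frame step SD `stepSigma` for
#' `exploreDuration` hours, then re-encysts in place. A colonization cohort
#' of `nColonizers` objects appears on the lawn half of the frame at
#' logistic-distributed times (half-time `colonizationHalfTime`, growth time
#' `colonizationGrowthTime`), each likewise motile for one bout before
#' settling. Gaussian sensor noise of SD `pixelSigma` is added and frames
#' are quantized to 8-bit levels. By construction the expected cumulative
#' activity follows the two-phase model: the shifted-exponential excystation
#' CDF gives the mono-exponential inoculum term and the logistic recruitment
#' CDF gives the colonization term.
#'
#' @param scene a [SceneSpec-class].
#' @param seed integer seed; all randomness is a pure function of
#'   (scene, seed).
#' @return A list with `stack` (an [ImageStack-class]) and `truth` (list
#'   with `trueParams` from [sceneToParams()], `excystationTimes`,
#'   `recruitmentTimes` in hours, `perFrameActive` counts, and `seed`).
#' @export
renderStack <- function(scene, seed = 1L) {
  stopifnot(is(scene, "SceneSpec"))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))

  nr <- scene@frameShape[1]; nc <- scene@frameShape[2]
  nf <- scene@nFrames
  dtH <- scene@frameInterval / 3600
  margin <- ceiling(max(scene@cystRadius, scene@trophozoiteRadius)) + 1L
  if (nr <= 2 * margin + 2 || nc <= 2 * margin + 2)
    stop("scene too small for the requested object radii")

  # inoculum band: rows above the lawn; lawn: lower half of the frame
  lawnTop <- max(margin + 1L, floor(nr / 2))
  bandBottom <- max(margin + 1L, lawnTop - ceiling(scene@lawnOffset))

  placeBand <- function(n, rows, minSep) {
    if (n == 0L) return(cbind(row = numeric(0), col = numeric(0)))
    pos <- matrix(NA_real_, n, 2)
    for (i in seq_len(n)) {
      for (try in 1:500) {
        cand <- c(stats::runif(1, rows[1], rows[2]),
                  stats::runif(1, margin + 1, nc - margin))
        if (i == 1L || minSep <= 0) { pos[i, ] <- cand; break }
        d2 <- (pos[seq_len(i - 1), 1] - cand[1])^2 +
          (pos[seq_len(i - 1), 2] - cand[2])^2
        if (all(d2 >= minSep^2, na.rm = TRUE)) { pos[i, ] <- cand; break }
        if (try == 500) stop("scene too small to place objects ",
                             "without overlap after bounded retries")
      }
    }
    pos
  }
  # inoculum cysts are kept separated so excystation events are distinct;
  # colonizers may crowd the lawn as real trophozoites do
  inocPos <- placeBand(scene@nCysts, c(margin + 1, bandBottom),
                       2 * scene@cystRadius)
  colPos <- placeBand(scene@nColonizers, c(lawnTop, nr - margin), 0)

  # event times (hours): shifted-exponential excystation, logistic recruitment
  excyst <- scene@excystationDelayMean +
    stats::rexp(scene@nCysts, rate = 1 / scene@explorationDecay)
  u <- stats::runif(scene@nColonizers)
  recruit <- scene@colonizationHalfTime +
    scene@colonizationGrowthTime * log(u / (1 - u))
  recruit <- pmax(recruit, 0)

  bout <- scene@exploreDuration
  offT <- .discOffsets(scene@trophozoiteRadius)
  offC <- .discOffsets(scene@cystRadius)
  objLevel <- min(scene@backgroundLevel + scene@contrast, 255)

  allPos <- rbind(inocPos, colPos)
  starts <- c(excyst, recruit)
  nObj <- nrow(allPos)
  isColonizer <- c(rep(FALSE, scene@nCysts), rep(TRUE, scene@nColonizers))
  cur <- allPos  # current continuous positions

  frames <- array(0, dim = c(nr, nc, nf))
  perFrameActive <- integer(nf)
  tFrames <- (seq_len(nf) - 1L) * dtH

  for (f in seq_len(nf)) {
    tNow <- tFrames[f]
    active <- which(tNow >= starts & tNow < starts + bout)
    settledIn <- which(tNow >= starts + bout | (!isColonizer & tNow < starts))
    # advance random walk for active objects (reflected at margins)
    if (length(active)) {
      stepR <- stats::rnorm(length(active), 0, scene@stepSigma)
      stepC <- stats::rnorm(length(active), 0, scene@stepSigma)
      cur[active, 1] <- pmin(pmax(cur[active, 1] + stepR, margin + 1),
                             nr - margin)
      cur[active, 2] <- pmin(pmax(cur[active, 2] + stepC, margin + 1),
                             nc - margin)
    }
    img <- matrix(scene@backgroundLevel, nr, nc)
    for (i in settledIn)
      img <- .drawDisc(img, round(cur[i, 1]), round(cur[i, 2]), offC,
                       objLevel)
    for (i in active)
      img <- .drawDisc(img, round(cur[i, 1]), round(cur[i, 2]), offT,
                       objLevel)
    if (scene@pixelSigma > 0)
      img <- img + stats::rnorm(nr * nc, 0, scene@pixelSigma)
    frames[, , f] <- pmin(pmax(round(img), 0), 255)
    perFrameActive[f] <- length(active)
  }

  stack <- imageStack(frames, frameInterval = scene@frameInterval,
                      metadata = list(generator = "renderStack",
                                      seed = as.integer(seed)))
  list(stack = stack,
       truth = list(trueParams = sceneToParams(scene),
                    excystationTimes = excyst,
                    recruitmentTimes = recruit,
                    perFrameActive = perFrameActive,
                    seed = as.integer(seed)))
}
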