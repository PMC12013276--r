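#' @import methods
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Six-parameter two-phase cumulative-activity model parameters
#'
#' Holds the parameters of the two-phase excystation/colonization model of
#' cumulative time-lapse activity: a mono-exponential inoculum phase of
#' amplitude \code{cIA} with excystation delay \code{tx} (h) and exploration
#' decay time \code{tp} (h), plus a logistic colonization phase of amplitude
#' \code{cCA} with half-plateau time \code{tc} (h) and growth time \code{tg}
#' (h, the inverse logistic growth rate).
#'
#' Amplitudes are in activity units (AU, above-threshold pixel counts unless
#' rescaled) and must be nonnegative; all time constants are in hours and must
#' be strictly positive (\code{tx} may be zero).
#'
#' @slot cIA numeric(1), inoculum-phase amplitude (AU), >= 0.
#' @slot cCA numeric(1), colonization-phase amplitude (AU), >= 0.
#' @slot tx numeric(1), excystation delay (h), >= 0.
#' @slot tp numeric(1), exploration decay time (h), > 0.
#' @slot tc numeric(1), colonization half-plateau time (h), > 0.
#' @slot tg numeric(1), growth time (h), > 0.
#'
#' @seealso [twoPhaseParams()] (constructor), [twoPhaseCA()], [fitTwoPhase()]
#' @export
setClass("TwoPhaseParams",
  representation(cIA = "numeric", cCA = "numeric", tx = "numeric",
                 tp = "numeric", tc = "numeric", tg = "numeric"))

setValidity("TwoPhaseParams", function(object) {
  v <- c(cIA = object@cIA, cCA = object@cCA, tx = object@tx,
         tp = object@tp, tc = object@tc, tg = object@tg)
  if (length(v) != 6L || !all(is.finite(v)))
    return("all six parameters must be finite scalars")
  if (object@cIA < 0 || object@cCA < 0)
    return("amplitudes cIA and cCA must be nonnegative")
  if (object@tx < 0)
    return("excystation delay tx must be nonnegative")
  if (object@tp <= 0 || object@tc <= 0 || object@tg <= 0)
    return("time constants tp, tc, tg must be strictly positive")
  TRUE
})

#' Construct two-phase model parameters
#'
#' @param cIA,cCA phase amplitudes (AU), nonnegative.
#' @param tx excystation delay (h), nonnegative.
#' @param tp exploration decay time (h), positive.
#' @param tc colonization half-plateau time (h), positive.
#' @param tg growth time (h), positive.
#'
#' @return A [TwoPhaseParams-class] object.
#' @examples
#' p <- twoPhaseParams(cIA = 100, cCA = 200, tx = 4, tp = 10, tc = 50, tg = 2)
#' twoPhaseCA(p, c(0, 24, 50, 200))
#' @export
twoPhaseParams <- function(cIA, cCA, tx, tp, tc, tg) {
  new("TwoPhaseParams", cIA = as.numeric(cIA), cCA = as.numeric(cCA),
      tx = as.numeric(tx), tp = as.numeric(tp), tc = as.numeric(tc),
      tg = as.numeric(tg))
}

#' Result of a two-phase cumulative-activity fit
#'
#' Produced by [fitTwoPhase()]. Carries the (possibly censored) parameter
#' estimates, the censoring flags, the derived relative colonization activity
#' cCA/(cCA + cIA), and fit diagnostics. When colonization is not observed
#' within the recording window, \code{tc} and \code{tg} are reported at
#' \code{windowEnd} with \code{tcCensored = TRUE} and relative colonization
#' is 0 exactly.
#'
#' @slot params [TwoPhaseParams-class], the reported parameters (censored
#'   values capped at the window end).
#' @slot rawParams [TwoPhaseParams-class], the uncensored optimizer solution.
#' @slot tcCensored logical(1), colonization half-time not observed in window.
#' @slot colonizationAbsent logical(1), no credible colonization phase.
#' @slot windowEnd numeric(1), recording window end (h).
#' @slot relativeColonization numeric(1) in [0, 1].
#' @slot rmse numeric(1), root-mean-square residual (AU).
#' @slot rSquared numeric(1), coefficient of determination.
#' @slot nPoints integer(1), number of fitted time points.
#' @slot converged logical(1), optimizer convergence.
#' @slot boundsHit character, names of parameters at a bound.
#' @slot notes character, plausibility flags (e.g. "tc<=tx").
#' @export
setClass("TwoPhaseFit",
  representation(params = "TwoPhaseParams", rawParams = "TwoPhaseParams",
                 tcCensored = "logical", colonizationAbsent = "logical",
                 windowEnd = "numeric", relativeColonization = "numeric",
                 rmse = "numeric", rSquared = "numeric", nPoints = "integer",
                 converged = "logical", boundsHit = "character",
                 notes = "character"))

setValidity("TwoPhaseFit", function(object) {
  if (object@relativeColonization < 0 || object@relativeColonization > 1)
    return("relativeColonization must lie in [0, 1]")
  if (object@rmse < 0) return("rmse must be nonnegative")
  if (object@tcCensored && object@params@tc < object@windowEnd - 1e-8)
    return("a censored tc must be reported at or beyond the window end")
  TRUE
})

#' Time-lapse grayscale image stack
#'
#' An ordered sequence of 2-D grayscale frames with a uniform frame interval;
#' the raw observable of the activity pipeline. Intensities are stored as the
#' integer-valued levels of the source bit depth (0..255 for 8-bit).
#'
#' @slot frames numeric 3-D array, rows x cols x frames (>= 2 frames).
#' @slot frameInterval numeric(1), seconds between frames (default 30).
#' @slot startTime numeric(1), acquisition start (h).
#' @slot metadata list, free-form provenance.
#'
#' @seealso [imageStack()], [readImageStack()], [computeActivity()]
#' @export
setClass("ImageStack",
  representation(frames = "array", frameInterval = "numeric",
                 startTime = "numeric", metadata = "list"))

setValidity("ImageStack", function(object) {
  d <- dim(object@frames)
  if (length(d) != 3L) return("frames must be a rows x cols x n 3-D array")
  if (d[3] < 2L) return("an image stack needs at least 2 frames")
  if (!is.finite(object@frameInterval) || object@frameInterval <= 0)
    return("frameInterval must be a positive number of seconds")
  if (any(!is.finite(object@frames))) return("frame intensities must be finite")
  TRUE
})

#' Construct an image stack
#'
#' @param frames a 3-D array (rows x cols x frames) or a list of equally
#'   sized matrices.
#' @param frameInterval seconds between frames; default 30.
#' @param startTime start of acquisition in hours; default 0.
#' @param metadata optional provenance list.
#' @return An [ImageStack-class].
#' @export
imageStack <- function(frames, frameInterval = 30, startTime = 0,
                       metadata = list()) {
  if (is.list(frames)) {
    d <- dim(frames[[1]])
    if (!all(vapply(frames, function(f) identical(dim(f), d), logical(1))))
      stop("all frames must share the same shape")
    frames <- array(unlist(frames, use.names = FALSE),
                    dim = c(d, length(frames)))
  }
  new("ImageStack", frames = frames, frameInterval = as.numeric(frameInterval),
      startTime = as.numeric(startTime), metadata = metadata)
}

#' Per-frame-pair activity series
#'
#' For each consecutive frame pair, the number of pixels whose absolute
#' intensity change exceeded the detection threshold. Each pair is stamped
#' with the time of the later frame.
#'
#' @slot times numeric, hours (one per frame pair).
#' @slot counts numeric, above-threshold pixel counts (0..nPixels).
#' @slot threshold numeric(1), intensity threshold used.
#' @slot roi logical matrix or NULL, the mask used for threshold estimation.
#' @slot nPixels integer(1), pixels per frame.
#' @export
setClass("ActivitySeries",
  representation(times = "numeric", counts = "numeric", threshold = "numeric",
                 roi = "matrixOrNULL", nPixels = "integer"))

setValidity("ActivitySeries", function(object) {
  if (length(object@times) != length(object@counts))
    return("times and counts must have equal length")
  if (any(object@counts < 0) || any(object@counts > object@nPixels))
    return("counts must lie in [0, nPixels]")
  if (object@threshold < 0) return("threshold must be nonnegative")
  if (is.unsorted(object@times, strictly = TRUE))
    return("times must be strictly increasing")
  TRUE
})

#' Cumulative activity curve CA(t)
#'
#' The running sum of per-frame-pair activity counts, optionally rescaled to
#' activity units (AU); the quantity the two-phase model is fitted to.
#'
#' @slot times numeric, hours.
#' @slot ca numeric, cumulative activity (AU), nondecreasing.
#' @slot scale numeric(1), AU per pixel count (default 1).
#' @slot windowEnd numeric(1), last observation time (h).
#' @seealso [cumulateActivity()], [fitTwoPhase()], [readCurveCSV()]
#' @export
setClass("CumulativeActivityCurve",
  representation(times = "numeric", ca = "numeric", scale = "numeric",
                 windowEnd = "numeric"))

setValidity("CumulativeActivityCurve", function(object) {
  if (length(object@times) != length(object@ca))
    return("times and ca must have equal length")
  if (length(object@times) && is.unsorted(object@times, strictly = TRUE))
    return("times must be strictly increasing")
  if (any(diff(object@ca) < -1e-9))
    return("cumulative activity must be nondecreasing")
  if (length(object@times) &&
      abs(object@windowEnd - object@times[length(object@times)]) > 1e-9)
    return("windowEnd must equal the last time")
  if (object@scale <= 0) return("scale must be positive")
  TRUE
})

#' Construct a cumulative activity curve from raw vectors
#'
#' @param times hours, strictly increasing.
#' @param ca cumulative activity (AU), nondecreasing.
#' @param scale AU per pixel count.
#' @return A [CumulativeActivityCurve-class].
#' @export
caCurve <- function(times, ca, scale = 1) {
  new("CumulativeActivityCurve", times = as.numeric(times),
      ca = as.numeric(ca), scale = as.numeric(scale),
      windowEnd = as.numeric(times[length(times)]))
}

#' Synthetic microcosm scene configuration
#'
#' Describes a rendered time-lapse scene: static high-contrast cysts, an
#' inoculum cohort excysting after a delay and exploring in short motile
#' bouts, and a colonization cohort recruited logistically on the lawn side
#' of the image. The temporal fields map to the nominal two-phase model
#' parameters via [sceneToParams()].
#'
#' @slot frameShape integer(2), frame rows and columns.
#' @slot nFrames integer(1), number of frames (>= 2).
#' @slot frameInterval numeric(1), seconds per frame.
#' @slot nCysts integer(1), inoculum amoebae (start as static cysts).
#' @slot cystRadius numeric(1), cyst disc radius (px).
#' @slot trophozoiteRadius numeric(1), trophozoite disc radius (px).
#' @slot excystationDelayMean numeric(1), onset of excystation (h); maps to tx.
#' @slot explorationDecay numeric(1), exponential spread of excystation
#'   events (h), the decay time of aggregate exploration activity; maps to tp.
#' @slot colonizationHalfTime numeric(1), logistic half-time of colonizer
#'   recruitment (h); maps to tc. Ignored when nColonizers = 0.
#' @slot colonizationGrowthTime numeric(1), logistic growth time (h); maps
#'   to tg.
#' @slot nColonizers integer(1), size of the colonization cohort (0 disables
#'   the colonization phase).
#' @slot stepSigma numeric(1), random-walk step SD (px per frame).
#' @slot exploreDuration numeric(1), motile bout length (h) after excystation
#'   or recruitment, before re-encysting.
#' @slot lawnOffset numeric(1), gap (px) between the inoculum band and the
#'   lawn half of the frame.
#' @slot backgroundLevel numeric(1), background intensity level.
#' @slot contrast numeric(1), additive object contrast.
#' @slot pixelSigma numeric(1), Gaussian sensor noise SD (intensity levels).
#' @export
setClass("SceneSpec",
  representation(frameShape = "integer", nFrames = "integer",
                 frameInterval = "numeric", nCysts = "integer",
                 cystRadius = "numeric", trophozoiteRadius = "numeric",
                 excystationDelayMean = "numeric", explorationDecay = "numeric",
                 colonizationHalfTime = "numeric",
                 colonizationGrowthTime = "numeric", nColonizers = "integer",
                 stepSigma = "numeric", exploreDuration = "numeric",
                 lawnOffset = "numeric", backgroundLevel = "numeric",
                 contrast = "numeric", pixelSigma = "numeric"))

setValidity("SceneSpec", function(object) {
  if (length(object@frameShape) != 2L || any(object@frameShape < 8L))
    return("frameShape must be two dimensions of at least 8 px")
  if (object@nFrames < 2L) return("a scene needs at least 2 frames")
  if (object@frameInterval <= 0) return("frameInterval must be positive")
  if (object@nCysts < 0L || object@nColonizers < 0L)
    return("object counts must be nonnegative")
  if (object@cystRadius <= 0 || object@trophozoiteRadius <= 0)
    return("radii must be positive")
  if (object@excystationDelayMean < 0) return("excystation delay must be >= 0")
  if (object@explorationDecay <= 0 || object@colonizationHalfTime <= 0 ||
      object@colonizationGrowthTime <= 0 || object@exploreDuration <= 0)
    return("time constants must be strictly positive")
  if (object@stepSigma < 0 || object@pixelSigma < 0)
    return("stepSigma and pixelSigma must be nonnegative")
  TRUE
})

#' Construct a scene specification
#'
#' Defaults describe the reference desk-scale scene: a 128 x 128 field
#' recorded every 30 s for 2,400 frames (20 h), 30 inoculum amoebae
#' excysting from 1.5 h with a 2 h exponential spread, and 120 colonizers
#' recruited logistically around 9 h with a 0.8 h growth time.
#'
#' @param frameShape,nFrames,frameInterval,nCysts,cystRadius,trophozoiteRadius
#'   see [SceneSpec-class].
#' @param excystationDelayMean,explorationDecay,colonizationHalfTime,colonizationGrowthTime
#'   nominal two-phase times (h); see [SceneSpec-class].
#' @param nColonizers,stepSigma,exploreDuration,lawnOffset,backgroundLevel,contrast,pixelSigma
#'   see [SceneSpec-class].
#' @return A [SceneSpec-class].
#' @export
sceneSpec <- function(frameShape = c(128L, 128L), nFrames = 2400L,
                      frameInterval = 30, nCysts = 30L, cystRadius = 3,
                      trophozoiteRadius = 3, excystationDelayMean = 1.5,
                      explorationDecay = 2, colonizationHalfTime = 9,
                      colonizationGrowthTime = 0.8, nColonizers = 120L,
                      stepSigma = 2, exploreDuration = 0.25, lawnOffset = 10,
                      backgroundLevel = 40, contrast = 90, pixelSigma = 2) {
  new("SceneSpec", frameShape = as.integer(frameShape),
      nFrames = as.integer(nFrames), frameInterval = as.numeric(frameInterval),
      nCysts = as.integer(nCysts), cystRadius = as.numeric(cystRadius),
      trophozoiteRadius = as.numeric(trophozoiteRadius),
      excystationDelayMean = as.numeric(excystationDelayMean),
      explorationDecay = as.numeric(explorationDecay),
      colonizationHalfTime = as.numeric(colonizationHalfTime),
      colonizationGrowthTime = as.numeric(colonizationGrowthTime),
      nColonizers = as.integer(nColonizers), stepSigma = as.numeric(stepSigma),
      exploreDuration = as.numeric(exploreDuration),
      lawnOffset = as.numeric(lawnOffset),
      backgroundLevel = as.numeric(backgroundLevel),
      contrast = as.numeric(contrast), pixelSigma = as.numeric(pixelSigma))
}
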