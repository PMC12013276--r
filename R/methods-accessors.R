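#' @rdname accessors
setMethod("paramVector", "TwoPhaseParams", function(object) {
  c(cIA = object@cIA, cCA = object@cCA, tx = object@tx,
    tp = object@tp, tc = object@tc, tg = object@tg)
})

#' @rdname accessors
setMethod("paramVector", "TwoPhaseFit",
          function(object) paramVector(object@params))

#' @rdname accessors
setMethod("params", "TwoPhaseFit", function(object) object@params)

#' @rdname accessors
setMethod("rawParams", "TwoPhaseFit", function(object) object@rawParams)

#' @rdname accessors
setMethod("tcCensored", "TwoPhaseFit", function(object) object@tcCensored)

#' @rdname accessors
setMethod("colonizationAbsent", "TwoPhaseFit",
          function(object) object@colonizationAbsent)

#' @rdname accessors
setMethod("converged", "TwoPhaseFit", function(object) object@converged)

#' @rdname accessors
setMethod("windowEnd", "TwoPhaseFit", function(object) object@windowEnd)

#' @rdname accessors
setMethod("windowEnd", "CumulativeActivityCurve",
          function(object) object@windowEnd)

#' @rdname accessors
setMethod("nFrames", "ImageStack", function(object) dim(object@frames)[3])

#' @rdname accessors
setMethod("frameInterval", "ImageStack", function(object) object@frameInterval)

#' @rdname accessors
setMethod("activityTimes", "ActivitySeries", function(object) object@times)

#' @rdname accessors
setMethod("activityTimes", "CumulativeActivityCurve",
          function(object) object@times)

#' @rdname accessors
setMethod("activityCounts", "ActivitySeries", function(object) object@counts)

#' @rdname accessors
setMethod("activityThreshold", "ActivitySeries",
          function(object) object@threshold)

#' @rdname accessors
setMethod("caValues", "CumulativeActivityCurve", function(object) object@ca)

#' Extract a single frame
#'
#' @param stack an [ImageStack-class].
#' @param i frame index (1-based).
#' @return The frame as a numeric matrix.
#' @export
getFrame <- function(stack, i) {
  stopifnot(is(stack, "ImageStack"), i >= 1, i <= nFrames(stack))
  stack@frames[, , i]
}

#' Frame-pair times of a stack
#'
#' Times (h) assigned to consecutive frame pairs: each pair is stamped with
#' the later frame's acquisition time.
#'
#' @param stack an [ImageStack-class].
#' @return numeric vector of length `nFrames(stack) - 1`.
#' @export
pairTimes <- function(stack) {
  n <- nFrames(stack)
  stack@startTime + seq_len(n - 1L) * stack@frameInterval / 3600
}

setMethod("show", "TwoPhaseParams", function(object) {
  v <- paramVector(object)
  cat("TwoPhaseParams: cIA =", format(v["cIA"], digits = 4),
      "AU, cCA =", format(v["cCA"], digits = 4), "AU\n")
  cat("  tx =", format(v["tx"], digits = 4),
      "h, tp =", format(v["tp"], digits = 4),
      "h, tc =", format(v["tc"], digits = 4),
      "h, tg =", format(v["tg"], digits = 4), "h\n")
})

setMethod("show", "TwoPhaseFit", function(object) {
  cat("TwoPhaseFit on", object@nPoints, "points over [0,",
      format(object@windowEnd, digits = 4), "] h\n")
  show(object@params)
  cat("  relative colonization:",
      format(object@relativeColonization, digits = 3),
      if (object@colonizationAbsent) "(colonization absent)" else "", "\n")
  if (object@tcCensored)
    cat("  tc/tg censored at window end (>",
        format(object@windowEnd, digits = 4), "h)\n")
  cat("  rmse:", format(object@rmse, digits = 4),
      "AU, R^2:", format(object@rSquared, digits = 4),
      ", converged:", object@converged, "\n")
  if (length(object@boundsHit))
    cat("  at bounds:", paste(object@boundsHit, collapse = ", "), "\n")
  if (length(object@notes))
    cat("  notes:", paste(object@notes, collapse = "; "), "\n")
})

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@frames)
  cat("ImageStack:", d[1], "x", d[2], "px,", d[3], "frames @",
      object@frameInterval, "s (",
      format(d[3] * object@frameInterval / 3600, digits = 4), "h )\n")
})

setMethod("show", "ActivitySeries", function(object) {
  cat("ActivitySeries:", length(object@counts), "frame pairs, threshold",
      format(object@threshold, digits = 4), "\n")
  cat("  total activity:", sum(object@counts), "px over",
      format(max(object@times), digits = 4), "h\n")
})

setMethod("show", "CumulativeActivityCurve", function(object) {
  cat("CumulativeActivityCurve:", length(object@ca), "points over [",
      format(object@times[1], digits = 4), ",",
      format(object@windowEnd, digits = 4), "] h, CA(end) =",
      format(object@ca[length(object@ca)], digits = 6), "AU\n")
})

setMethod("show", "SceneSpec", function(object) {
  cat("SceneSpec:", object@frameShape[1], "x", object@frameShape[2], "px,",
      object@nFrames, "frames @", object@frameInterval, "s\n")
  cat("  inoculum:", object@nCysts, "amoebae, tx =",
      object@excystationDelayMean, "h, tp =", object@explorationDecay, "h\n")
  cat("  colonization:", object@nColonizers, "objects, tc =",
      object@colonizationHalfTime, "h, tg =",
      object@colonizationGrowthTime, "h\n")
})

#' Plot a cumulative activity curve with an optional fit overlay
#'
#' @param x a [CumulativeActivityCurve-class].
#' @param fit optional [TwoPhaseFit-class] to overlay.
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plotCurve <- function(x, fit = NULL, ...) {
  graphics::plot(x@times, x@ca, type = "l", xlab = "time (h)",
                 ylab = "cumulative activity (AU)", ...)
  if (!is.null(fit)) {
    tt <- seq(min(x@times), max(x@times), length.out = 400)
    graphics::lines(tt, twoPhaseCA(rawParams(fit), tt), col = 2, lty = 2)
  }
  invisible(x)
}
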