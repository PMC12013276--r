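#' Accessor generics
#'
#' Small accessor family for the package's S4 classes: parameter vectors,
#' fitted parameters, time axes, activity counts and cumulative activity
#' values, censoring flags and fit diagnostics.
#'
#' @param object an amoebaCA S4 object.
#' @return The corresponding slot value; `paramVector` returns a named
#'   numeric of length six (cIA, cCA, tx, tp, tc, tg).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("paramVector", function(object) standardGeneric("paramVector"))

#' @rdname accessors
#' @export
setGeneric("params", function(object) standardGeneric("params"))

#' @rdname accessors
#' @export
setGeneric("rawParams", function(object) standardGeneric("rawParams"))

#' @rdname accessors
#' @export
setGeneric("tcCensored", function(object) standardGeneric("tcCensored"))

#' @rdname accessors
#' @export
setGeneric("colonizationAbsent",
           function(object) standardGeneric("colonizationAbsent"))

#' @rdname accessors
#' @export
setGeneric("converged", function(object) standardGeneric("converged"))

#' @rdname accessors
#' @export
setGeneric("windowEnd", function(object) standardGeneric("windowEnd"))

#' @rdname accessors
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setGeneric("frameInterval", function(object) standardGeneric("frameInterval"))

#' @rdname accessors
#' @export
setGeneric("activityTimes", function(object) standardGeneric("activityTimes"))

#' @rdname accessors
#' @export
setGeneric("activityCounts",
           function(object) standardGeneric("activityCounts"))

#' @rdname accessors
#' @export
setGeneric("activityThreshold",
           function(object) standardGeneric("activityThreshold"))

#' @rdname accessors
#' @export
setGeneric("caValues", function(object) standardGeneric("caValues"))

#' Relative colonization activity
#'
#' The fraction of total cumulative activity attributable to the colonization
#' phase, cCA/(cCA + cIA). The 0/0 case and fits flagged as
#' colonization-absent both map to 0 exactly.
#'
#' @param object a [TwoPhaseFit-class] or [TwoPhaseParams-class].
#' @return numeric(1) in [0, 1].
#' @examples
#' relativeColonization(twoPhaseParams(69.1, 276.4, 3.5, 9, 47, 3.4))
#' @export
setGeneric("relativeColonization",
           function(object) standardGeneric("relativeColonization"))
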