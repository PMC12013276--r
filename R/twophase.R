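#' Evaluate the two-phase cumulative-activity model
#'
#' Computes CA(t) = cIA (1 - e^-((t - tx)/tp)) for t >= tx (0 before the
#' excystation delay) plus the logistic colonization term
#' cCA / (1 + e^-((t - tc)/tg)). The inoculum term is defined as 0 for
#' t < tx because cumulative activity is a running sum of nonnegative counts
#' and cannot decrease; at t = tc the logistic term equals cCA/2 (half of its
#' plateau).
#'
#' @param params a [TwoPhaseParams-class].
#' @param t time or vector of times (h), nonnegative and finite.
#' @return CA value(s) in AU, nondecreasing in `t`, within `[0, cIA + cCA)`.
#' @examples
#' p <- twoPhaseParams(cIA = 100, cCA = 200, tx = 4, tp = 10, tc = 50, tg = 2)
#' twoPhaseCA(p, 50)  # 100 * (1 - exp(-4.6)) + 100
#' @export
twoPhaseCA <- function(params, t) {
  stopifnot(is(params, "TwoPhaseParams"))
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0))
    stop("t must be finite and nonnegative")
  .twoPhaseCA(paramVector(params), t)
}

# unchecked kernel shared with the fitter (th: named or positional
# c(cIA, cCA, tx, tp, tc, tg))
.twoPhaseCA <- function(th, t) {
  th <- unname(th)
  inoc <- ifelse(t >= th[3], th[1] * (1 - exp(-(t - th[3]) / th[4])), 0)
  unname(inoc + th[2] * stats::plogis((t - th[5]) / th[6]))
}

#' Instantaneous activity rate of the two-phase model
#'
#' Analytic time derivative of [twoPhaseCA()]:
#' (cIA/tp) e^-((t - tx)/tp) for t >= tx, plus the bell-shaped logistic
#' derivative (cCA/tg) p (1 - p) with p the logistic term's fraction of its
#' plateau. The logistic contribution peaks at t = tc with value cCA/(4 tg).
#' Integrating the rate from 0 to T recovers CA(T).
#'
#' @inheritParams twoPhaseCA
#' @return Activity rate(s) in AU/h, always >= 0.
#' @export
twoPhaseRate <- function(params, t) {
  stopifnot(is(params, "TwoPhaseParams"))
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0))
    stop("t must be finite and nonnegative")
  th <- unname(paramVector(params))
  inoc <- ifelse(t >= th[3], th[1] / th[4] * exp(-(t - th[3]) / th[4]), 0)
  p <- stats::plogis((t - th[5]) / th[6])
  unname(inoc + th[2] / th[6] * p * (1 - p))
}

#' Options for the two-phase fit
#'
#' @param nStarts number of deterministic multi-starts (>= 1).
#' @param inoculumWindow early window (h) used for the inoculum-only
#'   initialization fit; the effective window is
#'   `min(inoculumWindow, 0.4 * windowEnd)` so compressed recordings still
#'   leave room for the colonization phase.
#' @param ccaMinFraction censor the colonization phase when fitted cCA falls
#'   below this fraction of the total amplitude cIA + cCA.
#' @param tcCensorFraction censor when fitted tc exceeds this fraction of the
#'   recording window.
#' @param ampFactor amplitude upper bound as a multiple of max(CA).
#' @param timeFactor time-constant upper bound as a multiple of the window.
#' @param maxIter maximum Levenberg-Marquardt iterations per start.
#' @return A list of class `amoebaCA_fitOptions`.
#' @export
fitOptions <- function(nStarts = 5L, inoculumWindow = 24,
                       ccaMinFraction = 0.02, tcCensorFraction = 0.95,
                       ampFactor = 10, timeFactor = 2, maxIter = 300L) {
  stopifnot(nStarts >= 1L, inoculumWindow > 0, ccaMinFraction >= 0,
            ccaMinFraction < 1, tcCensorFraction > 0, tcCensorFraction <= 1,
            ampFactor > 1, timeFactor >= 1)
  structure(list(nStarts = as.integer(nStarts),
                 inoculumWindow = inoculumWindow,
                 ccaMinFraction = ccaMinFraction,
                 tcCensorFraction = tcCensorFraction,
                 ampFactor = ampFactor, timeFactor = timeFactor,
                 maxIter = as.integer(maxIter)),
            class = "amoebaCA_fitOptions")
}

# residuals for bounded Levenberg-Marquardt
.tpResid <- function(th, t, ca) .twoPhaseCA(th, t) - ca

# shrink the inoculum-initialization window when a colonization rate peak
# intrudes into it: end the window at the activity-rate trough between the
# early exploration peak and a later dominant peak
.refineInoculumWindow <- function(t, ca, w1, maxca) {
  n <- length(t)
  if (n < 12L) return(w1)
  inc <- diff(ca) / diff(t)
  tm <- t[-1]
  k <- max(5L, round(n / 40))
  if (k %% 2L == 0L) k <- k + 1L
  if (k >= length(inc)) return(w1)
  sm <- as.numeric(stats::filter(inc, rep(1 / k, k), sides = 2))
  ok <- !is.na(sm)
  smv <- sm[ok]
  tmv <- tm[ok]
  cav <- ca[-1][ok]
  i1 <- which(cav > 0.02 * maxca)[1]
  if (is.na(i1)) return(w1)
  t1 <- tmv[i1]
  igm <- which.max(smv)
  if (tmv[igm] <= max(0.5 * w1, t1)) return(w1)  # no late dominant peak
  mid <- which(tmv > t1 & tmv < tmv[igm])
  if (length(mid) < 3L) return(w1)
  w1new <- tmv[mid[which.min(smv[mid])]]
  max(min(w1new, w1), t[min(8L, n)])
}

# nonnegative 2-basis linear amplitude solve given the nonlinear parameters
# (variable projection): basis 1 = truncated saturating exponential, basis 2
# = logistic; returns c(cIA, cCA) clamped to [0, ampHi]
.ampSolve <- function(nl, t, ca, ampHi) {
  b1 <- ifelse(t >= nl[1], 1 - exp(-(t - nl[1]) / nl[2]), 0)
  b2 <- stats::plogis((t - nl[3]) / nl[4])
  g11 <- sum(b1 * b1); g12 <- sum(b1 * b2); g22 <- sum(b2 * b2)
  r1 <- sum(b1 * ca); r2 <- sum(b2 * ca)
  det <- g11 * g22 - g12 * g12
  if (det > 1e-10 * max(g11 * g22, 1e-300)) {
    a1 <- (g22 * r1 - g12 * r2) / det
    a2 <- (g11 * r2 - g12 * r1) / det
  } else {
    a1 <- if (g11 > 0) r1 / g11 else 0
    a2 <- 0
  }
  if (a1 < 0) { a1 <- 0; a2 <- if (g22 > 0) r2 / g22 else 0 }
  if (a2 < 0) { a2 <- 0; a1 <- if (g11 > 0) r1 / g11 else 0 }
  c(min(max(a1, 0), ampHi), min(max(a2, 0), ampHi))
}

# variable-projection residuals over nl = c(tx, tp, tc, tg)
.vpResid <- function(nl, t, ca, ampHi) {
  a <- .ampSolve(nl, t, ca, ampHi)
  .twoPhaseCA(c(a[1], a[2], nl), t) - ca
}

# one start: bounded variable-projection LM over the four time parameters,
# then a full six-parameter polish; returns list(par, sse, info)
.lmSolve <- function(start, lower, upper, t, ca, maxIter) {
  nl0 <- pmin(pmax(start[3:6], lower[3:6]), upper[3:6])
  vp <- tryCatch(
    minpack.lm::nls.lm(par = nl0, lower = lower[3:6], upper = upper[3:6],
                       fn = .vpResid, t = t, ca = ca, ampHi = upper[["cIA"]],
                       control = minpack.lm::nls.lm.control(
                         maxiter = maxIter, ftol = 1e-14, ptol = 1e-14,
                         gtol = 0)),
    error = function(e) NULL)
  if (!is.null(vp)) {
    nl <- pmin(pmax(vp$par, lower[3:6]), upper[3:6])
    a <- .ampSolve(nl, t, ca, upper[["cIA"]])
    full0 <- c(cIA = a[1], cCA = a[2], tx = nl[[1]], tp = nl[[2]],
               tc = nl[[3]], tg = nl[[4]])
  } else {
    full0 <- start
  }
  full0 <- pmin(pmax(full0, lower), upper)
  ans <- minpack.lm::nls.lm(par = full0, lower = lower, upper = upper,
                            fn = .tpResid, t = t, ca = ca,
                            control = minpack.lm::nls.lm.control(
                              maxiter = maxIter, ftol = 1e-14,
                              ptol = 1e-14, gtol = 0))
  par <- pmin(pmax(ans$par, lower), upper)
  list(par = par, sse = sum(.tpResid(par, t, ca)^2), info = ans$info)
}

#' Fit the two-phase model to a cumulative activity curve
#'
#' Bounded least-squares estimation of the six behavioral parameters (cIA,
#' cCA, tx, tp, tc, tg) with a deterministic two-stage initialization and
#' multi-start refinement, followed by window censoring: when the fitted
#' colonization half-time lies at the end of the recording window (default
#' beyond 95% of it) or the fitted colonization amplitude is negligible
#' (default below 2% of the total amplitude), colonization is declared
#' absent, tc and tg are reported censored at the window end, and relative
#' colonization activity is 0 exactly.
#'
#' Initialization: the inoculum parameters are first fitted alone on the
#' early window where cumulative activity has typically plateaued before the
#' colonization rise (24 h for a standard ~200 h recording); the logistic
#' phase is then initialized from the half-rise and 10-90% rise duration of
#' the residual. Bounds are amplitudes in `[0, ampFactor * max(CA)]` and
#' times in `(0, timeFactor * windowEnd]`. Multi-start candidates perturb the
#' logistic initialization deterministically; ties are broken by lowest RMSE,
#' then lowest cCA.
#'
#' @param curve a [CumulativeActivityCurve-class] with at least 20 points.
#' @param options a [fitOptions()] list.
#' @return A [TwoPhaseFit-class]. An identically zero curve yields a
#'   degenerate result with `converged = FALSE` and zero amplitudes;
#'   optimizer non-convergence is reported in the object, not raised.
#' @examples
#' p <- twoPhaseParams(100, 400, 4, 9, 60, 3)
#' cu <- sampleCurve(p, seq(0, 200, by = 0.5))$curve
#' fit <- fitTwoPhase(cu)
#' paramVector(fit)
#' @export
fitTwoPhase <- function(curve, options = fitOptions()) {
  stopifnot(is(curve, "CumulativeActivityCurve"))
  t <- curve@times
  ca <- curve@ca
  if (length(t) < 20L)
    stop("fitTwoPhase needs at least 20 time points")
  if (any(diff(ca) < 0)) {
    warning("cumulative activity is not nondecreasing; clipping with cummax")
    ca <- cummax(ca)
  }
  wend <- curve@windowEnd
  n <- length(t)

  degenerate <- function(conv) {
    pz <- twoPhaseParams(0, 0, 0, wend, wend, wend)
    new("TwoPhaseFit", params = pz, rawParams = pz, tcCensored = TRUE,
        colonizationAbsent = TRUE, windowEnd = wend,
        relativeColonization = 0, rmse = 0, rSquared = 0,
        nPoints = as.integer(n), converged = conv,
        boundsHit = character(0), notes = "all-zero curve")
  }
  if (all(ca == 0)) return(degenerate(FALSE))

  maxca <- max(ca)
  # decay/growth times below a fraction of the sampling interval are not
  # resolvable and create degenerate step-function attractors
  tFloor <- max(1e-6, stats::median(diff(t)) / 8)
  lower <- c(cIA = 0, cCA = 0, tx = 0, tp = tFloor, tc = 1e-6, tg = tFloor)
  upper <- c(cIA = options$ampFactor * maxca, cCA = options$ampFactor * maxca,
             tx = options$timeFactor * wend, tp = options$timeFactor * wend,
             tc = options$timeFactor * wend, tg = options$timeFactor * wend)

  ## --- stage 1: inoculum-only initialization on the early window
  w1 <- .refineInoculumWindow(t, ca, min(options$inoculumWindow, 0.4 * wend),
                              maxca)
  cIA0 <- max(stats::approx(t, ca, xout = w1, rule = 2)$y, 1e-8)
  i5 <- which(ca > 0.05 * cIA0)[1]
  tx0 <- if (is.na(i5)) 0.05 * wend else t[i5]
  i63 <- which(ca >= 0.63 * cIA0)[1]
  tp0 <- if (is.na(i63)) w1 / 3 else max(t[i63] - tx0, 1e-3)
  early <- t <= w1
  # the inoculum phase plateaus within the early window, so its amplitude
  # is bracketed by the plateau estimate and its decay time by the window
  inoc <- tryCatch({
    f <- function(q, tt, cc)
      ifelse(tt >= q[2], q[1] * (1 - exp(-(tt - q[2]) / q[3])), 0) - cc
    a <- minpack.lm::nls.lm(
      par = pmin(pmax(c(cIA0, tx0, tp0), c(0, 0, tFloor)),
                 c(3 * cIA0, w1, w1)),
      lower = c(0, 0, tFloor), upper = c(3 * cIA0, w1, w1),
      fn = f, tt = t[early], cc = ca[early],
      control = minpack.lm::nls.lm.control(maxiter = 150))
    a$par
  }, error = function(e) c(cIA0, tx0, tp0))
  cIA1 <- inoc[1]; tx1 <- inoc[2]; tp1 <- max(inoc[3], tFloor)

  ## --- stage 2: logistic initialization from the residual half-rise
  resid <- ca - ifelse(t >= tx1, cIA1 * (1 - exp(-(t - tx1) / tp1)), 0)
  rr <- pmax(resid, 0)
  rmax <- max(rr)
  cCA0 <- max(rr[n], ca[n] - cIA1, ca[n] - cIA0, 0)
  if (rmax > 1e-8 * maxca && cCA0 > 1e-8 * maxca) {
    # half-rise and 10-90% rise duration of the residual, scale-free
    pick <- function(frac) {
      i <- which(rr >= frac * rmax)[1]
      if (is.na(i)) wend else t[i]
    }
    tc0 <- pick(0.5)
    tg0 <- min(max((pick(0.9) - pick(0.1)) / 4, tFloor), wend / 10)
  } else {
    cCA0 <- 1e-6 * maxca
    tc0 <- wend
    tg0 <- wend / 20
  }

  base <- c(cIA = cIA1, cCA = cCA0, tx = tx1, tp = tp1, tc = tc0, tg = tg0)
  starts <- list(
    base,
    replace(base, c("tc", "tg"), c(0.7 * tc0, 0.5 * tg0)),
    replace(base, c("tc", "tg"),
            c(1.3 * tc0, min(2 * tg0, wend / 10))),
    replace(base, c("cCA", "tc", "tg"),
            c(max(cCA0, 0.5 * maxca), 0.35 * wend, wend / 40)),
    replace(base, c("cCA", "tc", "tg"),
            c(0.01 * maxca, wend, wend / 20)))
  if (options$nStarts < length(starts))
    starts <- starts[seq_len(options$nStarts)]
  if (options$nStarts > length(starts)) {
    extra <- options$nStarts - length(starts)
    fr <- seq(0.2, 0.9, length.out = extra)
    starts <- c(starts,
                lapply(fr, function(f) replace(base, "tc", f * wend)))
  }

  fits <- lapply(starts, .lmSolve, lower = lower, upper = upper,
                 t = t, ca = ca, maxIter = options$maxIter)
  sses <- vapply(fits, `[[`, numeric(1), "sse")
  ccas <- vapply(fits, function(f) f$par[["cCA"]], numeric(1))
  tol <- 1e-10 * (1 + min(sses))
  cand <- which(sses <= min(sses) + tol)
  best <- fits[[cand[which.min(ccas[cand])]]]

  par <- best$par
  sse <- best$sse
  convergedFlag <- best$info %in% c(1L, 2L, 3L)
  rel <- abs(par - lower) / pmax(abs(upper - lower), 1e-12)
  relu <- abs(par - upper) / pmax(abs(upper - lower), 1e-12)
  boundsHit <- names(par)[rel < 1e-9 | relu < 1e-9]
  boundsHit <- setdiff(boundsHit, c("cIA", "cCA", "tx")[par[1:3] == 0])

  rmse <- sqrt(sse / n)
  sst <- sum((ca - mean(ca))^2)
  r2 <- if (sst > 0) 1 - sse / sst else 0

  raw <- twoPhaseParams(par[["cIA"]], par[["cCA"]], max(par[["tx"]], 0),
                        max(par[["tp"]], 1e-6), max(par[["tc"]], 1e-6),
                        max(par[["tg"]], 1e-6))
  censor <- par[["tc"]] >= options$tcCensorFraction * wend ||
    par[["cCA"]] < options$ccaMinFraction * (par[["cIA"]] + par[["cCA"]])
  notes <- character(0)
  if (!censor && par[["tc"]] <= par[["tx"]])
    notes <- c(notes, "tc<=tx")

  if (censor) {
    rep <- twoPhaseParams(par[["cIA"]], 0, max(par[["tx"]], 0),
                          max(par[["tp"]], 1e-6), wend, wend)
    relcol <- 0
  } else {
    rep <- raw
    tot <- par[["cIA"]] + par[["cCA"]]
    relcol <- if (tot > 0) par[["cCA"]] / tot else 0
  }

  new("TwoPhaseFit", params = rep, rawParams = raw,
      tcCensored = censor, colonizationAbsent = censor, windowEnd = wend,
      relativeColonization = relcol, rmse = rmse, rSquared = r2,
      nPoints = as.integer(n), converged = convergedFlag,
      boundsHit = boundsHit, notes = notes)
}

#' @rdname relativeColonization
setMethod("relativeColonization", "TwoPhaseFit",
          function(object) object@relativeColonization)

#' @rdname relativeColonization
setMethod("relativeColonization", "TwoPhaseParams", function(object) {
  tot <- object@cIA + object@cCA
  if (tot > 0) object@cCA / tot else 0
})
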