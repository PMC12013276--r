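#' Aggregate replicate fits into a condition-level summary
#'
#' Computes per-parameter mean and dispersion (sample SD by default, SEM
#' optionally) across replicate [TwoPhaseFit-class] objects of one
#' condition, in the style of a per-condition parameter table. Censored tc
#' and tg values enter at the window cap and are counted in `nCensored`;
#' when every replicate is censored the display string is
#' `">windowEnd"`.
#'
#' @param fits list of [TwoPhaseFit-class] objects (>= 1), all from the same
#'   condition.
#' @param condition condition label.
#' @param dispersion "SD" (sample standard deviation, default) or "SEM".
#' @return A data.frame with one row per metric (cIA, relColonization, tx,
#'   tp, tc, tg) and columns `condition`, `metric`, `n`, `mean`, `disp`,
#'   `dispersion`, `nCensored`, `smallN`, `display`.
#' @examples
#' p <- twoPhaseParams(100, 400, 4, 9, 52, 3)
#' fits <- lapply(1:3, function(s)
#'   fitTwoPhase(sampleCurve(p, seq(0, 200, 0.5), 0.1, seed = s)$curve))
#' aggregateFits(fits, "ensemble")
#' @export
aggregateFits <- function(fits, condition, dispersion = c("SD", "SEM")) {
  dispersion <- match.arg(dispersion)
  if (!length(fits)) stop("aggregateFits needs at least one fit")
  stopifnot(all(vapply(fits, is, logical(1), "TwoPhaseFit")))
  n <- length(fits)
  wend <- max(vapply(fits, windowEnd, numeric(1)))
  vals <- vapply(fits, function(f) {
    v <- paramVector(f)  # censored tc/tg already capped at the window end
    c(cIA = v[["cIA"]], relColonization = relativeColonization(f),
      tx = v[["tx"]], tp = v[["tp"]], tc = v[["tc"]], tg = v[["tg"]])
  }, numeric(6))
  cens <- vapply(fits, tcCensored, logical(1))
  out <- do.call(rbind, lapply(rownames(vals), function(m) {
    x <- vals[m, ]
    mu <- mean(x)
    s <- if (n > 1) stats::sd(x) else 0
    if (dispersion == "SEM") s <- s / sqrt(n)
    ncens <- if (m %in% c("tc", "tg")) sum(cens) else 0L
    disp <- if (m %in% c("tc", "tg") && all(cens))
      paste0(">", format(wend, digits = 6))
    else
      paste0(format(signif(mu, 6)), " ± ", format(signif(s, 6)))
    data.frame(condition = condition, metric = m, n = n, mean = mu,
               disp = s, dispersion = dispersion, nCensored = ncens,
               smallN = n < 2, display = disp, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# insert-and-absorb compact letter display from a logical "significantly
# different" matrix (symmetric, conditions in rownames)
.letterDisplay <- function(sig) {
  g <- rownames(sig)
  cols <- list(g)
  pairs <- which(upper.tri(sig) & sig, arr.ind = TRUE)
  if (nrow(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      a <- g[pairs[k, 1]]
      b <- g[pairs[k, 2]]
      newCols <- list()
      for (col in cols) {
        if (a %in% col && b %in% col) {
          newCols <- c(newCols, list(setdiff(col, a)), list(setdiff(col, b)))
        } else {
          newCols <- c(newCols, list(col))
        }
      }
      # absorb: drop columns that are subsets of another column
      keep <- rep(TRUE, length(newCols))
      for (i in seq_along(newCols)) {
        for (j in seq_along(newCols)) {
          if (i != j && keep[j] &&
              all(newCols[[i]] %in% newCols[[j]]) &&
              (length(newCols[[i]]) < length(newCols[[j]]) || i > j)) {
            keep[i] <- FALSE
            break
          }
        }
      }
      cols <- newCols[keep]
    }
  }
  cols <- cols[order(vapply(cols, function(cl) min(match(cl, g)),
                            numeric(1)))]
  lets <- c(letters, paste0(rep(letters, each = 26), letters))
  out <- vapply(g, function(cond) {
    paste0(lets[which(vapply(cols, function(cl) cond %in% cl, logical(1)))],
           collapse = "")
  }, character(1))
  out
}

#' Compare conditions by one-way ANOVA with Tukey HSD letter groups
#'
#' Runs a one-way analysis of variance of a chosen metric across conditions,
#' follows with Tukey HSD pairwise comparisons, and summarizes them as a
#' compact letter display assembled by the insert-and-absorb algorithm:
#' conditions share a letter if and only if their pairwise comparison is
#' non-significant at `alpha`. If the metric has zero variance everywhere,
#' all conditions share the letter "a" and a degenerate-variance warning is
#' issued.
#'
#' @param values data.frame with columns `condition` and `value` (one row
#'   per replicate), or a named list of numeric replicate vectors. Censored
#'   values are expected already capped at the window end (as reported by
#'   [fitTwoPhase()] and [aggregateFits()]).
#' @param metric name of the compared metric (recorded in the output).
#' @param alpha significance level (default 0.05).
#' @return A data.frame with columns `condition`, `letters`, plus attributes
#'   `metric`, `alpha`, `method` ("one-way ANOVA + Tukey HSD"), `pMatrix`
#'   (symmetric Tukey adjusted p-values) and `anovaP`.
#' @examples
#' vals <- list(NGM = c(0, 0, 0.01), OP50 = c(0.99, 1, 0.98))
#' compareConditions(vals, metric = "relColonization")
#' @export
compareConditions <- function(values, metric = "value", alpha = 0.05) {
  if (is.list(values) && !is.data.frame(values)) {
    values <- data.frame(
      condition = rep(names(values), lengths(values)),
      value = unlist(values, use.names = FALSE))
  }
  stopifnot(all(c("condition", "value") %in% names(values)),
            alpha > 0, alpha < 1)
  values$condition <- factor(values$condition)
  conds <- levels(values$condition)
  if (length(conds) < 2L) stop("need at least 2 conditions to compare")
  if (any(table(values$condition) < 2L))
    stop("each condition needs at least 2 replicates")

  pm <- matrix(1, length(conds), length(conds),
               dimnames = list(conds, conds))
  if (stats::var(values$value) == 0) {
    warning("metric has zero variance in all groups; ",
            "all conditions share one letter")
    letts <- stats::setNames(rep("a", length(conds)), conds)
    aovP <- NA_real_
  } else {
    fit <- stats::aov(value ~ condition, data = values)
    aovP <- summary(fit)[[1]][["Pr(>F)"]][1]
    tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$condition
    for (i in seq_along(conds)[-1]) {
      for (j in seq_len(i - 1L)) {
        r <- paste0(conds[i], "-", conds[j])  # TukeyHSD row naming
        pm[conds[i], conds[j]] <- pm[conds[j], conds[i]] <- tk[r, "p adj"]
      }
    }
    letts <- .letterDisplay(pm < alpha)
  }
  out <- data.frame(condition = conds, letters = unname(letts[conds]),
                    stringsAsFactors = FALSE)
  attr(out, "metric") <- metric
  attr(out, "alpha") <- alpha
  attr(out, "method") <- "one-way ANOVA + Tukey HSD"
  attr(out, "pMatrix") <- pm
  attr(out, "anovaP") <- aovP
  out
}
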