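# literal per-pixel double-loop count of above-threshold changes between two
# frames; the independent oracle for computeActivity
bruteForcePairCount <- function(f1, f2, threshold) {
  cnt <- 0L
  for (i in seq_len(nrow(f1))) {
    for (j in seq_len(ncol(f1))) {
      if (abs(f2[i, j] - f1[i, j]) > threshold) cnt <- cnt + 1L
    }
  }
  cnt
}

# random small integer-valued stack (<= 16 x 16, <= 10 frames)
randomSmallStack <- function() {
  nr <- sample(2:16, 1)
  nc <- sample(2:16, 1)
  nf <- sample(2:10, 1)
  frames <- array(sample(0:255, nr * nc * nf, replace = TRUE),
                  dim = c(nr, nc, nf))
  imageStack(frames)
}

# draw a valid random parameter set within the ranges bracketing observed
# colonization kinetics
randomParams <- function() {
  twoPhaseParams(cIA = runif(1, 30, 400), cCA = runif(1, 0, 2000),
                 tx = runif(1, 1, 8), tp = runif(1, 3, 15),
                 tc = runif(1, 20, 120), tg = runif(1, 1, 10))
}

# two-sample permutation test on the difference of means (two-sided)
permutationP <- function(x, y, nPerm = 2000) {
  obs <- abs(mean(x) - mean(y))
  z <- c(x, y)
  nx <- length(x)
  hits <- 0L
  for (i in seq_len(nPerm)) {
    idx <- sample.int(length(z), nx)
    if (abs(mean(z[idx]) - mean(z[-idx])) >= obs - 1e-12) hits <- hits + 1L
  }
  (hits + 1) / (nPerm + 1)
}

# check a compact letter display against the pairwise significance matrix:
# two conditions share a letter iff their comparison is non-significant
lettersMatchSignificance <- function(comparison, alpha = 0.05) {
  pm <- attr(comparison, "pMatrix")
  conds <- comparison$condition
  lets <- strsplit(comparison$letters, "")
  names(lets) <- conds
  for (i in seq_along(conds)[-1]) {
    for (j in seq_len(i - 1)) {
      share <- length(intersect(lets[[conds[i]]], lets[[conds[j]]])) > 0
      signif <- pm[conds[i], conds[j]] < alpha
      if (share == signif) return(FALSE)
    }
  }
  TRUE
}
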