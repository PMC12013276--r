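# amoebaCA

Time-lapse activity quantification and two-phase colonization kinetics for
amoeba microcosms.

## What it is for

When dormant amoeba cysts (e.g. *Tetramitus*) are inoculated next to a
bacterial lawn and filmed at one frame every 30 s, the recording captures a
characteristic behavioral sequence: quiescence, an excystation/exploration
burst, and — on bacteria that support growth — a later logistic wave of
proliferation across the lawn. amoebaCA is for microbial-ecology and
behavior labs that want to turn such recordings (or precomputed activity
curves) into a small set of interpretable kinetic parameters and compare
them across bacterial conditions.

The measurement chain:

1. **Frame differencing** — per frame pair, count pixels whose absolute
   intensity change exceeds a threshold estimated from inactive image
   regions at the start of the recording (`mean + k·SD` of |ΔI|,
   default `k = 5`).
2. **Cumulative activity** — the running sum CA(t) of those counts, in
   activity units (AU).
3. **Two-phase fit** — bounded least squares of

   CA(t) = cIA·(1 − e^(−(t−tx)/tp))·1[t ≥ tx] + cCA / (1 + e^(−(t−tc)/tg))

   where cIA and cCA are the inoculum and colonization amplitudes, tx the
   excystation delay, tp the exploration decay time, tc the colonization
   half-plateau time and tg the growth time (inverse logistic rate). The
   derived readout is the relative colonization activity cCA/(cCA + cIA).
   Conditions with no colonization inside the recording window are
   censored: tc and tg are reported at the window end (">200" for a 200 h
   window) and relative colonization is 0.
4. **Replicate statistics** — per-condition mean ± SD tables and one-way
   ANOVA + Tukey HSD compact letter displays across conditions.

A synthetic-microcosm generator (noisy curves from known parameters, and
fully rendered image stacks of excysting, exploring and colonizing discs
with complete ground truth) makes the entire pipeline testable without any
external data.

## Worked example

Simulate one replicate of an *E. coli* OP50-like colonizing condition,
fit it, and inspect the parameters:

```r
library(amoebaCA)
op50 <- twoPhaseParams(cIA = 60.3, cCA = 800, tx = 5.6, tp = 9.6,
                       tc = 52.7, tg = 2.0)
sim <- sampleCurve(op50, seq(0, 200, by = 0.5), incrementCV = 0.1, seed = 1)
fit <- fitTwoPhase(sim$curve)
fit
#> TwoPhaseFit on 401 points over [0, 200 ] h
#> TwoPhaseParams: cIA = 62.31 AU, cCA = 810.6 AU
#>   tx = 5.482 h, tp = 10.49 h, tc = 52.75 h, tg = 1.951 h
#>   relative colonization: 0.929
#>   rmse: 0.9907 AU, R^2: 1 , converged: TRUE
```

With 10% increment noise the fit recovers the generating parameters
(tc 52.75 vs 52.7 h, tg 1.95 vs 2.0 h) and a relative colonization of
0.93 — nearly all activity comes from lawn colonization. Comparing a
colonizing against a non-colonizing (unseeded NGM-like) condition over
three replicates each:

```r
ngm <- twoPhaseParams(cIA = 88.9, cCA = 0, tx = 4.6, tp = 9.3,
                      tc = 300, tg = 5)
fits <- list(
  NGM  = lapply(1:3, function(s)
    fitTwoPhase(sampleCurve(ngm, seq(0, 200, 0.5), 0.1, seed = s)$curve)),
  OP50 = lapply(4:6, function(s)
    fitTwoPhase(sampleCurve(op50, seq(0, 200, 0.5), 0.1, seed = s)$curve)))
do.call(rbind, lapply(names(fits), function(nm)
  aggregateFits(fits[[nm]], nm)))[, c("condition", "metric", "n", "display")]
#>    condition          metric n               display
#> 1        NGM             cIA 3     88.8052 ± 1.39144
#> 2        NGM relColonization 3                 0 ± 0
#> 3        NGM              tx 3   4.64215 ± 0.0171398
#> 4        NGM              tp 3    9.23393 ± 0.178939
#> 5        NGM              tc 3                  >200
#> 6        NGM              tg 3                  >200
#> 7       OP50             cIA 3      60.785 ± 0.12228
#> 8       OP50 relColonization 3 0.928856 ± 0.00139017
#> ...
```

The NGM condition is censored (tc and tg rendered ">200", relative
colonization exactly 0), and `compareConditions()` assigns the two
conditions disjoint letters (`a` vs `b`): their relative colonization
differs significantly at α = 0.05.

The image-level path is the same, starting from a stack:

```r
sim  <- renderStack(sceneSpec(), seed = 1)     # 128x128, 2400 frames, 20 h
thr  <- estimateThreshold(sim$stack)           # inactive-region threshold
act  <- computeActivity(sim$stack, thr)        # per-pair pixel counts
fit  <- fitTwoPhase(cumulateActivity(act))     # two-phase kinetics
```

A thin command-line wrapper with `simulate`, `quantify`, `fit` and
`report` subcommands lives at `inst/scripts/amoebaca.R`.

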