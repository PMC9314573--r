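# rqasync

Multilevel physiological synchrony from cardiac interbeat intervals (IBIs),
for researchers in psychophysiology and group dynamics. `rqasync` implements
multidimensional recurrence quantification analysis (MdRQA) of triads at the
group level (all three members analysed jointly) and the individual level
(each member's two dyads, averaged), a z-composite *Vertical Synchrony*
measure, its task-minus-baseline change **ΔSync**, false-pair surrogate
testing with exact Wilcoxon signed-rank contrasts, and mixed-effects models
predicting group cohesion from ΔSync. A synthetic-data generator with known
coupling and effect sizes makes the whole pipeline testable end to end
without any participant data.

## The method in brief

Members' trimmed IBI series form the columns of a multivariate series that is
delay-embedded (dimension *m*, delay *d*) into a joint phase space. Two time
points *recur* when their Euclidean distance is at most a radius *r*; the
binary recurrence plot (main diagonal included, threshold inclusive) yields

- **%REC** = 100 · (recurrent cells) / N² — raw repetition;
- **%LAM** = 100 · (recurrent cells with a vertical neighbour) / (recurrent
  cells) — intermittent, patch-like coupling;
- **meanV**, **maxV** — mean and maximum vertical line length (runs ≥ 2
  beats).

Default embedding parameters are fixed sample-wide: *d* = 2, *m* = 7,
Euclidean norm, no normalisation, *r* = 0.457 (dyads) / 0.51 (triads); the
radius can be recalibrated so the sample-mean %REC lands in the 1–5% band.
%LAM, meanV and maxV are combined per level × phase into the Vertical
Synchrony z-composite, and ΔSync = composite(task) − composite(baseline).
Cohesion (1–6 scale) is then modelled as

    cohesion_ij = γ00 + u0j + γ10·ΔSync + γ20·Condition + γ12·(ΔSync×Condition) + ε_ij

with a random intercept per triad, F tests with between–within denominator
degrees of freedom, and a likelihood-ratio test comparing individual- vs
group-level predictors. See `vignette("methods")` for assumptions, parameter
rationale, and design decisions.

## Worked example

The toy calculation that fixes all conventions — three members, four beats
each, no embedding (*m* = 1), radius 3:

```r
library(rqasync)

x <- cbind(x1 = c(1, 1, 2, 25), x2 = c(1, 1, 3, 40), x3 = c(1, 1, 1, 99))
traj <- delay_embed(x, m = 1, d = 1)   # 4 joint phase-space coordinates
round(distance_matrix(traj), 1)
#>       [,1]  [,2]  [,3]  [,4]
#> [1,]   0.0   0.0   2.2 108.2
#> [2,]   0.0   0.0   2.2 108.2
#> [3,]   2.2   2.2   0.0 107.2
#> [4,] 108.2 108.2 107.2   0.0

recurrence_measures(recurrence_matrix(distance_matrix(traj), r = 3))
#> %REC = 62.500, %LAM = 90.000, meanV = 3.000, maxV = 3
```

Coordinates 1 and 2 coincide and coordinate 3 is within radius 3 of both, so
10 of the 16 cells recur (62.5%); 9 of those 10 sit in the three vertical
3-runs of columns 1–3 (%LAM = 90), and the isolated point at (4, 4) is not a
line, leaving meanV = maxV = 3.

A full synthetic study and the downstream stages:

```r
study <- generate_study(sim_config(seed = 1))   # 87 triads, 261 participants
sur   <- false_pair_surrogates(study$groups, seed = 2)
stab  <- sync_table(sur, study$params$dyad, study$params$triad, levels = "group")
run_contrasts(study$sync, stab)                 # real vs surrogate, task vs baseline

ind <- subset(study$deltas, level == "individual")
fit <- fit_cohesion_model(study$cohesion, ind)  # mixed model on cohesion
fit$anova
```

A command-line entry point mirrors the pipeline:
`simulate`, `estimate-params`, `rqa`, `sync`, `surrogate`, `fit`
(see `?rqasync_cli`).

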