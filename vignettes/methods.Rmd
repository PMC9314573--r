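---
title: "Multilevel IBI synchrony with MdRQA: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel IBI synchrony with MdRQA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rqasync)
```

## The problem

When three people interact, their cardiac interbeat intervals (IBIs) can
become coordinated. `rqasync` quantifies this physiological synchrony with
multidimensional recurrence quantification analysis (MdRQA) at two levels —
the triad as a single dynamical system, and each member through their two
dyads — and relates the *change* in synchrony from a quiet baseline to the
group task (delta synchrony, ΔSync) to self-reported group cohesion with a
mixed-effects model. Because no participant-level data are distributed with
the package, a synthetic-data generator with known coupling and effect sizes
stands in for the recordings, and every downstream stage is tested against it.

## Recurrence quantification

Given the members' trimmed IBI series as columns of an `N × D` matrix, the
series is delay-embedded (dimension `m`, delay `d`): point *t* concatenates
rows *t*, *t + d*, …, *t + (m−1)d*. Two time points recur when their Euclidean
distance is at most a radius `r` (inclusive). From the binary recurrence plot
we report:

* `%REC` — recurrent cells / N², the raw amount of repetition;
* `%LAM` — recurrent cells with a vertically adjacent recurrent cell, over all
  recurrent cells: patch-like, intermittent coupling;
* `meanV`, `maxV` — mean and maximum vertical run length (runs ≥ 2 beats).

Two conventions are fixed deliberately and differ across the RQA literature:

* **The main diagonal (line of identity) is included**, with no Theiler
  window. Only this convention reproduces the package's worked toy example
  (`%REC = 62.5` on the 4 × 4 plot, i.e. 10/16 cells, and `meanV = maxV = 3`),
  and it retains auto-recurrence information in the vertical structures.
* **Thresholding is inclusive (`≤ r`)** — immaterial for the toy example but
  fixed for reproducibility.
* **Minimum vertical line length is 2**: the isolated recurrent point at
  (4, 4) of the toy plot must not count as a length-1 line, otherwise
  `meanV` would drop below 3.

Distances are kept at full precision internally; 1-decimal rounding is a
display concern only. The pipeline's fast path computes squared distances via
cross-products, which is numerically equivalent to the explicit distance
matrix (clamped at zero) and is tested for exact agreement with a naive
double-loop implementation.

## Embedding parameters

The shipped defaults are the fixed sample-wide parameters used for this kind
of IBI analysis: delay 2, embedding dimension 7, Euclidean norm, no input
normalisation, radius 0.457 for dyads and 0.51 for triads (seconds of the
embedded space). When these defaults are used no estimation is run. The
estimation tools exist for re-deriving parameters on new data:

* **Delay**: first local minimum of the multivariate average mutual
  information (AMI). The estimator is an equal-width joint histogram with
  `ceiling(sqrt(N))` bins per axis, averaged over the series' columns; the
  source method cites an external toolbox without algorithmic detail, so the
  binning rule is this package's choice. Ties at a plateau break toward the
  smaller lag; a curve with no interior minimum falls back to the global
  minimum over lags ≥ 1, with a warning.
* **Dimension**: false-nearest-neighbour (FNN) fractions with Kennel-style
  criteria, `rtol = 10` and `atol = 2` (defaults; the source method names no
  thresholds). "Bottoming out" is operationalised as the smallest `m` whose
  decrease to `m + 1` is ≤ 0.01, or whose fraction is already below 0.05,
  whichever comes first.
* **Pooling**: per-group estimates are averaged over the sample and rounded to
  the nearest *higher* integer (ceiling) — "higher" distinguishing it from
  ordinary rounding — so one common, sufficiently large parameter pair serves
  every group.
* **Radius**: searched on an explicit ascending grid (default 0.05–1.00 in
  steps of 0.005) for the smallest value whose across-dataset mean `%REC`
  falls in the 1–5% band. `%REC` is monotone non-decreasing in `r`, so the
  smallest such grid value is well defined; if the grid jumps over the band an
  error reports the bracketing values. Estimation and calibration use
  task-phase data by default (the phase actually analysed for synchrony); this
  is configurable because the original choice is not documented.

## Levels, composite, and ΔSync

*Group level*: one MdRQA of the 3-column series, members trimmed to the
group-wide shortest length (excess beats removed from the end only).
*Individual level*: the three dyadic analyses — each pair trimmed within
itself, not to the triad minimum — and each member scored as the
measure-by-measure mean of their two dyads.

Because `%LAM`, `meanV` and `maxV` are strongly collinear on this kind of
data, they are combined into a *Vertical Synchrony* composite: within each
level × phase stratum the three measures are z-scored across the real
(non-surrogate) units and averaged per unit. Surrogate units are standardised
against the real-unit mean and SD — the standardisation stratum is not
documented in the source method; scoring surrogates on the real scale keeps
them comparable without letting them distort it. ΔSync is computed
composite-first: `ΔSync = composite(task) − composite(baseline)`, per unit.

*False-pair surrogates* estimate chance-level recurrence: each pseudo-triad
draws its three members from three distinct real groups (without replacement
within a pseudo-triad, with replacement across pseudo-triads), keeps both
phases intact, is re-trimmed internally, and is analysed with the same
parameters as real groups. The surrogate count defaults to the real-group
count so that signed-rank contrasts pair 1:1 by enumeration order; neither the
count nor the pairing rule is documented in the source method.

## Inference

The paired contrasts (task real vs surrogate, task vs baseline, baseline real
vs surrogate, all on group-level `%REC`) use a Wilcoxon signed-rank test
reporting the classical `T` (the smaller rank sum). Zero differences are
dropped, tied absolute differences get average ranks, and for fewer than 26
informative pairs the null distribution of the rank sum is computed exactly by
convolution of the per-pair generating functions — identical to enumerating
all 2^n sign assignments, ties included; larger samples use the normal
approximation with tie and continuity corrections.

Cohesion (mean of four 1–6 Likert items) is modelled as

cohesion_ij = γ00 + u0j + γ10·ΔSync + γ20·Condition + γ12·(ΔSync×Condition) + ε_ij

with a random intercept per triad and condition as a single 4-level factor
pooling both studies (that coding is what makes the condition term a 3-df
test). Fitting is REML via `lme4`. Sum-to-zero contrasts make the marginal
(type-III style) F tests well defined with the interaction present. Degrees
of freedom use the **between–within (containment)** rule: terms constant
within groups are tested against the group stratum (e.g. 87 − 7 − 1 = 79
denominator df for the group-level ΔSync model), terms varying within groups
against the residual stratum. A Satterthwaite approximation was the original
intent, but no Satterthwaite machinery for `lmer` fits is available in the
supported environment and the containment rule reproduces the reference
denominator df for the group-level model exactly; simulation shows the
resulting slope test holds its nominal 5% size. Marginal R² is
`var(Xβ) / (var(Xβ) + τ² + σ²)` (fixed-effects variance over total).

Level comparison refits both models by maximum likelihood (REML log-likelihoods
are not comparable across fixed-effect structures) and reports the
likelihood-ratio χ² for adding the group-level ΔSync to the individual-level
model. When the added predictor is exactly collinear it is dropped and the
statistic is ~0 with 0 df.

An optional random intercept per *study* (instead of per triad) is exposed
(`random = "study"`) because the original description of the random factor is
ambiguous; per-triad intercepts are the default. Random slopes are not
implemented beyond this option. Two-sided tests and α = 0.05 throughout.

## The synthetic world

`sim_config()` states the world the tests run in: 87 triads in 2 studies × 2
conditions (23/22/21/21), 280–400 beats per participant-phase (~5 minutes at
0.75–0.95 s mean IBI, drawn per participant), member fluctuations an AR(1)
with φ = 0.8 and innovation SD σ = 0.02 s (stationary SD ≈ 0.05 s, a realistic
HRV scale), and a latent AR(1) driver (coefficient 0.9, unit stationary
variance) shared within a group-phase.

**How coupling enters** was the one genuinely open design decision. An
additive driver term inflates task-phase variance, and with a single
sample-wide radius the lower-variance baseline phase then saturates the
recurrence plot — baseline `%REC` ≈ 90% against ~1% during the task, inverting
every expected contrast; we measured exactly that. Real task engagement
restructures heart-rate variability toward the common driver rather than
amplifying it, so the generator couples *variance-preservingly*:

IBI_t = μ_i + s_X · (X_t + κ_p·Z_t) / sqrt(s_X² + κ_p²)

with `s_X` the member's stationary fluctuation SD. κ (0 at baseline, 0.15
during the task by default) is the driver's amplitude relative to the member's
own fluctuations; at the defaults the implied intermember correlation is
κ²/(κ² + s_X²) ≈ 0.90 during the task and 0 at baseline, while the marginal
IBI variance is identical across phases. Series lengths are drawn per
participant-phase specifically so the trimming path is always exercised. A
0.05 s floor guarantees strictly positive IBIs (it essentially never binds at
the default scale). One global seed drives everything; per-triad and
per-purpose sub-seeds are derived by a fixed affine step so a single triad can
be regenerated in isolation.

Cohesion is generated per participant as γ00 + condition effect + β·ΔSync +
group intercept + noise, clipped to the 1–6 instrument range, with defaults
γ00 = 3.5 (the instrument midpoint, keeping clipping negligible), β = 0.5
cohesion units per ΔSync unit, condition offsets (0, 0.2, −0.2, 0.1) — small
against the 1–6 scale, as condition effects on cohesion typically are —
τ = 0.3 and residual SD 0.5. The ΔSync values used are the *measured*
pipeline outputs, so parameter-recovery tests exercise the whole chain, not
just the linear model.

**What the generator does not emulate**: respiratory sinus arrhythmia and
other structured HRV rhythms, ectopic beats and artifacts (the real
preprocessing removes these manually), point-process (IPFM-style) beat
generation, non-stationarity within a phase, and item-level questionnaire
structure. A green test therefore establishes that the pipeline recovers
known coupling and known effect sizes from data with the right first- and
second-order structure — not that it would be robust to every artifact of
real recordings.

## Numerical choices and degenerate inputs

* Trimming requires ≥ 2 non-empty series; it never alters values.
* Groups without exactly 3 members or missing a phase are excluded with a
  warning (never imputed), and baseline/task segments are trimmed
  independently per phase — whether the original analysis trimmed phases
  jointly is undocumented.
* Constant series make AMI (zero entropy) and FNN (zero attractor size)
  errors, not silent zeros; a dataset of identical coordinates recurs at 100%
  for every radius and makes calibration fail loudly.
* Composite standardisation refuses zero-variance measures, naming the
  measure.
* `beat_index` is 0-based and all internal slicing is half-open.
* The exact signed-rank null is used below 26 pairs (the convolution handles
  ties); beyond that the normal approximation with continuity correction.
* LRT statistics are floored at 0 (they can dip below by solver tolerance).

## Known limitations

* Only vertical-line measures are implemented — no diagonal measures (DET,
  meanL, ENTR), no windowed RQA, no cross-recurrence between groups.
* Only the Euclidean norm and a single fixed radius per level; no per-group
  adaptive radii or fixed-recurrence-rate thresholding.
* Denominator df are containment-based, not Satterthwaite; for very
  unbalanced designs the within-stratum df can be liberal.
* The generator's coupling is a single shared driver; leader–follower
  structure and directionality are out of scope.
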