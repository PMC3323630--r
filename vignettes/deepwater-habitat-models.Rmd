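---
title: "Modelling deep-water benthic habitats and lobster distribution from bathymetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling deep-water benthic habitats and lobster distribution from bathymetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`benthoscape` implements a hierarchical species-distribution workflow for
deep-water (45–80 m) temperate shelf habitats: terrain derivatives are
computed from a fine-resolution bathymetry grid, deviance-based binary
classification trees predict substrate classes from terrain, benthic biota
from terrain plus substrate, and finally the presence of western rock
lobster (*Panulirus cygnus*) in baited pots from the full predictor pool.
Because raw multibeam, towed-video and pot-survey data of this kind are
rarely deposited, the package ships a seeded synthetic seascape generator
that reproduces the statistical structure the analysis assumes, so every
stage is testable end to end.

## The terrain predictor stack

All models draw on twenty co-registered layers derived from one depth
raster (positive-down metres, 3 m cells by default):

* **DTH** — depth itself; **DETRND** — depth minus a least-squares plane
  fitted to all valid cells, exposing local relief free of the shelf
  gradient. Detrending is idempotent and leaves a zero-mean residual.
* **SLP**, **ASP** — Horn 3×3 slope (degrees) and aspect (degrees clockwise
  from north, direction of steepest descent). Flat cells get nodata aspect,
  because 0° would alias a north-facing slope.
* **PROFCURV**, **PLANCURV**, **CURV** — Zevenbergen–Thorne curvatures
  (1/m), convex-up positive, with `CURV = PROFCURV − PLANCURV`. These are
  computed on the *detrended* surface: their purpose is local shape, which
  the regional depth gradient would otherwise contaminate. Slope, aspect
  and surface area are computed on raw depth, where the gradient
  contributes only ~0.005 m/m at the study scale.
* **SURFA** — true surface area (m²) of the cell's 3×3 neighbourhood by the
  Jenness eight-triangle construction, normalised to one cell footprint;
  ≥ the planar area, with equality iff locally flat.
* **F7S**, **F21S**, **F21M** — focal standard deviation (7 m, 21 m) and
  mean (21 m) of SURFA: multiscale rugosity.
* **HYP5/10/25**, **RNG5/10/25**, **STD5/10/25** — hypsometric index, relief
  range and standard deviation of depth over circular kernels of 12.5, 25
  and 62.5 m radius.

Kernels are defined by cell-centre distance ≤ radius; the numeric suffix of
a layer code is a kernel label, not the radius. The hypsometric index is
the relief-normalised position of the focal cell,
`HI = (z_max − z_focal)/(z_max − z_min)` with depth positive-down, so 1
marks a local high and 0 a local low; a flat kernel returns 0.5 by
convention. This formula is one of several verbal definitions in use; it
was chosen because it is bounded, unitless and symmetric, and it is pinned
by brute-force oracle tests.

Edge policy: 3×3 operators use replicate padding, and kernel statistics are
taken over the cells actually available, so every layer has full coverage;
the standard deviation is nodata only when fewer than three valid cells
fall in the kernel. Kernel variances are computed after centring the layer
on its global mean, which keeps a constant layer at exactly zero.

## Classification trees

The response of every model is binary presence/absence of one class
(one-vs-rest). A node holding counts `(n0, n1)` has multinomial deviance
`D = −2·(n0·ln(n0/n) + n1·ln(n1/n))` (natural log, `0·ln 0 = 0`). Splitting
searches every predictor and every midpoint between consecutive distinct
values for the largest deviance reduction, with ties broken toward the
predictor declared first and then the smaller threshold; rows with
`x < threshold` go left.

Growth stops by the classic S rules (all exposed in `growth_control()`): a
node is split only if it holds ≥ 10 observations, its deviance is ≥ 0.01 of
the root deviance, each child would receive ≥ 5 observations, *and* the
split's deviance reduction is ≥ 0.01 of the root deviance. The last gate is
easy to miss — the classic engine applies it even though its documentation
only mentions the node-deviance rule — and with it the grown trees match
`tree::tree()` exactly (leaf counts and training probabilities), which the
suite uses as an independent cross-check.

Pruning is deviance-based weakest-link cost-complexity: the nested subtree
sequence is scored by 10-fold cross-validated misclassification (the tree
is regrown on each fold complement and pruned to each candidate
complexity), and the smallest subtree with mean CV misclassification ≤ 15%
is selected. The 15% threshold is only applied when it is *binding*: for a
class rarer than 15% the trivial always-absent tree already meets it, and a
literal reading would collapse every rare-class model to a single leaf. In
that case — and when no subtree meets the threshold — the CV-minimising
size is used, with ties to the smaller tree.

Model fit is summarised by adjusted explained deviance,
`AdjD² = 1 − ((n−1)/(n−p))·(1 − D²)` with `p` the number of leaves.
Evaluated on validation data a row may land in a leaf that is pure for the
opposite class; the evaluated log-probability is floored at `ln(1e−3)` so
the statistic stays finite while pure leaves predicting their own class
still contribute exactly zero. Variable importance is reported two ways,
because they answer different questions: the per-variable share of the
summed split reductions (`variable_contribution()`, the contribution-table
view) and the drop in AdjD² on refitting without a predictor
(`drop_term()`, which exposes redundancy that split shares hide).

## Evaluation

`roc()` computes sensitivity and specificity over all distinct scores (plus
one threshold above the maximum, presence predicted when
`score ≥ threshold`), and the AUC by the trapezoid rule, which equals the
tie-corrected Mann–Whitney statistic. Confidence intervals are percentile
2.5/97.5 over 1000 stratified bootstrap resamples (within-class resampling
keeps both classes present; the replicate count is a package default, as
the original tooling does not state one). The classification threshold
**P_fair** minimises `|sensitivity − specificity|`, with ties resolved
toward higher sensitivity and then the lower threshold; binary maps use
`probability ≥ P_fair`, so a cell exactly at the threshold maps to
presence.

## Spatial dependence

`indicator_semivariogram()` is the omnidirectional empirical semivariogram
of a 0/1 indicator, `γ(h) = Σ(I_i − I_j)²/(2N(h))` over unordered pairs
binned by separation; an independent indicator with prevalence q is flat at
q(1−q). Defaults: bin width one fifteenth of the maximum lag, maximum lag
half the domain diagonal.

`spatial_split()` tiles the domain into square blocks and assigns whole
blocks to validation (seeded order) until the holdout fraction is reached,
optionally dropping model points in blocks adjacent to validation blocks
(a one-block buffer, guaranteeing a minimum separation). The pipeline's
spatially independent lobster evaluation uses 250 m blocks *without* the
buffer: at the package's 1 km² working scale a buffered split leaves too
few training pots to fit anything but single-leaf trees, which would say
nothing about spatial dependence. On study domains tens of km² the buffer
is the better choice and is a single flag away.

## The synthetic seascape and what it does (not) emulate

`seascape_params()` defaults describe the package's reference conditions: a
1 km² domain at 3 m cells, depth running 45→80 m offshore (+x), a 5 m
Gaussian reef ridge striking north–south (σ = 120 m), ~40 rugose patches
per km² (Gaussian envelopes, σ = 25 m, 1 m relief inside), 0.15 m white
sounding noise and an optional sinusoidal boat-motion striping artifact.
Substrate labels follow planted quantile rules — hard ground where the
seafloor is shallower than the local trend and rough at fine scale, graded
obscured→flat→low→medium→high reef by F7S, rhodolith beds at local lows on
soft ground — with thresholds derived so class frequencies match the towed
video tally shipped in `inst/extdata/` (rhodolith most prevalent at ~32%,
under 7% of frames above 1 m relief). Biota follow depth rules: kelp
(*Ecklonia*) on hard ground shallower than 60 m, sessile invertebrates on
hard ground deeper than 65 m, other macroalgae elsewhere on consolidated or
rhodolith ground. Labels get 10% symmetric reassignment noise by default.

Pot catches are Poisson: `count ~ Pois(mean_catch · e^s)` per pot-year,
where the planted signal `s` is a linear combination of standardised
terrain layers (defaults: DETRND −3, F7S +3, RNG25 +1.5, HYP5 +1.5)
clamped to `[−4, 1.5]`. The clamp has an ecological reading — attraction to
a baited pot saturates at a couple of lobsters per lift, while genuinely
unsuitable ground is empty — and a statistical one: terrain derivatives are
heavy-tailed, and an unclamped log-linear rate produces absurd catches
inside rugose patches. With the default `mean_catch = 0.5` the pooled
three-year count histogram is dominated by zeros and ones, and habitat
quality is effectively bimodal, which is what a *strong* planted signal
must mean for a presence/absence model to be able to recover it. The
default pot grid keeps the survey's 11 lines × 30 pots but compresses
spacing to 30 m along-line / 90 m between lines so the 330 stations fit
the 1 km² domain; `make_pot_grid()` alone defaults to the full 400 m
design.

What the generator does **not** emulate: positional error in towed-video
georeferencing, observer disagreement structure (label noise is symmetric
and independent), multi-year dynamics (the rule is static; only Poisson
draws differ between years), tidal/datum effects, and acoustic artifacts
beyond simple striping. Passing tests therefore demonstrate that the
machinery recovers known structure under clean assumptions — not that real
surveys meet those assumptions.

## Problem sizes and reproducibility

The reference analyses run at the 1 km² / 1000-frame / 330-pot scale, which
keeps a full pipeline run (twenty terrain layers on a 333×333 grid, ten
cross-validated models, maps and semivariograms) in the tens of seconds,
and the 20-seed recovery study in a few minutes. Every random stage draws
from a substream derived from one scenario seed by fixed offsets
(bathymetry +0, substrate +2, biota +3, catch +5, frame split +6, CV folds
+7, bootstrap +8, spatial blocks +9, pot split +10), so stages are
independently reproducible and a rerun with the same configuration writes
byte-identical reports. The 75/25 split uses `round()` (round-half-even),
so 3122 records give 2342/780.

The recovery study (`recovery_study()`) sets every noise source to zero —
label noise and sounding noise — and checks three things across seeds:
that the pruned lobster tree retains only geophysical predictors (no
substrate or biota indicator survives pruning), that the random-holdout
AUC recovers the planted signal, and that a spatially independent holdout
does not outperform the random one. A caveat worth stating: with 330 pots,
a validation fold holds ~82 pots, so a single seed's AUC carries a
standard error of roughly 0.04, and misclassification-pruned trees often
keep only a handful of leaves, which caps the resolution of the
probability ranking that the AUC measures. Medians across seeds are the
honest summary at this scale.

## Known limitations

* One raster format (ESRI ASCII grid, bit-exact round-trip); no
  reprojection or datum handling — inputs must already be projected metres.
* Binary responses only; the multiclass map is assembled from one-vs-rest
  models by argmax over classes that clear their own P_fair (cells clearing
  none are `unclassified`) — a documented choice, since integrated mapping
  rules are rarely stated precisely in the literature this workflow
  follows.
* No surrogate splits: rows with missing predictors are excluded.
* The semivariogram is omnidirectional; anisotropy in a striped or ridged
  seascape will be averaged over.
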