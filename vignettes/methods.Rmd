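---
title: "A stochastic vertex model of epithelial junction fluctuations: model, calibration and analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: model, calibration and analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(vertexflux)
```

## The model

`vertexflux` simulates a two-dimensional apical epithelium as a polygonal
mesh on a periodic box.  Vertices move overdamped,

$$\alpha\,\frac{dx_i}{dt} = f_i = -\frac{\partial E}{\partial x_i},
\qquad
E = \sum_{\text{edges}} \gamma_{ij}\, l_{ij}
  + \sum_{\text{cells}} \frac{K}{2}\,(A_c - A_{0,c})^2 ,$$

with line tensions $\gamma_{ij}$ acting along cell-cell junctions and a
cell-area elasticity constraining each apical area $A_c$ to a preferred
value $A_{0,c}$.  Tensions fluctuate as Ornstein-Uhlenbeck processes
around per-junction reference tensions,

$$\frac{d\gamma_{ij}}{dt} = -\frac{1}{\tau_m}(\gamma_{ij}-\gamma^0_{ij})
 + \xi_{ij},\qquad
 \langle\xi_{ij}(t)\,\xi_{kl}(t')\rangle =
 \frac{2\sigma_i^2}{\tau_m}\,\delta(t-t')\,\delta_{ik}\delta_{jl},$$

so each junction's tension has stationary SD $\sigma_i$ and persistence
time $\tau_m$.  Extrinsic (junction-to-junction) heterogeneity enters
through per-cell tension draws from a normal distribution with mean
$\gamma$ and SD $\sigma_e$ truncated at zero; the reference tension of a
junction is the mean of its two flanking cells' draws.  Tensions are
clipped at zero (clip events are counted in the run metadata).  When a
junction shrinks below the threshold length `l_T1` it is flipped: a new
junction of length `l_new` is created at right angles through the old
midpoint and the four cells exchange neighbours (a T1 transition).  The
new junction's reference tension is recomputed from its new flanking
cells and its instantaneous tension restarts there; the collapsed edge's
noise history is deliberately not inherited.

## Parameters and units

Lengths are measured in the characteristic cell length $l$ (preferred
areas have mean $1\,l^2$), tensions in the mean line tension $\gamma$,
time in minutes.  Defaults (`model_params()`):

| parameter | default | origin |
|---|---|---|
| packing time $\tau_p=\alpha l/\gamma$ | 4.4 min | measured junction response time |
| tension/area-elasticity ratio $\gamma/(K l^3)$ | 0.025 ($K=40$) | reported calibration |
| preferred-area SD $\sigma_A$ | 0.19 $l^2$ | reported calibration |
| tension persistence $\tau_m$ | 2.2 min | measured intensity decorrelation time |
| intrinsic/extrinsic ratio $\sigma_i/\sigma_e$ | 0.08/0.13 | measured intensity CoVs |
| extrinsic spread $\sigma_e$ | 0.25 $\gamma$ | calibrated to the measured T1 rate (below) |
| T1 threshold `l_T1` | 0.05 $l$ | convention; `l_new` $=1.5\,$`l_T1` |
| time step `dt` | 0.02 min | $\ll \min(\tau_m,\tau_p)$ |

**Why $\sigma_e$ is the calibration knob.**  The published description of
this model reports an extrinsic spread of order the mean tension
($\sigma_e \simeq \gamma$) *and* a wild-type neighbour-exchange rate of
$8.5\times10^{-4}$ events/min/junction.  In the energy functional above
(line tension + area elasticity only, no perimeter contractility) these
two numbers are mutually exclusive: with $\sigma_e \simeq \gamma$ the
tissue is deep in a liquid-like regime and exchanges neighbours at
$\sim5\times10^{-2}$ events/min/junction for *every* admissible threshold
`l_T1` between 0.01 and 0.1 $l$ (we measured this directly; the rate is
threshold-insensitive because collapses are mechanically committed well
above the threshold).  The reference implementation therefore very likely
contained an additional stabilising term (its cited predecessors include
perimeter elasticity), which is out of scope here.  We keep the measured
*ratio* $\sigma_i/\sigma_e = 0.08/0.13$ and calibrate the *magnitude*
$\sigma_e$ so that the wild-type simulation reproduces the measured rate
— which is precisely the fitting step the original work describes
("adjusting the magnitude of fluctuations").  The calibrated value is
$\sigma_e = 0.25\,\gamma$, with the threshold left at its
conventional default.  Everything downstream (tension-length
anticorrelation with tension leading by $\sim$1 min, rate and order
trends with mean tension) follows without further adjustment.

## Initialization and steady state

Runs start from a regular honeycomb or from a periodic Voronoi
tessellation of uniform random points, are relaxed to mechanical
equilibrium with uniform tensions and no noise (adaptive step capping),
then receive their preferred-area and tension draws and a 20-min burn-in
before statistics are collected.  Preferred areas are rescaled to sum to
the box area, since the periodic tiling fixes the mean cell area.

Two caveats a user should know:

* At the wild-type calibration the T1 rate is low, so topological
  relaxation is slow: a honeycomb start stays close to hexagonal order
  over an 80-min window while a relaxed Voronoi start keeps its higher
  disorder.  The initialization-independence of the steady state is
  therefore exercised in the strongly fluctuating regime
  ($\sigma_e = 1.07\,\gamma$), where the tissue mixes within the
  simulated window and both starts converge to the same disorder within
  replicate SD.
* For the mean-tension sweep the honeycomb start is used: it approaches
  each steady state from the ordered side, so the finite window does not
  invert the ordering trend (from a disordered start the high-tension
  runs cannot anneal within the window and the hexagon-fraction trend
  reverses).

## Summary statistics

All coefficients of variation and the topological disorder (SD of
per-cell neighbour counts) use the population (divide-by-$n$)
convention.  Correlation functions follow the printed conventions: the
autocorrelation of a junction's intensity is
$(\overline{I(t)I(t+\Delta t)} - \bar I^2)/\bar I^2$ with $\bar I$ the
junction's own temporal mean; the cross-correlation of two per-junction
series subtracts each junction's temporal mean and normalizes by the two
per-junction population SDs; curves are computed per junction and then
averaged.  A positive lag of the cross-correlation extremum means the
first series leads.

Exponential fits use `nls`.  One estimator detail matters: computing the
autocorrelation with each junction's *finite-series* mean introduces a
small negative constant bias (about $-CV^2\,S/n$, where $S$ is the
summed autocorrelation and $n$ the number of frames; about $-7\%$ of the
lag-0 value at the default observation design).  Fitted naively, this
shortens the recovered decorrelation time by $\sim$30%.
`fit_exp_decay(curve, offset = TRUE)` fits $y = a e^{-bx} + c$ so the
constant absorbs the bias; the trace-calibration recovery uses this form
and reports $1/b$.  Because the constant is partially degenerate with a
slow decay, the recovery fits over lags up to 6 min (where the signal
dominates the offset) and averages the correlation curve over 20
independent ensembles; this brings the estimator to $2.24 \pm 0.06$ min
for a generator persistence of 2.2 min (measured over 10 disjoint seed
sets).

## The synthetic world

`synth_traces()` emulates the measured per-junction intensity series:
per-junction mean levels with extrinsic CoV 0.13 (truncated normal, unit
grand mean), stationary OU fluctuations with temporal CoV 0.08 and
persistence 2.2 min, sampled exactly (AR(1)) on a 30-s grid, 333
junctions and 120 frames by default.  Under independence the snapshot
CoV combines as $\sqrt{0.13^2+0.08^2}\approx0.15$.

`rasterize_movie()` draws simulated tissues as the segmentation pipeline
expects them: 1-pixel-wide junction skeletons (8-connected Bresenham
lines, default 25 px per $l$), an intensity channel in which junctions
are dilated to 7 px with brightness proportional to instantaneous
tension, brighter vertices (factor 1.5 by default), global exponential
bleaching, additive Gaussian noise and integer-pixel drift.  Junctions
crossing the periodic seam appear as border-touching chains — the
pipeline flags and excludes them, as it does at real image borders.
What a green round-trip test establishes is that parsing, tracking and
event detection recover the simulator's ground truth; it does *not*
establish robustness to segmentation errors, uneven illumination,
point-spread blur or rosettes, none of which the generator emulates.

One event-aligned observation worth knowing: in pooled wild-type
profiles the five-junction total length is slightly *elevated* (by a few
percent of its magnitude) around the four-way vertex rather than
depleted.  Exchanges occur preferentially while the quartet is
transiently stretched -- a selection effect, visible here because
simulated lengths are noise-free.  The conservation claim (no transient
loss of junctional length through the exchange, unlike a stepwise
remove-then-regrow process) holds: the total never dips by more than a
small fraction of the focal junction's excursion.

## The tracking pipeline

Skeleton frames are parsed by walking 8-connected chains between
vertices (pixels with $\ge 3$ skeleton neighbours, adjacent vertex
pixels clustered to their centroid).  Junction length uses the
block-decomposition rule: maximal axis-aligned pixel runs contribute
their straight spans and consecutive blocks are connected by their
diagonal distances; the published description of this rule is loose, and
the implementation here is one consistent reading validated against
constructed chains (collinear, diagonal, and corner-sharing L-shapes).
Drift is removed by integer-pixel phase correlation of whole frames
(only the net translation is used downstream).  Junctions and cells are
tracked by matching midpoints between frames, minimizing total squared
displacement under a 10-px cutoff; candidate pairs are split into
connected components and each component is solved exactly by branch and
bound (components beyond 12 points fall back to greedy with a warning).
T1 events require a contraction to the four-way-vertex scale (6 px by
default), re-expansion with a disjoint pair of flanking cells, and
stability of the new pair for 4 frames (2 min at 30-s cadence) — the
codified form of the published manual validation; contractions that
re-expand unchanged are counted as near misses.  A junction may vanish
into the four-way vertex for up to 10 frames before re-expanding
(four-way vertices pause for minutes in this system).  Intensity measurement
dilates each chain to 7 px, excludes disks around vertices, normalizes
each frame so the mean per-pixel intensity over dilated junctions is 1
(bleaching correction), and divides each junction's total by its pixel
count.

Reversibility is summarised per quartet of cells with the Kaplan-Meier
estimator (`survival`): the first exchange opens the clock, a later
exchange whose losing pair equals the first's gaining pair closes it,
otherwise the quartet is right-censored at the end of observation.

## Numerical choices and degenerate inputs

* Explicit Euler / Euler-Maruyama stepping at `dt` = 0.02 min; the
  driver aborts if any vertex moves more than $0.5\,l$ in a step.
  Relaxation caps per-step displacement at $0.1\,l$ adaptively.
* Sub-threshold edges are flipped in increasing length order; edges
  sharing a vertex with an edge already flipped in the same step are
  deferred to the next step (deterministic, avoids conflicting flips).
* Flips refuse to create two-sided cells (triangle-adjacent edges are
  left to shrink further; refusals are logged).
* Through a flip the four spoke junctions keep their identities (their
  flanking cell pairs are invariant) and their tensions; only the
  flipped junction receives a fresh id.
* Degenerate Voronoi vertices where four cells meet are split into two
  degree-3 vertices separated by $10^{-3}\,l$, the new edge adjacent to
  the opposite cell pair containing the smallest cell id (deterministic
  tie-break).  Meshes are assembled from original polygon coordinates so
  that parallel edges on very small tori remain distinct.
* Cell areas use the shoelace formula on minimum-image unwrapped cycles;
  areas sum to the box area to $10^{-9}$ relative tolerance.

## Known limitations

* No perimeter elasticity, cell division, delamination, growth, or
  external stress; vertices are strictly three-way between flips.
* The printed extrinsic tension spread is not reproduced as a default
  (see the calibration note above); users can set
  `model_params(sigma_e = 1.07, sigma_i = 1.07 * 0.08/0.13)` to explore
  that regime, which is liquid-like in this functional.
* The skeleton parser assumes clean 1-px skeletons; it does not repair
  segmentation gaps and treats every border contact as an exclusion.
* In-vivo data are not shipped; all pipeline validation is against the
  synthetic generators, with the scope stated above.
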