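---
title: "Automatic IMRT planning by fluence prediction and dose-mimicking fine-tuning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automatic IMRT planning by fluence prediction and dose-mimicking fine-tuning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npcplan)
```

## The planning problem

Nasopharyngeal carcinoma (NPC) is treated with intensity-modulated radiation
therapy delivered from nine equally spaced coplanar 6 MV beams. The planner
must push five overlapping/nested target volumes (a boost `PTV-GTV` nested in
`PTV-1` nested in `PTV-2`, plus two lateral nodal targets) to different
prescription levels while sparing seventeen organs at risk (OARs), several of
which — brainstem, spinal cord, optic apparatus — directly abut the targets.
Done by hand this is a slow trial-and-error loop inside a treatment planning
system.

`npcplan` implements an automated alternative as an open, testable pipeline:

1. **Fluence prediction.** A surrogate predictor produces per-beam fluence
   maps from the patient anatomy (here: a projection of the encoded
   prescription volume, with controllable multiplicative error standing in
   for a learned model's prediction error).
2. **Step 1 — initial plan.** The predicted maps are converted to deliverable
   multi-leaf collimator (MLC) segments and the resulting dose is computed.
   This *predicted-fluence plan* is already deliverable, but its target
   coverage and OAR sparing are only as good as the prediction.
3. **Step 2 — auxiliary structures.** Geometric helper structures (target
   crops, a conformity ring, a dose-spill shell) are built from the targets
   and the Step 1 dose.
4. **Step 3 — objective derivation.** A complete optimization objective set
   is generated automatically from the prescriptions and the Step 1 dose,
   deliberately *tightened* (5–25% below achieved OAR values) so that the
   subsequent optimization is guaranteed to push beyond the initial plan —
   this is the dose-mimicking idea.
5. **Step 4 — fine-tuning.** Beamlet fluences are re-optimized against those
   objectives, starting either from the predicted fluence (*warm start*) or
   from a neutral uniform state (*cold start*), then re-sequenced and the
   final dose computed.

Every stage is a pure function of the pipeline configuration, so a full run
is bit-reproducible.

## The synthetic case

No patient data ship with the package. `generate_phantom()` builds a seeded
head-and-neck stand-in: a water-equivalent elliptic-cylinder body, three
concentric ellipsoidal primary targets, lateral nodal targets, and the full
17-OAR roster as parametric ellipsoids/cylinders placed at fixed millimetre
coordinates with a small seeded jitter (±2 mm position, ±5% size). Default
prescriptions are 70 / 60 / 54 / 66 / 66 Gy for
PTV-GTV / PTV-1 / PTV-2 / PTV-LN(L) / PTV-LN(R), values chosen once from the
clinically used ranges so worked examples are reproducible.

What the phantom does **not** emulate: real CT heterogeneity (density is
binary water/air), anatomical shape variation, contouring uncertainty, and
the partial-volume behaviour of clinical contours. Tests that pass on this
phantom therefore demonstrate the *pipeline logic* — objective derivation,
optimization behaviour, sequencing exactness, metric definitions — not
clinical dose accuracy.

The default grid is 64 × 64 × 48 voxels at 4 mm (a desk-scale stand-in for
clinical resolution; all code is resolution-agnostic and the structure
definitions are in millimetres, so coarser grids cover the same anatomy).
Note one resolution effect: a 3 mm margin expansion is defined on voxel
centres, so at spacings above 3 mm it degenerates to the identity; the
margin semantics, not the margin value, are the tested contract.

## Dose engine

The proprietary clinical dose algorithm is replaced by an explicit
finite-pencil-beam kernel. For a beamlet of aperture $w \times h$ at lateral
offset $(x, y)$ and radiological depth $d$ (density line-integral in mm
water-equivalent):

$$
D(d, x, y) = C \, \min(d / d_b, 1)\, e^{-\mu d}
  \left[\Phi\!\left(\tfrac{x + w/2}{\sigma}\right) - \Phi\!\left(\tfrac{x - w/2}{\sigma}\right)\right]
  \left[\Phi\!\left(\tfrac{y + h/2}{\sigma}\right) - \Phi\!\left(\tfrac{y - h/2}{\sigma}\right)\right]
$$

with defaults $\mu = 0.005\,\mathrm{mm^{-1}}$ (6 MV), linear buildup depth
$d_b = 15$ mm, lateral $\sigma = 3$ mm, and calibration
$C = e^{\mu \cdot 100\,\mathrm{mm}}$ so that a unit-fluence open field
deposits 1 Gy at 100 mm water depth. Beamlets are parallel (no divergence) at
desk scale. Entries below $10^{-4}$ of their beamlet's maximum are truncated
to keep the influence matrix sparse. These constants live in
`pencil_beam_kernel()` and are deliberately simple: the quantity under test
is the planning logic, which needs a linear, nonnegative, depth-attenuating
dose operator, not convolution/superposition fidelity.

The surrogate fluence is scaled by `1 / n_beams` relative to the encoded
prescription so that, with this calibration, the nine-beam sum lands near the
prescription inside the targets; its lognormal error parameter defaults to
`noise_sd = 0.05`, a plausible few-percent beamlet-wise prediction error.

## Objectives and the optimizer

`derive_objectives()` emits the fixed 27-row template: hard prescription
rows for the targets (e.g. PTV-GTV maximum D~0%~ 73.5 Gy / minimum D~100%~
71.5 Gy at priorities 70/150), and reference-derived rows for OARs — maximum
gEUD at 0.85 × the Step 1 value for brainstem/cord (a = 20), 0.75 × for
normal parotids (a = 3), 1.00 × for optic structures (a = 1), and 0.95 ×
D~1%~/D~20%~/D~50%~/gEUD rows for the conformity ring (a = 15) and the 40 Gy
spill shell (a = 10). The gEUD is the Niemierko power mean
$\left(\frac{1}{N}\sum_i d_i^a\right)^{1/a}$ (the clinical source names gEUD
without writing the formula; the standard definition is adopted). D~x%~ uses
a sort-and-index convention with no interpolation
(index $\lceil xN/100 \rceil$ of the descending sort), which makes ties and
small-structure behaviour bit-exact and testable.

The composite objective is a priority-weighted sum of one-sided quadratic
penalties with weight $(\text{priority}/100)^2$: dose-volume penalties are
voxel *means* over the structure (equivalently, size-normalized sums), while
the scalar gEUD penalty is weighted directly — normalizing a scalar penalty
by structure size would make gEUD objectives on large organs vanish.
Dose-volume objectives use classic hottest-first voxel selection: only
voxels exceeding the objective dose beyond the allowed volume fraction are
penalized. This mapping is a documented design choice; the commercial
optimizer's internal mapping is undisclosed, and the quadratic form
preserves the 150 > 70 > 50 dominance ordering.

Optimization is projected gradient descent on $w \ge 0$ with
Barzilai–Borwein steps and a monotone Armijo backtracking line search:
deterministic, feasible at every iterate, and non-increasing by
construction. The iteration cap is 300; convergence is declared when the
relative decrease over a 10-iteration window falls below $10^{-6}$. Warm
start realizes the "intermediate dose" idea as initialization at the
predicted fluence; cold start ("no initial state") is made executable as a
uniform fluence scaled so the mean PTV-GTV dose equals its prescription.
Both modes terminate and both satisfy the improvement property; no claim is
made that warm start needs fewer iterations (the clinical experience it
mirrors found no significant reduction).

## Sequencing

`sequence_fluence()` quantizes each map to `levels` equal steps of its
per-beam maximum (default 10) and decomposes it by the textbook
unidirectional-sweep rule: unit segment $t$ opens leaf pair $j$ over the
contiguous column range where the cumulative profile increase has reached
$t$ but the cumulative decrease has not. The decomposition reconstructs the
quantized map *exactly*, identical consecutive apertures are merged, and the
per-beam MU equals the sweep lower bound. Because quantization grids nest
when the level count doubles, reconstruction error is monotone
non-increasing along 5 → 10 → 20 → 40 levels — the property the tests
assert. Machine constraints (leaf gaps, interdigitation, transmission) are
out of scope; 1 MU is defined as one unit of segment fluence weight, so MU
comparisons are internal-relative only.

## Evaluation

Plan quality uses the standard metrics: conformity index
$CI = TV_{RI}/TV \in [0, 1]$ (fraction of target covered by prescription),
homogeneity index $HI = (D_{5\%} - D_{95\%})/D_{px}$ (lower = more
homogeneous), D~max~ as the point maximum (a near-max like D~0.03cc~ is a
documented alternative, not used), D~median~ = D~50%~ under the same sort
convention, and cumulative DVHs on a 0.1 Gy axis (metrics are always
computed from raw voxel doses, never from the binned curve).
`compare_plans()` runs the two-sided paired Wilcoxon signed-rank test
(normal approximation from `stats::wilcox.test`; p-values reported from 5
pairs, all-zero differences reported as p = 1) at a 0.05 significance level.

## Numerical and degenerate-input choices

* Margin ties at exactly the margin distance are *included* (≤), for
  bit-exact tests.
* Objective doses are floored at 0 Gy after scaling (defensive only).
* Objectives referencing missing or empty structures are skipped with a
  warning rather than failing the run, since degenerate phantoms can lack a
  small structure at coarse resolution.
* All auxiliary structures are intersected with the body (whether the
  clinical scripts did so is unstated; this is the documented choice here).
* gEUD is evaluated with doses scaled by their maximum so a = 200 does not
  overflow; an all-zero structure has gEUD 0.
* The line search falls back to "no progress" termination if 40 halvings
  fail to produce descent — the trace is still monotone.
* The pipeline configuration is a validated R object
  (`pipeline_config()`), not an on-disk config dialect; the command-line
  driver exposes its fields as flags. Every stage being a pure function of
  this one object is what makes full runs bit-reproducible.

## Problem sizes used in the shipped checks

The test suite exercises the geometry-heavy stages on a 32 × 32 × 24 grid at
8 mm (the same anatomy, coarser sampling) and the optimizer recovery and
dose-mimicking checks at the full default 64 × 64 × 48 / 9 × 20 × 20-beamlet
size, chosen as the smallest sizes at which every structure is resolved and
the optimization is non-trivial. The end-to-end acceptance run
(`scripts/acceptance.R`) uses the full default configuration.

## Known limitations

* The dose engine is homogeneous-water pencil-beam physics; absolute doses
  are internally calibrated, not clinically meaningful.
* The surrogate predictor is a geometric projection, not a learned model;
  its error model (i.i.d. lognormal per beamlet) has no spatial structure.
* The phantom's organs are convex primitives; non-convex target/OAR
  interfaces, which drive much of the difficulty in real NPC planning, are
  only approximated by proximity.
* Clinical cohort statistics (population metric tables, MU levels) are not
  reproducible from this package and are not claimed.
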