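---
title: "Quantifying paraxial microtubule arrays: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying paraxial microtubule arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtarray)
```

Differentiating muscle cells reorganise their microtubule cytoskeleton from a
radial, centrosome-anchored array into a paraxial array: filaments running
parallel to the long axis of the elongating cell. mtarray quantifies that
reorganisation — and the in vitro behaviour of the crosslinkers that build it —
from tabular microscopy-derived data: manually traced filament polylines,
plus-end (EB) comet tracks, photoactivated tubulin-mark trajectories,
seed-anchored filament-encounter geometries, gliding-assay tracks,
density-gradient fraction profiles, and per-cell morphology records. No raw
images enter the package; segmentation and tracking are upstream concerns.

This vignette explains the statistical models, the parameters that matter, and
the choices made where the design was genuinely open.

## Alignment statistics

Every orientation analysis is referenced to the cell's longitudinal axis
(`cell_geometry()`), the ordered tip-to-tip segment whose length is the cell
length. Angles come in two conventions: *undirected* for filament orientations
(folded to (−90°, 90°], since a filament has no intrinsic direction here) and
*directed* for comet and mark motion ((−180°, 180°]).

The alignment index is a Kuiper-type statistic: map the angles onto (0, 1]
linearly from their support, form the weighted empirical CDF, and take

$$K = d_1 + d_2, \qquad
  d_1 = \sup_x\,[\hat F(x) - x], \qquad
  d_2 = \sup_x\,[x - \hat F(x)],$$

the maximum deviations above and below the uniform CDF. $K$ is 0 in the
isotropic limit and approaches 1 as all angular mass concentrates. Three
choices deserve emphasis:

* **Fixed support, no origin maximisation.** The classical circular Kuiper
  statistic is rotation-invariant; here the cell axis supplies a canonical
  origin, so deviations are computed on the fixed axis-referenced support.
  $K$ is used as a descriptive alignment index, not as a test statistic with
  circular-invariance guarantees.
* **Length weighting.** Each polyline segment contributes its angle weighted by
  its length, so a long aligned filament dominates the sample the way it
  dominates the image. Per-comet samples use unit weights. Whether published
  cumulative curves weight by length is not knowable from a figure; the
  weighting is exposed in `angular_sample()` and can be set to unit weights.
* **Exact suprema.** Both one-sided deviations are evaluated at every jump of
  the step ECDF (right value for $d_1$, left limit for $d_2$), where the
  suprema against a continuous CDF are attained; ties at machine precision are
  merged. The test suite checks this against a brute-force dense-grid
  evaluation to 1e−12.

The *asymmetry index* `asymmetry_index()` is a declared implementation
definition (the quantity is plotted in the motivating work but never defined):
$A = 2 f_{\mathrm{axial}} - 1$ with $f_{\mathrm{axial}}$ the weighted fraction
of folded angles within ±45° of the axis, mirroring the conventional colour
split of comet tracks into axial versus perpendicular quadrants. It is 0 for an
isotropic sample and ±1 at the axial/perpendicular extremes, and is invariant
under mirroring ($\theta \to -\theta$).

```{r kuiper-example}
s <- angular_sample(c(-45, 0, 45))
kuiper_statistic(s)
```

## Sliding-event detection and classification

Photoactivated (or photoconverted) tubulin marks are fiduciary segments on
microtubules; their motion reports filament sliding. `detect_events()` scores
an event when a mark moves more than 0.5 µm from its current rest reference —
the published scoring rule — and adds the segmentation detail the rule leaves
open:

* the event *start* is back-tracked to the last rest frame before sustained
  motion, so start times match the true onset exactly on clean data;
* an event *closes* after 2 consecutive frames of sub-noise motion (noise
  floor 3 × a 50 nm localisation σ = 0.15 µm by default), preventing
  single-frame jitter from splitting one excursion into several;
* the rest reference then *re-anchors*, so successive events are disjoint.

Mean event velocity is path length over duration; the `fast` flag marks events
above 700 nm/s, the published cut for motor-driven sliding. Classification
(`classify_event()`) gives looping precedence — any two instantaneous direction
estimates differing by more than 90° — then calls an event paraxial when its
net direction lies within 45° of the axis folded to either tip, else off-axis.
Direction estimates use only steps longer than the noise floor, so pauses do
not fabricate turns. Event frequencies are reported per activated region per
minute; the motivating work's per-pattern n suggests exactly this
normalisation, which is therefore fixed but documented.

## Fluorescence dissipation

Loss of mark intensity mixes three channels: depolymerisation, motor-driven
transport out of the region, and photobleaching. The drug design separates
them — taxol suppresses depolymerisation, azide suppresses transport, the
double treatment leaves bleaching only. `fit_half_life()` fits
$I(t) = A e^{-kt}$ by least squares on the linear intensity scale with free
amplitude (a log-transform would weight late, noise-dominated points too
heavily), profiling $A$ in closed form and searching $k$ on a refined grid; a
non-decaying series is reported with $t_{1/2} = \infty$ rather than as an
error. `dissipation_decomposition()` then inverts the design:
$k_b = k_{\mathrm{taxol+azide}}$, $k_t = k_{\mathrm{taxol}} - k_b$,
$k_d = k_{\mathrm{azide}} - k_b$, with the untreated rate kept as a
consistency check.

`bleach_correct()` implements the additive reading of the published
bleach-subtraction: on series normalised to their $t = 0$ value,
$\mathrm{corr}(t) = \mathrm{raw}(t) + (1 - \mathrm{control}(t))$. This
restores the control's fractional loss and is exact to first order in the
bleached fraction; for bleaching rates of order $10^{-3}\,\mathrm{s}^{-1}$
over a one-minute observation the residual error is below 2% RMS, which is the
regime the correction is intended for. The component *rates* never rely on the
correction — they come from the four-condition decomposition above.

## In vitro encounters, gliding, bundles

An encounter pairs a seed-anchored target filament with an incoming growing
filament. The incident angle is measured between plus-end-ward tangents
averaged over 0.5 µm of arc on the incoming side of the contact (damping
tracing noise on curved filaments); encounters above 90° are antiparallel by
convention. `classify_outcome()` calls an encounter zippered when the growing
filament runs along the target lattice — inter-filament distance below a
100 nm sub-resolution gap — for at least 2 µm past the contact, the published
minimum bundling length, with a polarity-consistency check on the direction of
the co-aligned run. The distance profile along the run is smoothed over a 1 µm
arc window before thresholding: with 50 nm vertex noise on both polylines the
pointwise distance fluctuates with ~60 nm scale, and an unsmoothed threshold
truncates genuine bundles, while a diverging crossed filament at even the
shallowest generated angle (5°) still exceeds the gap well before 2 µm.

Gliding assays are summarised by frame-to-frame instantaneous speeds per
object type; `bundle_survival()` reports the fraction of bundles intact at a
horizon among bundles that either survived or were separated by motor forces,
excluding right-censored objects (left the field, or dissociated as an intact
bundle) exactly as the published scoring does. `score_bundles()` carries two
named presets because the published thresholds differ between contexts: in
cells, elongated regions > 2.3 µm with intensity ratio strictly above 3×; in
vitro, regions at least 3× single-filament brightness with a 2 µm length rule.

## Hydrodynamics

Glycerol-gradient fractions are summarised by `peak_volume()` — the
signal-weighted centroid of the contiguous fractions at ≥ 50% of the peak
signal, more robust to 250 µl fraction granularity than an argmax — and mapped
to Svedberg units through a linear calibration fitted to standard proteins
(`calibrate_gradient()`). Note the quantisation this implies: a peak that does
not sit symmetrically on the fraction grid is localised with a bias of up to
~25 µl, so exactness checks use grid-symmetric fixtures and replicate profiles
should be averaged before localisation. The frictional ratio is

$$f/f_{\min} = S_{\max}/S, \qquad S_{\max} = 0.00361\,M^{2/3}$$

with $M$ in Daltons and $S_{\max}$ in Svedbergs: the sedimentation coefficient
of an anhydrous sphere of equal mass. Values near 1 indicate compact globular
particles; values around 2 indicate highly elongated or disordered monomers.

```{r frictional}
frictional_ratio(99000, 3.6)
```

## Morphology

`length_stats()` and `fusion_index()` score elongation (tip-to-tip length) and
fusion (fraction of cells with ≥ 3 nuclei over all scored cells — the
denominator includes mono- and bi-nucleated cells, following the published
counting). `orderliness_vs_length()` fits the per-condition Kuiper statistic
against mean cell length by unweighted OLS — the regression that links array
order to a cell's ability to elongate. Weighting by per-condition n or
variance is not applied because the published fit does not state any.

## The synthetic-data generator

Every input class has a seeded generator with ground-truth labels, so each
analysis stage can be tested by parameter recovery with no external data. One
root seed is split into fixed per-generator child streams: adding a generator
never perturbs another's draws, and an identical `synth_config()` yields
bit-identical output.

Defaults are the study conditions where stated, and field-typical conventions
otherwise:

| parameter | default | rationale |
|---|---|---|
| comet imaging | 3 s / 120 s | the published acquisition protocol |
| mark imaging | 1.6 s / 60 s | the published photoactivation protocol |
| cell | 100 µm, aspect 8 | elongated differentiating myoblast |
| filament orientation | axial von Mises, κ = 4 | single-parameter circular model; κ = 0 uniform |
| localisation noise | σ = 50 nm | typical widefield centroiding precision |
| sliding velocity | log-normal, median 500 nm/s | positive, right-skewed; spans the 700 nm/s fast cut |
| event geometry | displacement 1–2.5 µm, 15–25 s | published events "lasted on average 15–20 s" |
| dissipation rates | (0.010, 0.005, 0.002) s⁻¹ | depoly-dominated minute-scale loss |
| zippering probability | 0.7 below 25°, 0.8 above 150°, else 0 | reproduces the empty 25–150° zone |
| gliding | 600 ± 50 nm/s | kinesin-1 surface speed scale |
| bundle breakup | ln 2 / 450 s⁻¹ | half the bundles survive a 450 s observation |
| gradient | 250 µl fractions, 5 ml, σ = 400 µl | the published fractionation |

Two structural notes. Filament orientations are *axial* von Mises: the doubled
orientation angle is von Mises on the circle, so κ = 0 is exactly uniform on
(−90°, 90°]. Sliding events are placed without overlap in the 60-s record;
because events last 15–25 s, the per-mark event count is Poisson only in the
sparse regime (≲ 1 event · mark⁻¹ · min⁻¹) — at higher rates placement
saturates and thins the budget. The ground truth records what was actually
injected, so recovery tests are exact regardless; Poisson-recovery tests are
run in the sparse regime. Looping events get at least three frames so that
every injected event exceeds the 0.5 µm scoring excursion by construction.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: no point-spread rendering or segmentation error
beyond isotropic vertex/centroid noise, no filament curvature in cells, no
dynamic instability (tracks grow persistently), no motor-force mechanics of
zippering or breakup beyond exponential waiting times, and no gradient
non-linearity. Recovery results bound algorithmic error, not instrument error.

## Numerical choices and degenerate inputs

* Weighted-ECDF ties are merged at 1e−12; `K` is clamped to [0, 1] against
  floating-point overshoot.
* The decay fit brackets its rate on a 201-point grid over
  $[-10, 50]/\mathrm{span}$ before `optimize()`; `k ≤ 1e-10` reports
  $t_{1/2} = \infty$, and constant series are flagged, not errored.
* Zero-length segments, empty angle samples, flat gradient profiles,
  single-frame tracks and missing drug conditions raise typed errors or
  warnings; single-frame gliding tracks are excluded with a warning rather
  than failing the batch.
* Empty zippering-histogram bins report `NA` fractions, never 0.
* `run_pipeline()` writes `summary.json` with full-precision numbers and no
  timestamps, so a config + seed reproduces byte-identical summaries.

## Problem sizes

The shipped tests and the acceptance script run at desk scale, chosen as the
package's own verification conditions: 150-filament networks (50 replicates
per concentration for the monotonicity curve), 300–500 injected sliding events
for precision/recall, 50-replicate Monte-Carlo recovery for half-life,
decomposition and sedimentation, 300–500 encounters, and 200-bundle survival.
These sizes put Monte-Carlo standard errors comfortably inside the tolerances
being asserted.

## Known limitations

* The Kuiper index on the fixed support is origin-dependent by design; it is
  not the rotation-invariant circular test statistic.
* The asymmetry index is this package's definition of an undefined published
  summary; compare trends, not absolute values.
* The additive bleach correction degrades for bleached fractions beyond
  ~20%; prefer the four-condition decomposition for rates.
* Coaligned length is measured along the growing filament's arc, and the
  50%-centroid peak localisation is fraction-grid-quantised (see above).
* Event velocities average over the whole event including any sub-noise
  pause frames within it.
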