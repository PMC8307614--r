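---
title: "Measuring collective migration and its response to directional control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring collective migration and its response to directional control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(collmigr)
```

## The measurement problem

A confluent epithelial monolayer is an active material: cells crawl, and
cadherin-mediated junctions couple each cell's motion to its neighbors.
The strength of that coupling — tunable experimentally through
extracellular calcium, which sets junctional E-cadherin levels — controls
how *collective* the tissue is. When a directional command such as a DC
electric field is applied, the tissue's native coordination and the
command compete: weakly coupled tissues follow the field readily, while
strongly coupled ones respond slowly and can even damage themselves by
edge retraction.

`collmigr` implements the quantification stack for this problem:
velocimetry from time-lapse images, scalar order parameters, space–time
summaries (kymographs, edge traces), and a synthetic-data module that
generates inputs with known ground truth so every stage can be validated.

## Order parameters

All metrics operate on a `velocity_field`: a regular grid of velocity
vectors with a validity mask. With the `N` valid, nonzero vectors
$\vec v_i$ and $\theta_i$ the angle of $\vec v_i$ to the horizontal
(+x) axis:

* **Directionality** $= \frac1N \sum_i \cos\theta_i$, in $[-1, 1]$.
  Because the electrotactic command is horizontal, +1 means motion
  perfectly parallel with the field (toward the cathode), −1 perfectly
  antiparallel.
* **Coordination** $= \left\| \frac1N \sum_i \vec v_i / \|\vec v_i\|
  \right\|$, in $[0, 1]$ — the polarization order parameter of
  collective-motion theory. It measures alignment regardless of the common
  direction: 1 for a perfectly coordinated tissue, $O(1/\sqrt N)$ for
  isotropic motion.

Both metrics divide by $\|\vec v_i\|$, so vectors of magnitude below
$10^{-9}$ µm/min are excluded (the angle of a stationary vector is
undefined); a field with no valid nonzero vectors raises a classed
"undefined metric" condition rather than returning 0, and
`metric_timeseries()` converts that to a missing value. Both metrics are
invariant to rescaling all magnitudes; coordination is invariant to global
rotation, and for fields whose vectors all lie on the x axis,
coordination equals |directionality| — properties the test suite asserts.

Supporting metrics: mean speed (magnitudes, zero vectors included), mean
x-velocity (signed), a neighbor velocity correlation (mean cosine between
each node's vector and the mean vector of its valid 4-connected grid
neighbors — one of several possible estimators; we state ours explicitly
since the quantity is often reported without a formula), and pooled polar
histograms of $\mathrm{atan2}(v, u)$ over $(-\pi, \pi]$.

Whether a study reports coordination per frame and then averages, or pools
vectors across frames, is often ambiguous; `metric_timeseries()` computes
per-frame values (then optionally smooths with a centered moving average,
default 3 frames) and leaves temporal aggregation to the caller. The
"maximum migration speed" summary is defined here as the maximum over
frames of the smoothed spatial mean speed, and "directionality at 4 h
into stimulation" as the value at the frame nearest that time.

## PIV

`compute_piv()` interrogates each image pair on windows of
`window_size = 32` px spaced at 50% overlap. At a typical calibration of
~1.3 µm/px this makes each interrogation square cover roughly 42 µm of
monolayer, the scale at which velocity domains in epithelia are
conventionally displayed. Each window pair is mean-subtracted and
cross-correlated via FFT; the correlation peak gives the integer
displacement, refined per axis by a three-point Gaussian fit (parabolic
fallback when a log is undefined; parabolic also available as an option).

Two numerical choices matter:

* **Correlation normalization.** Plain circular FFT correlation weights
  large lags by smaller overlap between the windows, biasing peaks toward
  zero displacement (we measured ≈ −0.25 px at a true 4 px shift). The
  default therefore zero-pads to linear correlation and divides each lag
  by its overlap area, which removes the bias; `correlation = "circular"`
  is retained — it is exact when the texture is periodic at the window
  size, and the shift-theorem test uses it. The search is limited to
  |lag| ≤ window/4, the usual one-quarter rule.
* **Validity, not interpolation.** Nodes failing the peak-to-second-peak
  signal-to-noise gate (default 1.3; second peak searched outside a 3-px
  exclusion zone), zero-variance windows, and vectors failing the
  normalized median test (8-neighborhood residual to the neighborhood
  median over median absolute residual + 0.1 px, threshold 2) are marked
  invalid and excluded from all downstream metrics — they reduce `N`
  rather than being replaced by interpolated values. Fields with fewer
  than 9 valid vectors skip the filter with a warning.

Sign convention: image arrays are row-major top-down, but all outputs are
physical — `+u` rightward, `+v` upward (row lag negated). Velocities are
stored in px/frame; the exposure in µm/min is exactly
`px/frame × pixel_size / frame_interval`.

## Kymographs and edges

`xvelocity_kymograph()` bins u-values (averaged over y and over frames in
each time bin) into rows of 10 min and columns of 42 µm by default,
matching the conventional display for stimulation time courses; cells with
no valid vectors stay missing. Temporal binning happens only here — the
PIV stage applies no temporal smoothing.

Edge tracking segments tissue from background by local texture: a box
standard-deviation map (window 7 px), thresholded by Otsu's method floored
at an absolute `min_texture_sd = 0.05` (intensity units), then largest
connected component and hole filling. The absolute floor is what lets a
pure-noise frame yield an empty mask (with a warning) while a fully
textured frame yields a full mask — a purely relative threshold cannot
satisfy both. A fixed threshold is available for synthetic images. Edge
position is the per-row rightmost (leading) or leftmost (trailing) tissue
pixel, summarized by the median over rows, which ignores fingers affecting
fewer than half the rows; displacement is relative to the first frame, so
retraction appears as negative leading-edge displacement. The wound-closure
rate between two facing tissues is minus the least-squares slope of the
gap width over time.

## The synthetic-data module

The generator is a Vicsek-style model — the minimal standard model of
tunable collectivity, chosen because the coordination metric above *is*
the Vicsek order parameter. Each step, agent $i$ forms a target direction
from three unit-vector pulls: its own heading (weight 1, persistence), the
circular mean heading of all agents within `interaction_radius` (weight
`coupling`), and the +x axis (weight `field_bias`); it takes the direction
of the weighted sum, adds uniform angular noise on
$[-\eta, +\eta]$, and advances by `speed · dt`. The persistence term makes
`coupling` a genuine alignment-strength dial (with pure neighbor-averaging
the order parameter would not depend on the coupling at zero bias), and
gives ties and empty neighborhoods a natural default — the agent keeps its
heading. The relative weight of the command,
`field_bias / (1 + coupling + field_bias)`, expresses the central
competition: stronger native coupling dilutes the external command.

Speed is `max(base_speed (1 − slope·coupling), 0.1·base_speed)` — a linear
encoding, floored at 10% of base speed, of the qualitative observation
that strongly adhesive tissues migrate more slowly. The coupling is an
abstract stand-in for junctional adhesion strength and deliberately has no
units of calcium concentration.

Defaults were chosen once as study-like conditions: 400 agents in a
400 × 400 µm box (roughly cell-scale spacing for keratinocytes), base
speed 1.5 µm/min, frame interval 5 min, 108 frames (9 h — a 1 h control
hour plus 8 h of stimulation), interaction radius 40 µm, noise 0.8 rad,
speed–coupling slope 0.15. `field_bias` accepts a per-step schedule so a
command can switch on mid-run, mirroring a stimulation protocol.
`boundary_mode = "free_x_edges"` unwraps the x axis so the tissue has free
left/right edges. One seed drives initialization and noise; identical
config + seed is bit-identical, and the caller's RNG state is never
touched.

Two renderers produce images with ground truth: `render_speckle()` builds
a periodic Gaussian-blob texture and advects it by a prescribed per-pixel
displacement field with periodic bilinear warping (displacements above a
quarter window trigger a warning, since PIV recovery is then not
guaranteed); `make_edge_scenario()` renders a textured tissue over a
low-amplitude noise background whose right boundary advances, holds or
retracts at a programmed rate, returning the true edge position per frame.

### What the synthetic data does and does not show

The simulator reproduces the *statistical* structure the metrics are
designed to measure: coordination increasing with coupling, speed
decreasing with it, directionality responding to a bias, isotropic motion
at zero coupling and maximal noise, and edges with known kinematics. It
does not model cell shape, density fluctuations, jamming, junction
mechanics, retraction dynamics or field physics. Passing tests therefore
demonstrate that the measurement pipeline is correct — not that the model
captures real tissue mechanics; on microscopy data the PIV and edge
parameters (window size, texture window, thresholds) may need adjustment
to the imaging conditions.

## Problem sizes and determinism

The validation suite runs at desk scale, chosen to exercise every code
path with comfortable statistics: metric oracles on 16 × 16 grids (100
random fields), the isotropic coordination null with $10^5$ unit vectors
(tolerance $3\sqrt{\pi/4}/\sqrt N$), PIV recovery on 160 × 160 speckle
pairs, simulator trends with 256 agents × 60 frames × 10 seeds per
coupling, and edge scenarios of 120 × 320 px × 11 frames. The full
pipeline is deterministic for a fixed configuration: reruns produce
byte-identical CSV outputs, and each output records an MD5 hash of the
analysis-relevant configuration (the output path is excluded from the
hash).

## Known limitations

* Single-pass PIV only; no window deformation, multi-pass refinement or
  optical flow. Displacements beyond a quarter window are not recovered.
* The neighbor-correlation estimator is one declared choice among several
  in the literature; compare absolute values across packages with care.
* Edge tracking assumes a horizontally oriented free edge (tissue on the
  left); other geometries require rotating the input.
* The speed–coupling trade-off is linear by construction; real tissues
  need not be.
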