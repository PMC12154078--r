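---
title: "Quantitative methods for endothelial imaging and plate assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative methods for endothelial imaging and plate assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endoquant)
```

endoquant collects the quantitative computations that sit behind a typical
brain-microvascular-endothelium study: actin filament quantification from
phalloidin-stained micrographs, shape parameterization of Fura-2 ratio
calcium transients, scratch-assay wound-width and migration-rate estimation,
and the plate-assay normalization and significance layer shared by
viability, ROS, ATP, adhesion and Transwell permeability endpoints. Every
stage comes with a synthetic-data generator that emits ground truth, so the
whole pipeline is testable without any microscope.

## Filament detection by oriented template correlation

The detector follows the Fiberscore family of algorithms: a bank of `K`
binary line templates, each a centered Bresenham segment of `2L + 1` pixels
in a `(2L + 1) x (2L + 1)` window at orientations `k * 180 / K` degrees, is
correlated against every pixel neighborhood of the min–max normalized image.
For each pixel and orientation we compute

- the Pearson correlation between the square neighborhood and the template;
- the coefficient of variation of intensities sampled along the oriented
  segment (`CV_along`) and along the perpendicular segment (`CV_cross`).

A pixel is a core fiber pixel at its best orientation when the best
correlation reaches `TC`, `CV_along <= M`, and `CV_cross / CV_along >= N`.
The direction of the two CV tests expresses what a ridge is: homogeneous
lengthwise, heterogeneous crosswise. Defaults (`L = 6`, `K = 10`,
`TC = 0.55`, `M = 0.3`, `N = 2.1`, `T = 0.25`) are the values tuned for
bEnd.3 endothelial cells; `T` is only meaningful on the normalized unit
intensity scale, which is why images are rescaled first. We read the kernel
size parameter as a half-length, since a centered line template needs an odd
window side; the full-size reading is available through
`fiberscore_params(kernel = "full")`. "Normalized standard deviation" is
taken as sd/mean; sd/range would only rescale the `M` and `N` thresholds.

Three implementation choices matter in practice and are worth spelling out:

- **Matched pre-filter.** Real filaments are ridges a few pixels wide
  (diffraction plus cytoskeletal bundling), while the raw template is one
  pixel wide. Correlating the raw template against a noisy ridge saturates
  near the acceptance threshold. We therefore blur the image *and* the
  template with the same small Gaussian (`smooth = 1` px by default) before
  correlating. This is matched filtering: both signals pass the same kernel,
  the profiles align, and pixel noise is suppressed without biasing the
  correlation. Setting `smooth = 0` recovers the raw behaviour.
- **Tip reclamation.** The `CV_along` test necessarily rejects filament
  tips: there the sampling segment lies half on, half off the filament, so
  its CV is large. Applied literally, every filament loses about `L` pixels
  per end. Pixels whose correlation still reaches `TC` and that are
  8-connected to core pixels are therefore reclaimed by geodesic
  reconstruction. Reclamation preserves monotonicity: raising `TC` or `T`,
  lowering `M`, or raising `N` can only shrink the final mask.
- **Sub-bin orientation.** The per-pixel orientation is refined by parabolic
  interpolation of the correlation over the best bank angle and its two
  angular neighbors, followed by a doubled-angle vector average over the
  5 x 5 masked neighborhood. Without refinement the `180 / K = 18` degree
  quantization and occasional misassigned pixels bias polarity low by up to
  0.1.

The binarized mask is thinned to one-pixel skeletons with Guo–Hall
homotopic thinning (hand-written; idempotent and connectivity-preserving),
components are measured as path length — 1 px per 4-neighbor step, √2 per
diagonal — and components shorter than the minimum filament length (default
5 µm, from the 5–30 µm working range) are discarded. Branched skeletons are
measured by total path length rather than longest path: simpler, monotone
under pruning, and reproducible. Polarity is the axial resultant
`sqrt(Dx^2 + Dy^2)` with `Dx = mean(cos 2θ)`, `Dy = mean(sin 2θ)` over
fiber pixels; the doubled angle is essential because filaments are
undirected (θ and θ + π are the same line) and antiparallel orientations
must reinforce. Polarity is computed over the pixels of components that
survive the minimum-length filter, so isolated noise blobs that never count
as filaments do not dilute it either. Interactive cell individualization is
replaced by an optional integer label mask (`fiberscore(..., labels = )`),
which preserves per-cell metrics without the manual step.

`optimize_parameters()` scans a grid over `{M, N, TC, T}` and records the
filament count restricted to the 5–30 µm window, returning the contour
table and its argmax — the procedure used to adapt the thresholds to a new
cell type.

## Calcium transient parameterization

Traces are I340/I380 ratios after background subtraction; samples with a
non-positive corrected denominator are flagged invalid and excluded. Six
shape parameters are extracted per transient: amplitude (peak above
baseline), latency (stimulus to onset), duration (stimulus to return —
duration therefore embeds latency by definition), area (trapezoidal
integral above baseline from onset to return), rising velocity (maximum
first difference over the sampling step on the rising phase), and asymmetry
`b/a` (decay over rise time).

The baseline is the mean of at least 10 pre-stimulus samples. Onset
detection uses a conventional sustained-threshold rule — first post-stimulus
time above baseline + 3 pre-stimulus SDs for 3 consecutive samples — and is
then refined by regressing the rising flank (up to 60% of the provisional
amplitude) and extrapolating to the baseline. The refinement matters: a bare
threshold crossing is systematically late by the time the signal needs to
climb three noise SDs, about 1.7 samples under 5% noise, while the flank
regression is unbiased for ramp-like onsets and brings the mean absolute
latency error below one sampling interval. Return is the first post-peak
crossing of baseline + 5% of amplitude. On noiseless traces both rules
collapse to exact baseline departure/return, so triangular test transients
are recovered to machine precision; area is integrated above baseline,
which makes it zero for a flat trace. All thresholds (`onset_sd_mult`,
`onset_run`, `return_frac`) are exposed.

Inter-parameter structure is summarized by the Pearson correlation matrix
across cells (`correlate_params()`, at least 3 cells; constant columns are
reported as missing rather than NaN), and per-condition summaries are
ratios of means against the control group.

## Wound width and migration rate

Scratch images are segmented by texture, not intensity: a
difference-of-Gaussians band-pass (σ = 0.8/2 px), absolute response and
local smoothing yield a texture-energy image in which confluent cell
regions score high regardless of shading; Otsu's threshold gives the cell
mask. A closing with a 6 px disk bridges sparse cell texture; the
subsequent opening uses a deliberately smaller 2 px disk — opening with the
same large radius deepens the bays that missing cells leave at the wound
boundary and inflates the width by several pixels at 30% sparsity. The
wound axis is the principal axis of the largest background component
(making the measurement orientation-independent); the mask is rotated so
the wound is vertical, the per-row width is the widest background run, and
the summary is the median over rows, which is robust to boundary spurs. A
field is declared wound-free when the background band fails to span the
image along its axis or the per-row gaps are not positionally coherent.

The migration rate is total gap closure per unit time,
`(width_t0 − width_t) / elapsed`; per-edge half-closure differs only by a
factor of 2, which cancels under normalization to the control, and wound
widening yields a flagged negative rate. Normalized rates map the control
to 1 by construction.

## Plate assays and significance

Viability, ROS, ATP and adhesion reduce to normalization against the
control mean (100% or ratio 1); ROS per cell divides total fluorescence by
the nuclei count. The Transwell apparent permeability coefficient is
`Papp = (dQ/dt) / (A · C0)` with the flux taken as the least-squares slope
through the cumulative basolateral amounts; with times in minutes, amounts
in µg, `C0` in µg/mL and `A` in cm², units reconcile to cm/s. Basolateral
sampling is assumed non-replaced; with the standard 15/30/45 min scheme,
`C0` = 200 µg/mL and `A` = 0.33 cm², a flux of 0.08 µg/min gives
`Papp ≈ 2.02 × 10⁻⁵` cm/s.

Group comparisons use one-way ANOVA followed by pairwise t tests against
the control on the pooled error term. Bonferroni multiplies raw p values by
the number of comparisons (capped at 1); Fisher's LSD reports raw p values
gated on a significant omnibus F — the classical definition, chosen because
both post hoc conventions are in routine use for these endpoints and the
choice is exposed per run. Stars follow * p < 0.05, ** p < 0.01,
*** p < 0.001. The ANOVA decomposition is verified in the test suite
against an explicit sums-of-squares oracle, and its size is checked by
simulation under the null.

## What the synthetic data emulate — and what they do not

The generators are designed so that every downstream quantity has a known
truth value:

- **Fiber fields** (`gen_fiber_image()`): straight anti-aliased segments
  with a Gaussian cross-profile (sd 0.7 px, about the diffraction-limited
  width at 0.25 µm/px), axial von Mises orientations (sampling the doubled
  angle and halving, since orientations are axial), truncated-normal
  lengths (default 18 ± 4 µm, inside the 5–30 µm working range), a linear
  background gradient emulating uneven illumination, and additive Gaussian
  noise. The default `fiber_intensity/noise_sd = 5` is the low
  signal-to-noise stress condition; filaments are placed without overlap
  (minimum 8 px centerline separation), matching the recovery conditions
  under which counts are meaningful. Real micrographs additionally contain
  curved and crossing filaments, cytoplasmic autofluorescence texture and
  defocus — recovery on these fields bounds detector error under clean
  geometry, not under entanglement.
- **Calcium transients** (`gen_calcium_trace()`): triangular (piecewise
  linear) pulses, chosen deliberately so every parameter has a closed-form
  truth (area `(a+b)·amplitude/2`, rising velocity `amplitude/a`, asymmetry
  `b/a`). Real transients have curved SOCE-driven decays; the triangle
  tests the extraction logic, not the biophysics.
- **Wound fields** (`gen_wound_image()`): two speckle-textured regions
  (grain 3 px) split by a clean band of known width at arbitrary angle;
  `cell_sparsity` removes random disk patches. Real wounds have ragged,
  cell-scale boundaries, so the ±2–3 px synthetic accuracy is a lower bound
  on real-image uncertainty.
- **Plate tables** (`gen_plate_table()`): Gaussian replicates per condition,
  control first — exactly the model under which the ANOVA layer is exact.

Noise is additive Gaussian throughout: the simplest controllable
signal-to-noise model, adequate for fluorescence at moderate counts though
not Poisson-faithful at very low light.

## Numerical conventions and degenerate inputs

Identical seeds give bit-identical outputs; detection itself is
deterministic. Constant correlation windows score 0, never NaN. An empty
mask thins to an empty skeleton; a cell with no surviving filaments reports
a count of 0 with a flag and is excluded from mean-length statistics. A
trace with no sustained excursion reports all parameters 0 with a
`no_transient` flag. Pipeline CSVs pin numeric formatting (`%.10g`) so
reruns are byte-identical; the run report echoes the fully resolved
configuration and the MD5 of every output file. All randomness in
`run_pipeline()` descends deterministically from one master seed.

Problem sizes used in the bundled tests — 256 px fiber fields with 12
filaments, 200 simulated cells for latency recovery, 1,000 null tables for
the type-I-error check — were chosen as the smallest sizes at which the
recovery statistics stabilize.

## Known limitations

The detector assumes straight, non-overlapping filaments at the template
scale; heavily entangled or strongly curved bundles are fragmented. Only
single-channel 2-D images are handled (no stacks, no deconvolution). The
wound detector assumes exactly one wound band. Calcium parameters are
extracted per trace without correcting for dye bleaching or drift beyond
the constant baseline. Fisher's LSD is provided for comparability, with its
well-known weaker control of the family-wise error rate relative to
Bonferroni.
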