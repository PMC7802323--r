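---
title: "Methods: micropillar traction forces, laurdan GP and motility metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: micropillar traction forces, laurdan GP and motility metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellmech)
```

cellmech implements the measurement chain behind a class of single-cell
biophysics experiments: membrane fluidity imaged with the ratiometric dye
laurdan, cell-generated traction forces read out from the bending of
elastomeric micropillars, cell-shape and migration descriptors, and the
fold-change filters that select genes and metabolites for downstream
network analysis. Every stage can be exercised on synthetic scenes with
planted ground truth, which is how the package validates itself.

## Membrane fluidity: laurdan generalized polarization

Laurdan's emission spectrum shifts by tens of nanometres between ordered
(rigid) and disordered (fluid) lipid phases. With two emission bands
centred at 420 nm and 473 nm, the generalized polarization

$$\mathrm{GP} = \frac{I_{420} - I_{473}}{I_{420} + I_{473}} \in [-1, 1]$$

indexes membrane order per pixel: higher GP means a more ordered, less
fluid membrane. `compute_gp_map()` evaluates this wherever the summed
intensity exceeds a threshold; background exclusion is deliberately
explicit because the choice silently shapes every downstream statistic.
The default threshold is Otsu's method on the sum image — a standard,
parameter-free foreground separator — overridable by a scalar threshold or
an explicit mask. No spectral (G-factor) calibration is applied; the
index is computed from the raw two channels.

Distributions are histograms over the full GP range $[-1, 1]$ with 100
bins (width 0.02) by default; the bin count is configurable and 100 bins
keeps binning error well below typical between-condition GP shifts while
leaving tens of counts per bin for cell-sized masks. A single Gaussian
$A \exp(-(x-\mu)^2 / 2\sigma^2)$ is fitted to the bin frequencies by
Levenberg–Marquardt least squares, initialized at the histogram moments;
one component is the default because condition-level GP distributions are
near-unimodal, and a non-converged fit is flagged rather than zeroed.
Condition differences are per-bin subtractions of two normalized
distributions (the minuend is recorded on the result and flippable), so a
difference curve always sums to zero. The colocalization of nanoparticle
signal with ordered domains is reported as the fraction of high-GP pixels
that also exceed a nanoparticle-channel threshold — one explicit
operationalization of a claim that is usually made qualitatively; it is
undefined (NaN, flagged) when no high-GP pixels exist.

Mean GP is reported as the pooled-pixel mean of the masked map. When a
per-cell summary is wanted instead, compute one map per cell mask and
average the per-cell means; both reductions are legitimate and differ
when cell sizes differ.

## Micropillar traction force microscopy

Cells adhering to a regular array of flexible elastomeric posts bend each
post by a deflection $d$; for small deflections the post behaves as an
Euler–Bernoulli cantilever with circular cross-section, so the restoring
force is $F = k\,d$ with

$$k = \frac{3EI}{L^3}, \qquad I = \frac{\pi D^4}{64}
  \quad\Rightarrow\quad k = \frac{3}{64}\,\pi E \frac{D^4}{L^3}.$$

`pillar_stiffness()` evaluates this in nN/µm from the geometry (default
$D = 0.9$ µm, $L = 1$ µm, $E = 2$ MPa, 1.8 µm pitch, giving
$k \approx 193$ nN/µm). Published stiffness values do not always agree
with published geometry — effective lengths, base compliance and curing
variability all shift $k$ — so the geometry object accepts a
`stiffness_override`; an override that disagrees with the formula by more
than 1% triggers a message stating both values and their ratio, and every
force result records which source was used. For the default geometry the
widely quoted value 24.2 nN/µm is exactly 1/8 of the formula value, the
ratio expected if the effective length were twice the nominal height;
the package takes no side and surfaces the discrepancy.

The image chain is:

1. **Detection** (`detect_pillars()`): local maxima of a lightly smoothed
   frame above an adaptive threshold (background median plus the larger of
   6 robust noise sd and 25% of the peak excursion), then
   intensity-weighted centroids in a window of radius pitch/2, with one
   re-centering iteration. Centroid weights are floored at background +
   3 noise sd: for a symmetric spot the truncation is symmetric, so the
   estimate stays unbiased while rectified-noise bias is suppressed.
2. **Lattice reconstruction** (`reconstruct_grid()`): nearest-neighbour
   direction statistics give the array orientation (circular mean modulo
   the 90° or 60° lattice symmetry); each detection gets integer lattice
   indices after removal of the global fractional phase, estimated
   circularly so a phase near one half cannot split the rounding; origin
   and basis vectors are then fitted by linear least squares, iteratively
   trimming detections whose residual exceeds max(4 robust sd, 3% of the
   pitch) so deflected pillars do not bias the rest grid. A fit whose
   inlier RMS residual exceeds pitch/4 is rejected as a wrong-lattice
   error. Square and hexagonal packings are supported; square is the
   default mould layout.
3. **Tracking** (`track_pillars()`): per frame, each node takes its
   nearest detection within a pitch/2 gate. The gate is centred on the
   rest position shifted by the previous frame's median displacement:
   with slow stage drift the cumulative offset can approach pitch/2 over
   a movie, and a static gate would mis-assign nodes, while the
   frame-to-frame increment stays tiny. The stored raw displacement is
   always detection minus rest position; missing pillars are flagged,
   never interpolated, and a frame with more than 20% unassignable
   detections is an error.
4. **Drift correction** (`classify_reference_pillars()`,
   `correct_drift()`): pillars whose rest position lies outside the cell
   mask dilated by a 2 µm margin (configurable) are references; the
   per-frame mean reference displacement is subtracted from every pillar.
   Any global translation is removed exactly, and the reference-mean
   corrected displacement is zero by construction. Cell masks are inputs
   (drawn or simulated); segmentation is out of scope.
5. **Forces and aggregation** (`compute_forces()`,
   `aggregate_cell_forces()`): $F = k d$ componentwise on corrected
   displacements. The per-cell "total force" sums force *magnitudes* over
   under-cell pillars — a net vector sum would largely cancel for a
   contractile cell — and the net vector magnitude is reported alongside.
   Per-frame tables are kept so either per-pillar-over-frames or
   per-frame-over-pillars summaries can be formed.

`tfm_recovery_benchmark()` wires the whole chain against the simulator
and reports per-pillar relative force errors and the residual reference
displacement; it is the package's own end-to-end validation and what the
acceptance script runs.

## Morphometry and motility

Cell shape uses the standard equivalent ellipse: the ellipse sharing the
mask's area-normalized second-order central moments. Axis lengths are
$4\sqrt{\lambda_{1,2}}$ for the eigenvalues of the pixel covariance, and
the aspect ratio $\sqrt{\lambda_1/\lambda_2} \ge 1$; this is the
moment-based definition common imaging tools use, not a contour fit, and
it is rotation-, translation- and scale-invariant up to discretization.
Masks must be a single connected component; callers split multi-cell
masks first.

Track metrics follow the travel-distance convention: path distance is the
sum of consecutive step lengths, mean velocity is path distance over
elapsed time (not a per-step average — the two differ for irregular
sampling), and net displacement is start-to-end. Tracks must be uniformly
sampled (default every 5 min over 6 h); gaps up to two missing samples
are bridged linearly by `bridge_track_gaps()` — at 5-min sampling a
10-min gap changes a path length negligibly — while longer gaps split the
track, because bridging them would manufacture straight-line motion.

Group comparisons use one-way ANOVA with pooled-SD pairwise t-tests and
Bonferroni adjustment (adjusted p = min(1, m·raw) over the m pairs),
significance at p < 0.05.

## Omics fold-change filters

Gene tables are filtered at a 3-fold cutoff applied symmetrically — a
feature passes when the treated/control ratio or its reciprocal exceeds
the cutoff — because downregulated features are as informative as
upregulated ones; the cutoff is on the linear ratio scale (configurable).
Metabolites pass at |relative change| > 20%. Both filters are monotone in
their cutoff by construction. Tables are assumed pre-normalized
(microarray quantile normalization and similar preprocessing are
upstream of this package); non-positive levels are skipped with a
counted warning. `export_network_nodes()` emits the flagged features as
an (id, class, direction, magnitude) table for external network tools.

## The synthetic-data generator

The generator exists so every analysis stage has a known answer:

* **Pillar movies**: bright spots on a dark background — each pillar a
  PSF-blurred disk approximated by a Gaussian whose variance is
  $\sigma_{\mathrm{PSF}}^2 + R^2/4$ (the disk's second moment), which
  preserves the centroid the tracker estimates — at rest position plus
  planted deflection plus cumulative linear drift, with Poisson shot
  noise and optional Gaussian read noise. Defaults follow the array the
  analysis targets: 1.8 µm pitch, 0.9 µm diameter, 0.1 µm pixels, PSF
  sigma 1.5 px, peak 500 counts over background 10. Deflections above
  pitch/2 are rejected at specification time since no tracker could
  identify them.
* **Laurdan scenes**: channels built as $I_{420} = T(1+\mathrm{GP})/2$,
  $I_{473} = T(1-\mathrm{GP})/2$ before noise, so the GP formula inverts
  the construction analytically. In floating point the inversion is
  *bit-exact* when GP and $T$ are exactly representable; the validation
  suite therefore uses GP fields quantized to 1/256 (0.004 GP units,
  far below any measurement noise) with power-of-two $T$, and asserts a
  zero maximum error, while unrestricted fields invert to machine
  epsilon.
* **Tracks**: constant-speed persistent random walks — one speed per
  cell, heading increments with configurable sd, 5-min sampling over 6 h
  — whose truth table (speed = path length / duration) is exact by
  construction.
* **Omics tables**: log-normal baselines with planted multiplicative
  fold changes and optional log-normal noise; truth flags follow the
  planted change against the 3-fold / 20% cutoffs.

All draws come from one seeded generator per scene; a fixed seed gives
byte-identical outputs, and the caller's RNG state is restored.

What the generator deliberately does **not** emulate: photobleaching and
blinking, spatially varying background and illumination, pillar-top vs
base parallax and substrate warping, 3-D bending profiles, cell-shaped
(non-disk) masks, segmentation errors, track gaps from detection
failures, and correlated omics noise. Passing tests therefore demonstrate
that the analysis chain is correct and well-conditioned under realistic
shot-noise and drift levels — not that it is robust to every artifact of
real microscopy; on real data the dominant additional error sources are
illumination structure and mask quality.

## Problem sizes and numerical choices

The validation suite and the acceptance script use 240×240 px, 20-frame
movies (≈140 pillars) at five seeds for the end-to-end force recovery,
10^5-pixel GP maps for Gaussian-fit recovery, and 400×400 px masks for
morphometry — sizes at which the planted effects are measured with
comfortable statistical headroom while the whole suite runs in well under
a minute. Tolerances asserted in tests are stated next to each check;
notable internal constants are the detection threshold and centroid floor
above, the lattice-trim threshold max(4·MAD, 0.03·pitch), and the
pitch/2 assignment gate with ties broken toward the smaller displacement.

## Limitations

Beam theory is linear: forces from deflections beyond the small-bending
regime (roughly a quarter of the pillar height) are extrapolations. The
stiffness formula assumes a rigid base and uniform modulus; calibrated
overrides are first-class for that reason. Drift correction removes only
global translation — rotation or field distortion would need a
higher-order reference model. The GP pipeline applies no spectral
calibration, so absolute GP values are instrument-specific even though
differences and shifts are comparable within an instrument.
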