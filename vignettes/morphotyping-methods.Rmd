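---
title: "Morphotyping methods: models, conventions and design choices"
author: "fibromorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphotyping methods: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibromorph)
```

This vignette is the package's own account of its methods: the models and
conventions each stage implements, the tunable parameters and their
defaults, what the synthetic-scene generator does and does not emulate,
and the design choices made where several defensible options existed.
No empirical claim is made here beyond what the test suite and
`scripts/acceptance.R` themselves compute.

## The problem and the pipeline

Fibroblasts cultured on adhesive line micropatterns (width × spacing of
20×20, 10×10 or 5×5 µm) elongate, align, and remodel their focal
adhesions (FAs); quantifying this *morphotype* requires per-cell
measurements at three object levels — whole cell, nucleus, FA — plus
spatial and orientation statistics. The pipeline runs:

simulate (optional) → preprocess → segment → measure → normalize →
spatial/orientation → determinant ranking → group statistics.

Stages communicate through files (CSV tables, TIFF images) so any stage
can be re-run in isolation; `run_all()` orchestrates them from a single
YAML-able configuration and records a provenance manifest (config hash,
seeds, versions, per-stage timing).

## Coordinate and unit conventions

* Images are `pixels[row, col]` matrices; centroids are **1-based
  (row, col) pixel-centre coordinates**, R's native array convention.
* Orientations θ are measured counter-clockwise from the +column (x)
  axis with y pointing against the row index, wrapped into (−90°, 90°];
  exact perpendicularity reports +90°, never −90°.
* All lengths and areas are micrometres (µm, µm²) derived through the
  mandatory `pixel_size`; distances and axes scale linearly, areas
  quadratically (the scale-equivariance property test asserts this).

## Preprocessing

* `max_project()` — per-pixel maximum over z-planes.
* `autocontrast(img, saturated = 0.0035)` — a linear rescale mapping the
  `saturated/2` and `1 − saturated/2` intensity quantiles to [0, 1] with
  clipping outside. The default saturates 0.35% of pixels, the common
  enhance-contrast convention; the percent-vs-fraction reading of "0.35"
  is resolved toward percent and is config-overridable. Constant images
  are returned unchanged with a `degenerate` flag.
* `tophat(img, radius = 5)` — white top-hat with a flat disk (image minus
  its morphological opening), retaining bright structures smaller than
  the disk. The element size is exposed because no single value suits
  both pixel sizes; 5 px at ~0.5 µm/px comfortably exceeds FA puncta.
  Opening commutes with monotone affine intensity maps, so inputs of any
  range are rescaled into the morphology engine's [0, 1] domain and
  mapped back exactly; borders are replicate-padded.

**Order of operations for the FA channel.** `preprocess_image_set()`
applies the top-hat to the *raw* FA channel and then rescales the result
to [0, 1] **without clipping** (`fa_saturated = 0`). A clipping
autocontrast is counterproductive here: FA puncta typically occupy well
under 0.35% of the field, so the saturated fraction would clip every
punctum *and* the upper noise tail to the same value, destroying exactly
the separation the top-hat creates. Because threshold selection is
invariant to monotone rescaling, the non-clipping rescale loses nothing.

## Segmentation

* **Nuclei (primary).** Otsu's two-class threshold is computed on a
  256-bin histogram by exhaustively maximizing the inter-class variance
  σ²_b(t) = w₀w₁(µ₀ − µ₁)²; ties break toward the smallest t, and a
  single-valued histogram is flagged degenerate (empty foreground).
  Foreground is hole-filled, components are 8-connected, and objects are
  filtered to [`min_area` = 50, `max_area` = 500] µm² with
  border-touching objects removed by default (truncated objects would
  bias morphometry).
* **Cells (secondary).** The foreground is the union of the actin Otsu
  foreground and all nucleus pixels; every foreground pixel is assigned
  to the nucleus seed with the smallest *geodesic* (within-foreground)
  distance, computed by a multi-source Dijkstra with steps 1 and √2 and
  deterministic smaller-label tie-breaks. This guarantees exactly one
  cell per nucleus, each nucleus inside its own cell, and a boundary at
  the perpendicular bisector between equal seeds in uniform foreground.
  When the actin channel is entirely below threshold, each cell
  degenerates to its nucleus footprint by design.
* **FAs (tertiary).** The threshold histogram is restricted to pixels
  *inside the union of cell masks* (the masking-first order). This
  restriction matters: within the cell interior, puncta are a percent or
  so of pixels and two-class Otsu separates them cleanly, whereas over
  the whole field they are so rare that Otsu splits the background mode
  instead. A Gaussian pre-smoothing (`smooth_sigma = 1` px) suppresses
  single-pixel shot-noise speckle. Components are filtered at
  `min_area = 0.4` µm²; each FA's parent is the cell covering the
  majority of its pixels, and FAs outside all cells are discarded.
* Connectivity is 8-connected throughout, implemented in C++ because the
  available labeling routine is 4-connected; the manual object-editing
  step of interactive pipelines is replaced by these deterministic
  filters (externally corrected label maps can be supplied as
  `label_map` objects at any point).

## Morphometry

Per object: area, perimeter, equivalent diameter, major/minor axis,
aspect ratio, eccentricity, orientation, solidity, extent, form factor
4πA/P², compactness (its reciprocal), and max/min Feret diameters.

* Moments use the second central moments of pixel centres **plus 1/12**
  on the diagonal (each pixel treated as a unit square); axes are
  4√λ, matching the full axes of the moment-equivalent ellipse, and
  e = √(1 − λmin/λmax).
* The perimeter is the outer-boundary walk with diagonal steps weighted
  √2 (Moore contour tracing with a state-cycle termination); objects are
  hole-filled first, and degenerate objects with fewer than three
  boundary pixels fall back to exposed pixel-edge length. The convention
  is stated because perimeter-derived quantities (form factor, FA
  perimeter) depend on it; a 10×10 px square walks to exactly 36 px.
* Solidity uses the convex-hull *image* (pixels whose centres fall in
  the hull), so a filled square scores exactly 1; Feret diameters come
  from rotating calipers on the hull with +1 px for pixel extent.

**The 40-feature catalog** is fixed in code (`feature_catalog()`):
13 descriptors at cell level, the same 13 at nucleus level, 13 FA
aggregates (mean/sd of area, perimeter, major axis, eccentricity; mean
minor axis, aspect ratio, form factor, solidity; total FA area), and the
FA count. The exact membership of the catalog is a documented stand-in
(the canonical determinants — FA eccentricity, cell long axis, nucleus
eccentricity, areas, perimeters — are all present); cells without FAs
carry zeroed aggregates plus an explicit `zero_fa` flag.

**Two-point normalization.** For each feature,
n = (x̄ − x̄_ctrl)/(x̄_myo − x̄_ctrl) maps the control-condition mean to 0
and the myofibroblast-anchor mean to 1. Means (not medians) are used for
non-anchor conditions. Features whose anchor gap is below a relative
tolerance (10⁻⁹) are flagged `defined = FALSE` and retained, never
silently dropped.

## Spatial statistics and orientation

* FA–nucleus distance is measured from each FA centroid to the nucleus
  centroid **of its parent cell** (not the nearest nucleus), in µm.
* Cell and fiber orientations are axial (180°-periodic); all circular
  statistics use doubled angles. The order parameter
  S = |⟨e^{2iθ}⟩| is 1 for perfect alignment and 0 for isotropy, and is
  invariant to flipping any subset of orientations by 180°.
* The fiber orientation map ridge-enhances the actin image with a
  Frangi-style vesselness filter (bright ridges, scale-normalized
  Gaussian Hessians at scales {1, 2, 4} px — fixed across images, i.e. a
  constant parameter combination; β = 0.5, structureness cutoff at half
  the per-scale maximum) and takes local orientation from the smoothed
  structure tensor (gradient at the mid scale, tensor smoothing at twice
  that). The histogram is vesselness-weighted; blank images return an
  `undefined` flag rather than a value.

## Determinant ranking and group statistics

* `rank_features_shap()` fits one seeded xgboost binary classifier per
  non-control condition (one-vs-control; fixed hyperparameters
  `nrounds = 60`, `max_depth = 3`, `eta = 0.3`, single-threaded for
  determinism), standardizes features internally, drops constant
  features with a warning, and ranks by mean |φ| pooled over conditions.
  Attributions come from the engine's exact tree-path algorithm
  (`predcontrib`); local accuracy (Σφ + base = margin) holds to float32
  precision. Model quality is seeded cross-validated accuracy; a model
  not beating the binomial 95% band at p = 0.5 is flagged near-chance
  and the report marked unreliable.
* `shapley_tree_attributions()` is the slow independent route: full 2ⁿ
  enumeration (`exact_shapley()`) of the cover-weighted tree-path
  expectation game, in double precision. Two float32 details are
  essential for agreement with the fast engine: the sample is rounded
  through single precision before descent, and split thresholds parsed
  from the model dump (printed at 9 significant digits, which
  round-trips float32 but not double) are restored to their exact
  float32 values. Without these, samples within 1 ulp of a split route
  differently.
* `anova_dunnett()` uses the standard one-way ANOVA decomposition, then
  Dunnett many-to-one comparisons with the adjusted p computed by seeded
  Monte Carlo (default 10⁵ draws) of the null max-|T| statistic.
  Draws are generated group-by-group so that enlarging the comparison
  set reuses the same underlying draws, making the monotonicity of
  adjusted p in the number of comparisons exact under a fixed seed; the
  adjusted p is additionally floored at the unadjusted per-comparison t
  p-value, a bound the exact Dunnett distribution satisfies. Monte Carlo
  over closed-form tables was chosen for arbitrary unbalanced group
  sizes with seed-exact reproducibility.

## Auxiliary assays

* **Hertz (pyramid) fit.** F(δ) = tan α/(√2(1 − ν²)) · E · (δ − δ₀)² for
  δ > δ₀, the four-sided pyramidal indenter form, with ν = 0.5 for cells;
  both are config-exposed since vendor software rarely documents its
  variant. For fixed δ₀ the optimal E ≥ 0 is closed-form, so the fit
  profiles the residual over δ₀ (101-point grid, golden-section
  refinement). Units: E in Pa, δ in µm, F in nN (prefactor includes the
  10⁻³ Pa·µm² → nN conversion). The contact point is fitted, not assumed
  at zero, because real curves have unknown contact. All-zero curves
  return E = 0 with a degenerate flag.
* **ΔΔCt.** ΔCt = Ct_target − Ct_ref per sample; ΔΔCt is the group-mean
  difference to the control group; fold = 2^(−ΔΔCt), so control folds are
  identically 1. Amplification-efficiency correction is out of scope.

## The synthetic-scene generator

`generate_scene()` renders what the study conditions require and nothing
more: elliptical cell bodies placed without overlap (≥ 3 µm clearance,
bounded rejection sampling with an explicit infeasible-packing error),
optionally clipped to the line-pattern mask when the gap exceeds the
cell's bridging width (12 µm default); centred elliptical nuclei that are
always part of their cell; FA puncta placed in a perinuclear annulus
(15–45% of the cell's elliptical radius) or a peripheral band (72–90%)
with probability `fa_radial_placement`, oriented near the cell axis;
additive Gaussian noise (sd 0.08) plus Poisson shot noise (scale 200) on
amplitudes ≤ 1, i.e. SNR near 10 — the regime the default segmentation
settings are designed for. Orientations are wrapped-normal around the
pattern angle with sd 45°/concentration (uniform at concentration 0),
which makes the orientation spread strictly monotone in the
concentration parameter.

Deliberate generator choices:

* **Elongated shapes by construction.** Cell width is capped at 0.85 ×
  length and nuclear minor axis at 0.8 × major (defaults: nucleus
  17 × 10 µm, cell 60 × 18 µm). Fibroblast cells and nuclei in
  contact-guidance experiments are clearly elongated, and near-circular
  objects make eccentricity ill-conditioned (the error in *e* scales as
  1/(2e)), which would turn the recovery tolerances into noise rather
  than a meaningful check.
* **Resolvable puncta.** FA placement enforces ≥ 2 µm clearance between
  punctum boundaries, so "FA count" is well-defined and exact count
  recovery is a property of the conditions, not luck.
* **Ground truth is analytic.** Tables record sampled centres, axes,
  orientations and e = √(1 − (b/a)²); rendered label-map centroids agree
  within 0.5 px and pixel areas within 2% of πab for non-clipped
  objects.

What the generator does **not** emulate: optics (no PSF, single plane —
z-stacks are simulated as attenuated noisy copies only for projection
tests), intensity texture inside cells (actin fibers are tested with
separate line-texture images), touching or overlapping cells, clipped
ground-truth shape parameters (clipped cells are flagged and excluded
from recovery tests), and FA-scale rasterization fidelity: a ~2 × 1 µm
punctum at 0.5 µm/px covers ~7 pixels, so its area and eccentricity are
pixelization-dominated; recovery tolerances (area 2%, major axis 3%,
e 0.02, centroid 0.5 px) are therefore asserted for cells and nuclei,
and centroid recovery only for FAs. Passing tests show the *measurement
and segmentation machinery* is correct at these geometries; they do not
certify performance on real images with debris, uneven illumination, or
confluent cells.

## Numerical choices and degenerate inputs

* Otsu ties → smallest threshold; degenerate histograms → flagged, empty
  foreground. Geodesic ties → smaller seed label. Empty label maps →
  empty tables, not errors; missing FA parents, broken cell–nucleus
  bijections, or absent anchors → immediate contract errors.
* CSV output is written at 17 significant digits (`%.17g`), which
  round-trips IEEE doubles exactly; image output uses 16-bit TIFF
  samples (bit-exact for 8/16-bit sources).
* All randomness flows from explicit seeds (`scene_spec(seed=)`,
  `rank_features_shap(seed=)`, `anova_dunnett(seed=)`, the pipeline's
  config seed), and `run_all()` is byte-deterministic in its CSVs.

## Problem sizes used in validation

The test suite and acceptance script run at desk scale, chosen to keep a
full validation under a couple of minutes while leaving comfortable
statistical margins: default scenes of 10 cells × 8 FAs on 768² px at
0.5 µm/px; pipeline runs with 2 conditions × 2 images × 5 cells on 448²
px; 100-histogram Otsu oracle sweeps; 20-seed simulation studies for the
planted SHAP determinant, noisy Hertz recovery, and ΔΔCt; 10⁴–10⁵ draw
Dunnett Monte Carlo. Each was fixed before the corresponding check was
first run and is stated here as the package's validation design.

## Known limitations

* Segmentation has no declumping: touching nuclei or cells would merge.
  The generator never produces them; real confluent fields would need a
  watershed step.
* FA morphology from segmented masks is resolution-limited (puncta
  minor axes inflate by roughly a pixel under smoothing + thresholding);
  cross-condition *contrasts* of FA shape remain informative because the
  bias is shared, but absolute FA eccentricities are convention-bound.
* The SHAP model class (boosted trees, one-vs-control) and its
  hyperparameters are fixed, documented choices; rankings from other
  model families may differ.
* The vesselness scales {1, 2, 4} px are stand-in defaults; for other
  magnifications they should be set to the expected fiber widths.
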