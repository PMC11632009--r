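---
title: "Methods: unrolling tubular vessels and comparing endothelial cell shapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: unrolling tubular vessels and comparing endothelial cell shapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesselmorph)
```

## The measurement model

Endothelial cells (ECs) line the lumen of blood vessels, which at the
scale of an embryonic axial vessel are well approximated by straight
generalized cylinders: a straight centerline with a constant conic cross
section (circle or ellipse for an intact tube, a hyperbola branch for an
open, saddle-shaped wall segment such as a remodelling plexus wall). A
traced EC is an ordered closed loop of ~100 boundary points in 3D,
micrometre units.

Planar shape parameters are obtained by developing the wall onto a plane:

1. **Centerline.** The axis direction is the principal direction of the
   pooled boundary points of one vessel segment, and the origin their
   centroid. A principal axis alone is biased when cells cover the tube
   asymmetrically, so by default the direction is then polished by
   minimizing the RMS Sampson residual of the conic fitted to the points
   projected along the candidate axis (Nelder–Mead over the two rotation
   angles). For a noiseless generalized cylinder this objective is exactly
   zero at the true axis. The polish matters: on sparse cohorts (5–15
   cells) it reduces axis error from ~10^-2 rad to below 10^-5 rad, which
   is the difference between per-mille and per-cent area errors
   downstream.
2. **Rigid alignment.** Points are mapped through
   `rotation %*% (p - origin)`; the rotation is proper orthonormal, so all
   pairwise distances are preserved to machine precision.
3. **Cross-section conic.** A direct least-squares conic is fitted to the
   transverse (y, z) coordinates. For ellipses we use the
   ellipse-constrained direct fit (`4AC − B² = 1`) in the Halir–Flusser
   formulation, which is non-iterative and always returns an ellipse; for
   hyperbolae, the unconstrained algebraic fit (smallest right singular
   vector of the design matrix). `kind = "auto"` fits the unconstrained
   conic, classifies by the discriminant `B² − 4AC`, and refits ellipses
   with the constrained method. Points are centred and isotropically
   scaled before fitting so the normal matrices stay well conditioned at
   micrometre magnitudes.
4. **Unrolling.** Each point is projected to its nearest point on the
   conic (coarse 720-cell parameter grid, then golden-section refinement
   to 10^-12), and its transverse position is replaced by the signed arc
   length *s* along the conic to that projection. The axial coordinate
   passes through unchanged. A generalized cylinder is developable, so for
   an exact fit this mapping is an isometry: areas, lengths and angles in
   the (x, s) plane equal their geodesic counterparts on the wall.
5. **Shape parameters.** Area is the shoelace polygon area of the closed
   unrolled outline; perimeter the closed polyline length; elongation and
   angle come from an ellipse fitted to the unrolled boundary
   (elongation = a/b; angle = the major-axis angle to the vessel axis,
   folded to [0°, 90°] because an undirected axis is defined modulo 180°
   and alignment is an unsigned deviation from the flow axis).

### Seam placement

Arc length on a closed conic is periodic, so a seam is unavoidable. It is
placed per cell, in the middle of the largest angular gap of that cell's
own projected points — the angle farthest from the cell — which guarantees
*s* is continuous along every outline (no 2πr jumps inside a cell). A
global seam convention would corrupt any cell that happens to straddle it.
Outlines whose unwrapped angular span reaches 2π (a cell wrapping the
whole tube) cannot be developed injectively and are rejected.

### Numerical choices

* Ellipse arc length has no closed form; cumulative composite Simpson
  quadrature on 2^13 intervals with a monotone (Hyman) spline inverse
  gives relative errors around 10^-12, far below tracing noise.
* The radial tolerance band for unrolling defaults to 20% of the mean
  semi-axis; points farther from the conic than that are reported by index
  and the cell is rejected rather than silently distorted.
* The parabola boundary (`|B² − 4AC| < 10^-9 (A² + B² + C²)`) is treated
  as a degeneracy error: a parabolic cross section has no finite centre
  and cannot be developed by this scheme.
* Conic fit quality is reported as the RMS Sampson (first-order
  orthogonal) distance, in micrometres.

## Vessel-level measurements

Diameters are read off per axial station: a conic is fitted to the points
in a 4 µm slab around the station and the diameter is the full extent of
that conic along one transverse direction (default y). A single direction,
rather than the mean width, matches how diameters are measured on
maximum-intensity projections, which collapse one axis. The per-vessel
value is the arithmetic mean over stations; in synthetic vessels stations
are equally spaced axial positions, standing in for the midpoints between
successive intersegmental vessels used as landmarks in vivo. Cell counts
use the outline centroid and a half-open window [start, start + 430 µm) to
avoid double counting at boundaries; proliferation rates are events
divided by that count.

## Population comparison

The four features are always handled in the fixed order area, angle,
elongation, perimeter (`vm_feature_cols`).

**Normalization.** Features are z-scored before embedding. For the
divergence the scaling is pooled across the two groups being compared:
per-group scaling would erase exactly the mean and scale differences the
divergence is supposed to measure. A `normalize = FALSE` escape hatch
preserves raw-feature behaviour.

**UMAP.** Defaults n_neighbors = 15, min_dist = 0.1, Euclidean metric.
Determinism is a hard contract here: exact (FNN) nearest neighbours and a
single-threaded, seeded layout make coordinates bitwise reproducible for a
fixed seed, so pipeline reruns are checksum-identical. Each group's
scatter is outlined by its covariance ellipse scaled by the chi-square
quantile for a 90% mass fraction — a display convention, not a test.

**Jensen–Shannon divergence.** One Scott's-rule Gaussian KDE per group
(bandwidth matrix `cov(X) · n^(-2/(d+4))`, d = 4), both densities
evaluated on the pooled sample points of the two groups, renormalized to
discrete distributions, then the discrete JSD with log base 2. Base 2 is
what makes the [0, 1] bound hold. This plug-in scheme is deterministic
given the data (no auxiliary sampling), symmetric by construction (the
evaluation set is the same for both orderings), and exactly zero for a
group against a copy of itself. Grid integration is not an option in 4D.
Because the divergence and the distance (its square root) are frequently
conflated in practice, both are always reported. Groups with fewer than 5
cells, or with duplicated points that make a covariance singular, are
refused with an actionable error rather than silently jittered.

A permutation test (`jsd_permutation_test()`) calibrates an observed JSD
against label shuffles of the pooled records, since the plug-in estimate
of two finite samples from the same distribution is positive, not zero.

## The synthetic-data generator

The generator exists so that every stage has ground truth. Defaults are
chosen to resemble embryonic axial vessels at ~72 hpf: artery-like tubes
of radius 12.5 µm (25 µm diameter) carrying fewer, larger cells
(mean 450 µm²), vein-like tubes of radius 17.5 µm with more, smaller
cells (mean 300 µm²); lognormal areas with CV 0.2; mean elongation 1.8;
orientation angles Gaussian around 25° (SD 18°); 100 boundary points per
cell; isotropic tracing noise of SD 0.2 µm, small against cell scales of
tens of micrometres. Group contrasts are expressed as a multiplier on the
mean area (e.g. 1.17 or 1.5 for "+17%"/"+50%" groups), which the
lognormal generator honours exactly in expectation.

Cells are ellipses in the developed (u, s) plane, placed on a
non-overlapping grid of slots sized to the largest drawn cell; a vessel
with `length = NULL` is auto-sized to hold its population, so oversized
draws are never truncated (truncation would bias the realized mean area
and break effect-size fidelity). Ellipses give closed-form truth for all
four parameters. Tessellation requires an untapered tube because only
generalized cylinders develop isometrically; tapered tubes are still
available for diameter work via `sample_surface_points()`.

What the generator does **not** emulate: real EC outlines are polygonal
and concave, neighbours share borders rather than leaving gaps, tracing
error is anisotropic (worst along the optical axis), and centerlines
curve. Passing the recovery suite therefore shows the geometry and
statistics are implemented correctly, not that the pipeline is robust to
every property of real tracings.

## Design decisions that were genuinely open

* **Area from polygon, not π·a·b.** The traced outline is the
  measurement; the ellipse is introduced only to define elongation and
  angle. `area_from = "ellipse"` provides the alternative, and both
  variants are kept as columns.
* **Per-vessel vs per-cell conic.** Default is one conic per vessel
  segment from pooled points ("the cross section of the vessel"); a
  per-cell scope (`fit_scope = "cell"`) exists for tapered or irregular
  segments.
* **Angles in degrees folded to [0, 90]**, flagged low-confidence below
  elongation 1.05 where orientation is unidentifiable.
* **Uniform arc-length point spacing** in the generator, with a
  `jitter_spacing` flag, since real tracing spacing regularity is
  unknowable from the data.
* **No shell CLI.** The exported functions, `run_pipeline()` with a JSON
  config, and this vignette are the interface; an R user drives the
  pipeline from scripts.

## Problem sizes and verification

The test suite checks, among others: conic recovery from noiseless
parametric samples (1e-6 to 1e-4), exact cylinder development against the
closed form (x, r·θ) at 1e-6 µm, ground-truth recovery on 200-cell
cohorts (areas within 1% noiseless; median within 3% under 0.2 µm noise),
diameter recovery within 0.5% at 9 stations under noise, end-to-end
effect-multiplier recovery (1.17 and 1.5 at n = 200/group, within 3
combined SEM), monotone median JSD over separations of 0–10 pooled SD
(20 replicates at n = 500/group), rigid-motion and scale equivariance,
and checksum determinism of the whole pipeline including UMAP. These sizes
were chosen as the smallest at which the statistical checks have
comfortable power.

## Known limitations

Straight centerlines only; no surface reconstruction or meshing; the
conic is constant along the axis (taper is flagged by the radial band,
not modelled); the KDE-JSD is a plug-in estimate whose finite-sample bias
is positive (use the permutation test for calibration); UMAP coordinates
are reproducible but, like all neighbour embeddings, not a metric-faithful
map of the 4D space — the JSD, not the embedding, is the quantitative
comparison.
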