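---
title: "Quantifying endothelial motility, sprout arbors and vessel morphometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying endothelial motility, sprout arbors and vessel morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sproutquant)
```

## Scope

`sproutquant` quantifies four readouts of endothelial cell behaviour that are
routinely measured in angiogenesis assays:

1. **cell and sprout-tip motility** from tracked positions (average
   displacement versus time lag; time-dependent average speed),
2. **multicellular sprout arbors** grown from spheroid aggregates in 3D gels,
   quantified by a cylinder-based (modified Sholl) traversal count from
   brightfield z-stacks,
3. **vessel-network morphometry** (density, mean width, total length per
   field) from fluorescence images of quasi-2D tissue such as fetal chorion,
4. **gelatin degradation** (fraction of substrate digested) from fluorescent
   gelatin assays.

Cell detection and tracking are out of scope: tracks are an input, in the
tabular format produced by interactive trackers. So is any model fitting on
top of the motility curves (persistence models, MSD fits).

## Trajectory statistics

With $x_i(t)$ the position of cell $i$ at time $t$ on a uniform grid of
spacing $\Delta t$, the average displacement over lag $\tau$ is

$$ d(\tau) = \left\langle\, \lVert x_i(t+\tau) - x_i(t)\rVert \,\right\rangle_{i,t}, $$

averaged over *every* cell and time point for which both endpoints were
observed (overlapping windows). The time-dependent average speed uses a fixed
lag $\tau_0$ (1 h by default, matching hourly sprout-tip sampling):

$$ v(t) = \left\langle\, \lVert x_i(t+\tau_0) - x_i(t)\rVert / \tau_0 \,\right\rangle_{i}. $$

Notes on conventions, all deliberate:

* $d(\tau)$ is the mean displacement **magnitude** in µm — the quantity
  plotted in motility figures. A root-mean-square variant is available via
  `rms = TRUE`.
* $v(t)$ is a **chord speed** over the lag window; it under-estimates the
  path speed of strongly turning cells. This is a property of the estimator,
  shared by the assays it reproduces, not a bug.
* Missing observations exclude pairs; nothing is imputed, smoothed or
  drift-corrected.
* SEM is computed from the **population** variance of the pair (or cell)
  population, $\mathrm{SEM} = \hat\sigma_\mathrm{pop}/\sqrt{n}$. This makes
  pooling exact: `pool_curves()` merges the underlying populations from the
  stored moments, so pooling a curve with itself halves the variance of the
  mean exactly. Displacement pairs sharing a track are correlated, so the
  reported SEM for displacement curves is an optimistic error bar; it is
  computed over pairs, not cells, and documented as such.

## The modified Sholl analysis of sprout arbors

The input is a brightfield z-stack of a fixed aggregate with sprouts
(default geometry: 20 µm slice spacing, ≈10 µm depth of field, so the axial
sampling is *gapped* — half the volume is never in focus).

1. **Segmentation.** Each slice is segmented by local intensity variance
   (`local_variance_map()`, exact summed-area-table implementation with
   reflected borders): in-focus multicellular structures are strongly
   textured, out-of-focus structures are smooth. The threshold is chosen by
   Otsu's between-class-variance criterion on the log-variance values. For a
   whole stack the histogram is pooled over all slices before thresholding:
   slices that contain no in-focus structure are unimodal on their own, and a
   per-slice threshold there would split the background noise mode.
   Components smaller than `min_size_px` (default 9 px) are removed.
2. **Reconstruction.** Each foreground pixel of slice $k$ becomes a voxel at
   $z = k\,\mathrm{d}z$ with axial extent equal to the depth of field. Voxels
   are *not* stretched across the inter-slice gap; instead the particle
   counting tolerates one-slice gaps (below).
3. **Aggregate localization.** By default the aggregate is the largest
   connected component of the middle slice; its centre and radius are taken
   from the maximum of the Euclidean distance transform (largest inscribed
   circle). A centroid/equivalent-radius rule was considered and rejected:
   sprouts attached to the aggregate outline are thin but long, and inflate
   an area-equivalent radius by tens of percent, while the inscribed circle
   ignores them. Manual centre/radius override is supported.
4. **Cylinder traversals.** Concentric cylinders (radii 20–560 µm, step
   20 µm) with their axis through the aggregate centre are sampled at arc
   steps of one pixel over all z levels; a surface point is marked iff it
   lies in an occupied voxel. The rolled-out surface (angle × slice) is the
   flattened-cylinder representation in which each sprout crossing appears as
   a patch.
5. **Particle counting.** Patches are connected components with
   8-connectivity, an angular wrap (a patch split across the θ = 0 seam is
   one sprout) and a one-slice axial gap tolerance, because a sprout crossing
   between two sampled planes appears as two thin patches one empty column
   apart. Patches under `min_patch_px` (default 4 samples) are speckle.
6. **Zone boundary.** Traversal counts rise through the branching zone and
   fall through the elongation zone; the boundary is the smallest radius
   outside the aggregate attaining the maximal count (ties toward the
   smaller radius). Radii at or inside the aggregate radius are flagged and
   excluded.
7. **Length distributions.** Per aggregate, counts at radii beyond its own
   boundary are re-expressed against sprout length beyond the boundary;
   group means are normalized by the control group's average count at its
   boundary, so the control curve is 1 at length 0 by construction. Length
   is measured from the zone boundary (not the aggregate surface); a
   different convention would shift, not reshape, the curves.

## Morphometry estimators

Vessel density is the foreground fraction of the segmented mask — exact by
definition. Width and length require a declared estimator, since "width of a
network" is not unique:

* **Length** is the topological skeleton length (Zhang–Suen thinning,
  implemented in-package), counting lateral steps as one pixel and diagonal
  steps as $\sqrt 2$ pixels, with a diagonal step skipped when a lateral
  two-step path covers it. Terminal spurs shorter than 1.5× the local radius
  at their junction are pruned (thinning artifacts at blunt ends), and each
  remaining free end is extended by its local radius, because the medial
  axis retreats by one radius at a blunt end. On rectangular bar phantoms
  4–40 µm wide this keeps length within 5% and width within one pixel.
* **Width** is twice the mean Euclidean distance-transform value along the
  skeleton, excluding points within one local radius of junctions (where the
  distance transform is inflated) and endpoints (where it is deflated).
* Hole filling during vessel segmentation is limited to speckle-sized holes
  (default 50 µm²): at the high densities of real chorion fields, enclosed
  avascular gaps are genuine structure and must not be filled.

Gelatin digestion is the fraction of pixels below threshold (digested
regions lose fluorescence), after removal of speckle-sized dark objects.

## Synthetic data and what it does (and does not) establish

Every estimator is validated against generators with exact ground truth:

* **Tracks** are persistent random walks: the heading diffuses so that
  directional correlation decays as $e^{-t/P}$; default persistence
  $P = 8$ h reflects the strongly persistent day-scale motion of endothelial
  cells, and per-step speed equals the programmed schedule ($P = \infty$
  gives exactly ballistic motion). With the default 10-min sampling and a
  1 h speed lag, the chord-speed estimator recovers a programmed 11 µm/h
  within 5%.
* **Arbors** are straight radial tubes (capsules of 14 µm diameter) leaving
  a 90 µm aggregate sphere, with branches appearing only inside the
  branching zone (outer edge 210 µm) at a per-segment rate of 0.12 per
  20 µm shell, stochastically rounded so expected counts scale exactly with
  the configured rates. Radial extents snap to midpoints of the 20 µm
  analysis grid so each tube either fully crosses a cylinder or misses it,
  making ground-truth counts exact. Tubes are placed with a minimum
  angular-arc (34 µm) and axial (80 µm) clearance so that distinct sprouts
  remain resolvable as separate patches — the generator emulates the sparse,
  countable arbors the method is designed for, not confluent networks.
  Rendering is stylized: textured where a tube meets a slice's
  depth-of-field window, smooth defocused shading nearby, noise elsewhere.
  It exercises the focus-variance segmentation but is not an optics
  simulation, so passing tests demonstrate correctness of the geometry and
  counting pipeline, not robustness to real brightfield artifacts
  (uneven illumination is included; debris, halos and gel texture are not).
* **Thinned arbors** (`thin_arbor()`) delete a programmed fraction of tubes
  from a simulated arbor, stratified by origin shell. This provides a group
  with exactly 40% fewer sprouts *at every radius* for validating the
  normalization contract. Independently generated groups would carry that
  deficit only in expectation; at 20 aggregates per group their sampling
  noise alone exceeds a ±1-SEM band, so the paired construction is the one
  that tests the contract rather than generator noise.
* **Vessel fields / gelatin substrates** paint networks (or dark patches) of
  programmed density (or total area) and render them with slight blur and
  noise; closure is within 0.02 density and 0.005 area fraction.

Problem sizes used in the validation suite — 20 seeded arbors spanning 5–25
sprouts for count recovery, 20 aggregates per group for the normalization
contract, 100 cells × 24 h for speed recovery — were chosen to exercise the
full configuration range while keeping per-radius counts in the regime of
the real assays (tens of sprouts per aggregate).

## Numerical choices and degenerate inputs

* All geometry is in µm; pixel indices are 0-based at pixel centres; slice
  $k$ (0-based) sits at $z = k\,\mathrm{d}z$; frame 0 is $t = 0$ h.
* Lags must be multiples of $\Delta t$ (tolerance $10^{-6}\,\Delta t$); time
  grids must be uniform to $10^{-9}$ h. Lags with no valid pair are dropped
  with a warning; an empty track set is an error.
* A flat slice or an all-background threshold result yields an empty mask
  with a warning, not an error; "no sprouts detected" is an error only when
  a profile has no traversals anywhere outside the aggregate.
* Variance maps are computed with summed-area tables (exact, no windowed
  loops); ties in the boundary search resolve toward the smaller radius;
  `which.max` semantics are relied on for the smallest arg-max.
* Empty vessel masks report density 0, length 0 and undefined (NA) width.

## Known limitations

* The displacement SEM treats overlapping pairs as independent.
* Chord speeds under-report path speed for weakly persistent motion; with
  the default generator persistence the bias is under 3%, but the estimator
  is not intended for strongly diffusive cells at long lags.
* The cylinder sampling uses nearest-voxel lookup; sub-pixel anti-aliasing
  is unnecessary at the 20 µm radial step but would matter below ~4 px of
  arc per step.
* Sprout counting assumes sprouts remain resolvable on the cylinder
  surfaces; merging of touching sprouts is counted as one traversal, as in
  the manual convention the method replaces.
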