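---
title: "Nuclear-envelope morphometry from localized NPCs: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nuclear-envelope morphometry from localized NPCs: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucmorph)
```

`nucmorph` reconstructs the budding-yeast nuclear envelope in 3D from the
positions of fluorescently tagged nuclear pore complexes (NPCs) and derives
per-nucleus geometry and population-level spatial statistics. This vignette
explains the models, the tunable parameters and the design decisions, and
states what the simulation-based validation does and does not show.

## The measurement model

A GFP-tagged nucleoporin renders each cluster of adjacent NPCs (a "cNPC") as
a diffraction-limited spot in the envelope; a typical interphase nucleus
shows ~22 such spots. Spot positions are obtained by localization
microscopy: candidate local maxima above a robust threshold
(median + k·MAD of the image, k = 5 by default) are refined by
least-squares fits of an anisotropic 3D Gaussian plus a constant background
over a 7×7×5 voxel window, initialized at σ_xy = 1.3·dx, σ_z = 1.3·dz. Two
quality filters reject fits whose amplitude does not rise k·MAD above the
noise floor or whose width collapses below half a voxel (isolated noise
spikes do exactly that). Detections closer than `min_separation`
(default 0.3 µm) merge, keeping the brighter fit, with ties broken by lower
residual then lexicographic position so output is deterministic. At peak
SNR ≈ 10 the median 3D localization error on rendered test spots is ~7 nm,
comfortably inside the 30 nm the downstream analysis assumes.

All coordinates are physical micrometres: voxel `[i, j, k]` is centred at
`origin + ((i, j, k) − 0.5) · (dx, dy, dz)`. Anisotropic confocal voxels
(dz > dx) make index-space geometry meaningless, so nothing downstream ever
sees voxel units.

The spindle pole body (SPB) shares the NPC channel but is much brighter: the
single detection exceeding 3× the nucleus's median amplitude is taken as the
SPB. If none or several qualify (a duplicated SPB after its replication in
S/G2), the nucleus simply gets no SPB annotation — only cells with a single
unambiguous spot contribute to SPB statistics. The nucleolar channel is
segmented by Otsu's threshold inside a bounding box around each nuclear
center, with a contrast guard (foreground − background > 4× the local MAD)
so a featureless box yields "absent" rather than noise.

## Axial aberration: model and correction

Refractive-index mismatch between immersion optics and the aqueous sample
elongates apparent distances along the optical axis. Because the interphase
yeast nucleus is almost spherical, a population of round nuclei calibrates
this bias directly: for each detection we form the normalized center
distance d/R (R = the nucleus's mean center-to-detection distance) and the
normalized absolute axial coordinate x = |z − z_c|/R, pool the samples, and
fit

d/R = a·x² + b·x + c

by ordinary least squares. The correction subtracts only the x-dependent
part, d_corr/R = d/R − (a·x² + b·x), rescaling each detection's axial offset
so its center distance equals d_corr while its lateral coordinates stay
bit-identical; c is reported but unused. Centers are recomputed afterwards.
A detection whose corrected distance falls below its lateral offset is
clamped to the equatorial plane (counted); a non-positive corrected distance
drops the detection with a warning. The SPB position, which sits in the same
envelope, is corrected with the same formula.

Design notes:

* **x is absolute and normalized.** Pooling across nuclei of different sizes
  requires a dimensionless abscissa, and the aberration is symmetric about
  the focal center; |z − z_c|/R is the only choice that makes a single
  coefficient set meaningful for a population.
* **Round-nucleus selection.** Roundness is judged laterally only (the axial
  coordinate is biased before correction): the x–y covariance ellipse axis
  ratio must not exceed `eccentricity_max` (1.15), *after* dividing the raw
  ratio by a finite-sample calibration factor 1 + 2.6·n^(−0.67). The raw
  eigenvalue ratio of ~22 points from a perfect circle has a null median of
  ~1.23 — the fitted orientation adapts to noise — so an uncalibrated 1.15
  cut would reject half of all truly round nuclei. The calibration was fitted
  once against the Monte-Carlo null (uniform sphere samples, n = 12…100). A
  nucleus must additionally cluster as a single lobe (see below), which is
  what actually removes dumbbells whose long axis points along z.
* **An estimator property worth knowing.** With centers estimated as
  detection centroids, the fitted a is positive even on unaberrated data:
  at large |z|-offset the center distance is mechanically inflated by the
  same error that inflated the offset. The correction is self-consistent —
  it removes the trend it models, and refitting on corrected data yields
  |a| < 0.03 — but the fitted coefficient on real few-spot data should be
  read as "optical aberration plus center-noise curvature". On dense
  samplings with known centers the round trip (inject polynomial stretch →
  fit → correct) restores mean |d/R − 1| < 0.01 and equalizes the per-axis
  distance distributions within 5%.

## Cluster-wise envelope reconstruction

Mitotic nuclei are not star-shaped around one center, so detections are
first partitioned by k-means (squared-Euclidean, Lloyd's algorithm, 20
seeded restarts plus a deterministic warm start derived from the best
(k−1)-solution, which makes the within-cluster sum of squares non-increasing
in k). Clusters need at least 4 members — fewer cannot anchor a surface.

The number of clusters (1, 2 or 3) is selected by a gap rule: k+1 is
accepted only if within_ss(k)/within_ss(k+1) exceeds the step's threshold
*and* the nearest pair of centroids is more than 1 µm apart. The step
thresholds are 2.0 (1→2) and 1.3 (2→3). The first is calibrated on the
sphere null: splitting a spherical shell into hemispheres reduces the sum of
squares only ~1.33-fold, while separating true dumbbell lobes reduces it
several-fold. The second is lower by necessity — the late-anaphase tube
holds a minority of detections, so isolating it cannot halve the cost; for
that step the centroid-separation guard provides the specificity, because
the alternative (splitting one lobe in half) produces hemisphere centroids
less than one lobe radius (< 1 µm) apart. With these defaults, uniform
spheres select k = 1, dumbbells k = 2 and long-tube hourglasses k = 3.
Automatic selection still falsely splits a few percent of spherical nuclei;
for populations known to be interphase, `fit_envelopes(..., force_k = 1)`
applies the single-cluster treatment directly, mirroring how stage-wise
analysis would fix k per cell-cycle stage.

Per cluster, the initial envelope is the convex hull of its detections (the
surface Delaunay triangulation of a star-shaped cloud of envelope points;
implemented as an incremental hull in C++ with a deterministic symbolic
perturbation retry for near-cospherical degeneracies). Two refinement
models:

* **Spline model** (`refine_spline`): butterfly-style interpolating
  subdivision, three passes. Original detections are retained unmoved and
  remain the outermost points of the surface, so this model is a strict
  inner bound — it systematically underestimates surface and volume of a
  convex nucleus. It is kept because its bias direction is known and it
  needs no center.
* **Anchor model** (`refine_anchor`): per pass, every surface triangle emits
  one anchor point along the direction from the cluster center (the
  detection centroid) to the triangle's mass center, at the mean distance of
  the triangle's three vertices to that center; the vertex union is then
  re-triangulated by convex hull. Three passes. Anchors can lie outside the
  detected cloud, removing the inscription bias almost entirely: on 50 exact
  sphere samples the volume is within 2% of the ball.

Known limitation: at very low detection counts the anchor model still
underestimates volume — after three passes from a 12-point patch the final
hull has only ~250 vertices and an inscribed polytope of that size sags ~7%
even when every vertex lies exactly on the sphere (~15% in the mean at
n = 12 including center noise). At the typical 22 spots the bias is ≈ −5%,
and it falls below 1% by n = 100. We did not observe the small-n
*over*estimation that has been reported for this family of models; with a
convex-hull re-triangulation and a centroid center the bias is strictly
negative (distances to a cloud's own centroid shrink as E|p − c̄|² = 1 − 1/n,
so no positive size bias arises there either). A triangle-splitting variant
that keeps original triangles and inserts anchors as apexes was evaluated
and rejected: original edges are never lifted, and it is uniformly worse.

Whole-nucleus geometry merges the 1–3 cluster meshes: volume is the sum of
mesh volumes minus pairwise (minus triple) intersections counted on a voxel
grid (default pitch 0.02 µm, configurable; the convexity of per-cluster
hulls makes point-in-mesh tests exact half-space checks), and surface drops
faces whose centroid lies inside another mesh. Sphericity is
Ψ = π^{1/3}(6V)^{2/3}/S, 1 for a sphere and < 1 otherwise (isoperimetric
inequality); it is the scale-free shape readout used across conditions.

## Population statistics and density maps

The central axis of a nucleus runs from the nucleolar centroid through the
nuclear center and is oriented away from the nucleolus, so an SPB
diametrically opposed to the nucleolus — the interphase configuration — has
α = arccos(axis · unit(SPB − center)) = 0. Signed distances to a fitted
ellipsoid are computed by solving the closest-point equation on the quadric
per detection (root-finding on the Lagrange parameter, tolerance 1e-10).

For population maps, each nucleus is translated to the origin and its
detections (or its SPB) are expressed in cylindrical-collapse coordinates:
s = signed position along the axis with the *landmark at negative s*
(a single orientation convention used everywhere), r = transverse radius
≥ 0. Pooled points feed a product-Gaussian kernel density estimate on a
50 nm grid over [−2.5, 2.5] × [0, 2.5] µm, with each point mirrored to −r so
the estimate is unbiased at the axis; bandwidths default to Silverman's rule
per coordinate (the right order for hundreds-to-thousands of pooled points;
override for very small or very structured sets). Maps can be expressed as
highest-density-region "cumulative percentage" levels — the 50% contour
encloses half the detections — which is also what `autoplot()` draws,
together with display overlays: the median nuclear-envelope circle (radius
median (3V/4π)^{1/3}), the median aligned nucleolar centroid, and a
sphere-cap arc sized from the median nucleolar volume. The arc is a display
approximation only; no statistic is computed from it.

The axial NPC density profile bins the polar angle θ = atan2(r, s) (0 at the
anti-nucleolar pole, π at the nucleolar pole) into 18 bands and divides the
counts by each band's solid angle, so an isotropic envelope reads 1.0
everywhere. This is the readout that exposes NPC depletion at the
nucleolar–nucleoplasmic interface: a rejection-sampled depletion band in the
simulation is recovered as the profile minimum in the same angular range.

## The synthetic-data generator

Every module is validated against generated ground truth:

* **Shapes.** Area-uniform sampling on spheres, ellipsoids (rejection
  against the exact surface element), dumbbells (two lobes, points inside
  the other lobe rejected) and hourglasses (two lobes plus an open
  connecting tube, sampled proportional to area, attachment caps removed).
  Default dumbbell: 0.8 µm lobes, 1.8 µm apart — the alpha-factor-arrest
  morphology of two clearly separated lobes. Default hourglass: 0.75 µm
  lobes 4.2 µm apart with a 0.25 µm tube, a late-anaphase nucleus spanning
  the bud neck. Closed-form surface/volume travel with every sample (exact
  for spheres, spheroids and two-sphere unions; Thomsen's approximation,
  max error ~1.1%, for triaxial ellipsoids).
* **Populations.** Radii log-normal with median 0.894 µm (median volume
  3 µm³, the exponential-growth interphase value) and sdlog 0.12; NPC counts
  Poisson with median 22 (the typical peripheral-spot count), floored at 12;
  nucleolar centroid at 0.55·R on one side (the nucleolus fills roughly a
  third of the nucleus); SPB placed on the envelope with a von Mises–Fisher
  distribution about the anti-nucleolar pole, concentration κ = 5, whose
  median angle (≈ 30°) matches the interphase SPB alignment; SPB amplitude
  8× the median NPC amplitude. Nuclei sit on a 6 µm grid with jitter, like
  cells in a field of view.
* **Aberration injection.** `apply_axial_stretch` displaces points along z
  so the center distance grows by (a·x² + b·x)·R — the exact inverse of the
  correction contract — or by a constant axial factor.
* **Image rendering.** Gaussian PSF splatting (defaults σ_xy = 0.10 µm,
  σ_z = 0.25 µm on 0.08 × 0.08 × 0.20 µm voxels, typical spinning-disk
  scale), a solid nucleolar body clipped to the nuclear sphere (the classic
  crescent), and Poisson noise; `snr_to_amplitude()` converts a target peak
  SNR into counts.

What passing these tests shows: the localization, correction, clustering,
reconstruction and mapping machinery is numerically correct and meets its
stated error bounds under the generator's assumptions. What it does not
show: robustness to structured background (autofluorescence, out-of-focus
neighbours), depth-dependent PSF broadening, chromatic offsets between
channels, spot blinking or motion during acquisition — none of which the
generator emulates. Conclusions about real images rest on the method's
design, not on these simulations.

## Numerical choices and edge cases

* Seeds: every stochastic routine derives independent sub-streams from one
  caller seed (32-bit safe), so identical configuration + seed reproduces
  every artifact byte-for-byte; stage artifacts are plain CSV/JSON and any
  pipeline stage can be rerun in isolation with identical output.
* k-means solutions with any cluster under 4 members are rejected and the k
  declared infeasible after the restart budget; labels are re-ordered by
  centroid position so they are stable.
* Convex-hull degeneracies (coplanar or collinear input) are errors;
  near-cospherical degeneracy in large refined hulls triggers a
  deterministic joggle retry (1e-8 → 1e-6 of the scale).
* Mesh closure (every edge shared by exactly two triangles) is asserted at
  construction and before any metric is computed.
* The empirical cumulative frequency is right-continuous and reported in
  percent; ties in volume terciles break by stable input order.
* Problem sizes in the validation suite — e.g. 20,000 samples for the
  polynomial refit, 200 rendered spots for localization accuracy, 50-nucleus
  populations for end-to-end determinism, 20 × 2,000-point nuclei for the
  correction round trip — were chosen as the smallest sizes at which the
  Monte-Carlo noise of each check is well below its tolerance.
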