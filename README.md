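# nucmorph

Nuclear-envelope morphometry for budding yeast from localized nuclear pore
complexes (NPCs).

GFP-tagged nucleoporins turn each NPC cluster into a diffraction-limited,
point-like marker embedded in the nuclear envelope. Localizing a couple of
dozen such spots per nucleus in a 3D confocal stack gives enough anchor
points to reconstruct the envelope of every nucleus in a field of cells — in
3D, without assuming the nucleus is a sphere. `nucmorph` implements the full
chain for microscopists and quantitative cell biologists:

1. **Spot localization** — local-maximum candidates refined by least-squares
   fits of an anisotropic 3D Gaussian + background over a 7x7x5 voxel window,
   giving sub-voxel positions (median 3D error well under 30 nm at peak
   SNR ~ 10). The single much-brighter spot in the same channel, when
   present, is identified as the spindle pole body (SPB); the nucleolar
   channel is segmented by Otsu thresholding.
2. **Axial aberration correction** — refractive-index mismatch elongates
   distances along z. Pooling round nuclei, the normalized center-to-spot
   distance d/R is fitted as a second-degree polynomial of the normalized
   axial coordinate x = |z − z_c|/R,

   d/R = a·x² + b·x + c,

   and every detection is corrected by d_corr/R = d/R − (a·x² + b·x).
3. **Cluster-wise envelope reconstruction** — detections are partitioned into
   1–3 k-means clusters (squared-Euclidean, seeded restarts), so mitotic
   dumbbells and late-anaphase hourglass nuclei are fitted per lobe/tube. Per
   cluster, the surface is reconstructed either by interpolating subdivision
   of the detection patch (`spline` model, a strict inner bound) or by
   three passes of anchor-point generation — one new point per surface
   triangle, at the mean vertex distance from the cluster center, along the
   center-to-triangle-centroid direction (`anchor` model, the accurate one).
   Overlapping cluster meshes are merged with voxel-based intersection
   subtraction.
4. **Geometry and population statistics** — surface S, volume V, sphericity
   Ψ = π^{1/3}(6V)^{2/3}/S per nucleus; SPB central-axis angle α; cumulative
   frequency curves; and landmark-aligned kernel-density maps: every nucleus
   is translated to the origin, rotated so the nucleolar centroid (or SPB)
   sits on the negative axis, and collapsed cylindrically onto the (s, r)
   half-plane, pooling thousands of detections from a population into one
   probability map with median-nucleus overlays and axial density profiles.
5. **Synthetic data** — ground-truthed generators (spheres, ellipsoids,
   dumbbells, hourglasses; aberration injection; Poisson-noise image
   rendering), so the whole pipeline is testable without microscopy data.

## A worked example

```r
library(nucmorph)

# 60 ground-truthed interphase nuclei, ~22 NPC spots each
pop <- simulate_population(60, seed = 11)

# reconstruct every envelope (interphase: one cluster) and quantify
geom <- fit_envelopes(pop, model = "anchor", seed = 3, force_k = 1)
median(geom$volume)                       # 2.604 um^3
median(geom$true_volume)                  # 2.768 um^3 (generator truth)
median(geom$volume / geom$true_volume - 1)  # -0.039
median(geom$sphericity)                   # 0.997

# inject the axial aberration at the reference coefficients, then recover it
ab <- pop
for (i in seq_len(nrow(ab))) {
  ctr <- c(ab$true_center_x[i], ab$true_center_y[i], ab$true_center_z[i])
  ab$detections[[i]] <- apply_axial_stretch(ab$detections[[i]], ctr,
                                            "polynomial", coef = c(0.26, 0.0029))
}
model <- fit_aberration(compute_samples(select_round_nuclei(ab, seed = 2)))
model
#> <aberration_model> d/R = 0.2769 x^2 + -0.06233 x + 0.914  (rmse 0.1054, n 1260)
corrected <- correct_detections(ab, model)
mean(abs(compute_samples(ab)$d_over_R - 1))         # 0.111 before
mean(abs(compute_samples(corrected)$d_over_R - 1))  # 0.093 after

# population density map aligned on the nucleolar centroid
aligned <- align_population(geom, "nucleolus", "npc")
autoplot(kde_map(aligned))
```

Per-nucleus volumes land ~4% below truth — the anchor envelope is built from
points on the surface and its triangulation is inscribed, a documented small
negative bias at 22 spots per nucleus. The fitted quadratic coefficient
(0.277) sits close to the injected 0.26 but also absorbs a small positive
curvature caused by estimating each center from few spots; at realistic spot
counts the residual scatter (rmse ~ 0.1) is dominated by that center noise,
which is why the corrected mean deviation shrinks but does not reach zero.
On dense samplings with known centers the same round trip flattens
mean |d/R − 1| below 0.01 (see the test suite).

A command-line front end wrapping the same functions is installed at
`inst/cli/nucmorph.R` (subcommands `simulate`, `detect`, `correct`,
`cluster`, `fit`, `quantify`, `map`, `run`), writing per-stage CSV/JSON
artifacts that make every run resumable and byte-reproducible under a fixed
seed.

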