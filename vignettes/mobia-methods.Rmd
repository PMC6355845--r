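---
title: "Object-based facies mapping of a cold-water coral mound: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Object-based facies mapping: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Cold-water coral (CWC) mounds are biogenic seabed structures built by
scleractinian corals and hemipelagic sediment. Mapping which facies covers
which part of a mound — live coral framework, dead framework, coral rubble,
sponges, sediments, dropstones — at the scale of individual organisms
requires centimetre-resolution imagery (an ROV video mosaic) combined with
much coarser acoustic products (ROV-multibeam bathymetry and backscatter).
Classifying such imagery pixel-by-pixel is noisy; object-based image
analysis (OBIA, or MOBIA in its marine form) first *segments* the mosaic
into spectrally homogeneous objects and then classifies objects from
spectral, textural, shape and terrain features.

`mobia` implements that workflow end to end, driven by a seeded synthetic
scene generator, so every stage can be exercised and tested without any
survey data. The package is organised as an analysis: the numbered scripts
under `analysis/` run the stages in order, and all computation lives in the
package functions they call.

# The synthetic scene

`scene_spec()` describes a desk-scale stand-in for a mound survey. The
defaults are fixed once and define the study conditions for all tests:

* **Extent and resolution.** 12 m x 16 m scene; mosaic at 8 mm
  (1500 x 2000 px); bathymetry and backscatter at 0.25 m. A real survey of
  this kind covers roughly 40 x 60 m at 2 mm and 0.1-0.5 m respectively;
  the desk defaults preserve the two-orders-of-magnitude resolution gap
  between the optical and acoustic products while staying far below a
  gigapixel. All sizes are parameters.
* **Relief.** Depth is negative metres below sea level. The mound is an
  anisotropic Gaussian bell (height 4 m, sigma 2.2 m east-west x 3.2 m
  north-south, giving the current-aligned ovoid plan shape) on a base
  plane at -976 m with a gentle southward regional dip and smoothed
  bathymetric noise (2 cm sd).
* **Facies and zonation.** Seven mapped classes — live coral framework
  (LCN), dead coral framework (DC), sponges (SPG), hemipelagic sediment
  (HEMS), hemipelagic sediment with dropstones (HESDR), coral rubble
  (CRUB), dropstones/pebbles (PEB) — plus a sparse OTHER class (shadow
  streaks) that is excluded from training and evaluation. The mound core
  carries a DC/CRUB background; live-coral patches are placed only where
  the bathymetric aspect lies within ±45° of north (the north-flank
  restriction typical of these mounds); sponges sit near the summit and
  the upper west flank, preferentially on dead framework; off-mound
  sediment is HEMS/HESDR with dropstone/pebble patches weighted toward
  the deeper south.
* **Appearance.** Each class renders as a mean RGB colour plus a zero-mean
  class-specific texture (blotch for frameworks, speckle for rubble and
  pebbles, fine mottle for sponges) plus Gaussian pixel noise (sd 8 of
  255). The colours are not photorealistic; they are chosen so that the
  *between-class colour separation relative to within-class variance*
  matches what makes the real workflow viable — in particular live coral
  (pink-white) vs dead framework (grey) vs rubble (tan) are strongly
  separated, because at the published segmentation scale an object
  survives merging only if its colour contrast times its pixel count
  exceeds the scale threshold. Patch sizes (coral colonies 0.5-0.8 m
  across, sponge clusters 0.3-0.55 m, dropstones 0.25-0.5 m) were set
  to realistic organism scales under the same constraint. Backscatter is
  class-mean intensity (hard substrates brighter than sediments) plus
  noise.
* **Seeding.** One integer seed drives everything; each stage derives a
  sub-seed by hashing its name (`derive_seed()`), so adding a stage never
  perturbs existing streams and every output is a pure function of
  (spec, seed).

What the generator does **not** emulate: mosaicking artefacts (seams,
illumination gradients, navigation smear), gradual facies transitions,
partial occlusion, or genuinely ambiguous textures. Passing the recovery
tests therefore shows the pipeline machinery is correct and the published
workflow's behaviour is reproduced *under its stated assumptions*; it does
not certify field accuracy on real mosaics, where class overlap is far
larger.

# Segmentation

`segment_mosaic()` grows objects from single pixels by pairwise region
merging. The merge cost of neighbours $a,b$ is the increase in weighted
heterogeneity

$$f = w\,\Delta h_{colour} + (1-w)\,\Delta h_{shape},$$

with $\Delta h_{colour}=\sum_b w_b\left(n_{ab}\sigma_{ab,b} -
n_a\sigma_{a,b} - n_b\sigma_{b,b}\right)$ and the shape term split between
compactness $n e/\sqrt n$ and smoothness $n e/\mathrm{bbox}$ (perimeter
$e$ counted in exposed pixel edges). A merge is permitted while
$f < \mathrm{scale}^2$, so "scale" is in the units object-based analysts
know from commercial tools. The published workflow fixes scale = 400 for a
2 mm mosaic; its shape/compactness weights are not stated, so the tool's
conventional defaults (colour 0.9, compactness 0.5) are used and exposed.

Scheduling is the one place the commercial implementation is unspecified:
we use deterministic raster-order sweeps with *local mutual best fitting*
(a merges b only if each is the other's minimum-cost neighbour; ties by
lower cost, then lower id), repeated to a fixed point. This makes the
result a pure function of the input. On images up to 8 x 8 the C++
implementation is tested for exact equality against an exhaustive oracle
that recomputes every statistic from raw pixels.

Because the absorption cost of an object scales with its pixel count, the
"adequate" scale shrinks with pixel size: the acceptance scene (8 mm
pixels) uses the published scale 400, while the reduced unit-test scene
(2 cm pixels) uses 150. `esp_scale()` implements the local-variance scale
diagnostic (mean within-object standard deviation and its rate of change
across scales); all local ROC-LV maxima are reported as candidates and the
choice is left to the analyst, as in the original tool.

Bathymetry is deliberately **not** a segmentation input; terrain enters
only as object features, matching the published feature scheme.

# Features

`build_feature_table()` emits 22 columns per object:

* *Spectral*: per-band means; brightness is the **sum** of the three band
  means — the convention stated alongside the original feature table, even
  though some OBIA software defines brightness as their mean.
* *Texture*: grey-level co-occurrence features computed on backscatter
  (luminance fallback when absent, reported), after scene-wide min-max
  quantization to 32 levels so features are comparable across objects;
  distance-1 symmetric GLCM averaged over the four offsets; homogeneity,
  natural-log entropy, and GLCM mean. An object's footprint on the coarse
  intensity grid is the set of cells whose centres fall inside it, with a
  nearest-cell fallback for slivers (flagged, with the degenerate
  convention homogeneity 1 / entropy 0).
* *Shape*: area and border length (metric); shape index, border index
  (against the minimum-area oriented bounding rectangle), compactness,
  roundness, density, asymmetry, main direction (degrees clockwise from
  north, folded to [0, 180)), and moment-matched elliptic/rectangular
  fits. The original feature names come without formulas; the standard
  moment/perimeter definitions documented in `?shape_features` are fixed
  here — comparability, not bit-parity with any proprietary tool, is the
  goal. For the fits, the matched shapes use square-corrected moments
  (centre moments + 1/12 per axis) and 4 x 4 sub-pixel sampling of the
  overlap, which keeps them stable under resolution changes.
* *Terrain*: mean depth, Horn slope, aspect (circular mean of the
  direction of steepest descent, clockwise from north; flat cells excluded
  and all-flat objects flagged) and curvature. Whether the original
  "curvature" is profile, plan or total curvature is unstated; the
  Laplacian (total) is used.

# Classification

150 training samples per mapped class are drawn (seeded; with replacement
plus a warning when the scene yields fewer objects — routine at desk
scale), then split 15% train / 85% test, stratified by class. The unusual
15/85 convention follows the published accuracy assessment and is a flag.
Whether the published 150-per-class pool is what the 15/85 split divides is
ambiguous in the source; splitting the sampled pool is the default here.

Three seeded models are compared on z-scored features (statistics stored
with each model): multinomial logistic regression with an L2 penalty
(`nnet::multinom`), a 100-tree random forest with sqrt(p) candidate
features (`ranger`), and a two-hidden-layer (64 + 64 ReLU) softmax network
trained with Adam for 200 epochs at batch 32 — implemented in the package,
as no installed R package provides a multi-hidden-layer classifier. None
of the hyperparameters are stated in the source; these defaults were
chosen for desk-scale stability and live in the config.

`evaluate_classification()` reports overall accuracy, *average accuracy*
(the mean one-vs-rest binary accuracy — the convention of the ML platform
used in the original workflow), and micro/macro precision and recall.
Undefined per-class precision (a class never predicted) is counted as 0
and flagged rather than dropped, so macro averages stay comparable. For
single-label multiclass data micro-precision = micro-recall = overall
accuracy; the tests assert this identity on random labelings.

# Spatial statistics

* **Zonation** (`zonation_stats()`): per-class total area, % of total,
  object count, mean object area, area inside the mound boundary and % of
  mound area. Everything is computed in full precision and rounded to two
  decimals only in the `printed_*` presentation columns. Mound membership
  is area-based (pixel-centre intersection with the boundary polygon), not
  a centroid rule, because the published %-of-mound column is area-based.
  The invariant `mound_area <= total_area` is asserted; the published
  table itself violates it in one cell (sponges), which the tests document
  as an anomaly rather than reproduce.
* **Hotspots** (`hotspot_field()`): a 1 m fishnet scored with the summed
  target-class object area per cell, then the Getis-Ord Gi* statistic with
  binary fixed-band weights (3 m band, self included) — the convention of
  the GIS tool cited by the workflow; no multiple-testing correction,
  matching the raw 90/95/99% confidence presentation. The fishnet support
  is not stated in the source; 1 m / 3 m are scene-scaled defaults and
  both are flags. Gi* is validated against a double-loop oracle; note
  Gi* is not globally standardised, so no mean-zero property is asserted.
* **Hotspot-depth correlation** (`zscore_depth_scatter()`): Pearson r
  between cell Z-scores and mean cell depth. With depth negative down,
  "shallower implies hotter" appears as r > 0; on the default scene the
  sponge correlation is strongly positive while the live-coral one is
  weak, reproducing the published contrast between the two taxa.
* **Aspect polar histograms** (`aspect_polar()`): counts and area-weighted
  counts of target-class objects per 10° aspect bin at the object
  centroid; flat centroids are excluded and reported.

# Numerical choices and degenerate inputs

Ties in merging break by lower cost then lower segment id; single-pixel
objects take shape-index 1, asymmetry 0, fits 1; constant-intensity
footprints take homogeneity 1 and entropy 0; a constant hotspot field is
an error (Gi* undefined at zero variance); a flat bathymetry has no mound
boundary (explicit error) and flagged aspect everywhere. Horn derivatives
replicate the border row/column; tests that assert analytic values do so
on grid interiors. Raster I/O stores integer rasters losslessly at 8 bits
and float rasters min-max scaled at 32 bits (float32-precision
round-trip), with georeferencing in a JSON sidecar; vectors are GeoJSON.

# Problem sizes

The test suite runs the full default scene (1500 x 2000 px) through
segmentation, features, three classifiers and the spatial statistics for
five seeds in the acceptance tests (~5 minutes on one CPU), and uses a
6 x 8 m / 2 cm reduced scene with the same structure for module tests.
Oracle-equality tests run on instances up to 16 x 16 where the naive
reference implementations are exact.

# Known limitations

* The merge scheduler reproduces the *published semantics*, not the
  proprietary implementation bit-for-bit; object counts on real mosaics
  will differ from eCognition's.
* Shape-feature formulas are fixed from standard definitions, not reverse
  engineered from any tool.
* The desk-scale scene yields tens of objects, not the ~14,000 of a real
  mound mosaic, so per-class counts rely on sampling with replacement and
  held-out metrics are optimistic relative to a field campaign.
* Classification is flat (single-stage); the two-level class hierarchy is
  carried as metadata only. Re-segmentation of selected classes and
  multi-level object hierarchies are out of scope.
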