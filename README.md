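# mobia

Object-based image analysis for cold-water coral mound facies mapping in R.

Cold-water coral (CWC) mounds are biogenic seabed structures whose surface
is a mosaic of facies: live and dead coral framework, coral rubble,
sponges, hemipelagic sediments and dropstones. Mapping these facies at
organism scale combines a centimetre-resolution ROV video mosaic with much
coarser ROV-multibeam bathymetry and backscatter. `mobia` implements the
marine object-based image analysis (MOBIA) workflow for this problem as a
tested R package, for benthic ecologists and habitat mappers who want a
fully scripted, reproducible alternative to GUI toolchains:

1. **Segmentation** — multiresolution region merging (Rcpp core). Merge
   cost for neighbouring objects *a, b*:
   `f = w·Δh_colour + (1−w)·Δh_shape`, with
   `Δh_colour = Σ_b w_b (n_ab σ_ab − n_a σ_a − n_b σ_b)` and the shape
   term split between compactness `n·e/√n` and smoothness `n·e/bbox`;
   a merge is permitted while `f < scale²` (scale 400 by default).
   Deterministic mutual-best-fitting sweeps; ESP-style local-variance
   scale diagnostic (`esp_scale()`).
2. **Features** — per-object spectral means and brightness, grey-level
   co-occurrence texture (homogeneity, entropy, mean; 32 levels) from
   backscatter, moment/perimeter shape descriptors, and Horn
   slope/aspect/curvature terrain statistics.
3. **Classification** — 150 seeded training samples per class, stratified
   15/85 train/test split, and three models: L2 multinomial logistic
   regression, random forest, and a two-hidden-layer softmax network;
   confusion matrices with overall/average accuracy and micro/macro
   precision and recall.
4. **Spatial statistics** — zonation area tables (per-class % of total
   area, object counts, mean object area, % of mound-enclosed area),
   Getis-Ord Gi* hotspot fields (`Gi* = (Σ w x − x̄ Σ w)/(S √((nΣw² −
   (Σw)²)/(n−1)))`, binary 3 m band, 90/95/99% bins), hotspot-Z vs depth
   correlation, and aspect polar histograms.
5. **Synthetic scene generator** — a seeded 12 × 16 m coral-mound scene
   (Gaussian ovoid mound, 8 mm RGB mosaic, 0.25 m bathymetry and
   backscatter, seven facies classes with realistic zonation: live coral
   restricted to the north flank, sponges at the summit/west flank,
   dropstones to the deeper south) so the whole pipeline runs and is
   tested without survey data.

## Worked example

The numbered scripts under `analysis/` run the whole study; each is a thin
driver over package functions and writes its tables under
`results/analysis/`:

```sh
Rscript analysis/01_simulate.R      # scene + mound boundary
Rscript analysis/02_segment.R       # ESP curve + scale-400 segmentation
Rscript analysis/03_features.R      # 22-column object feature table
Rscript analysis/04_classify.R      # LR / RF / DNN + accuracy metrics
Rscript analysis/05_spatial_stats.R # zonation, hotspots, polar plots
```

Abridged output at seed 1:

```
Ground-truth cover fractions (%):
  LCN    DC   SPG  HEMS HESDR  CRUB   PEB OTHER
 2.61 16.22  1.92 23.82 20.02 32.41  2.85  0.15
Segmented 2000 x 1500 px into 83 objects at scale 400
== DNN held-out metrics
overall_accuracy average_accuracy  micro_precision  macro_precision
               1                1                1                1
LCN: 29 cells at 99% confidence; Z-depth Pearson r = 0.086
SPG: 15 cells at 99% confidence; Z-depth Pearson r = 0.653
LCN aspect histogram: 100% of objects face the north half
```

Reading: the generator covers ~2.6% of the scene with live coral and ~32%
with rubble; segmentation at the published scale delimits 83 objects; all
three classifiers recover the facies of held-out objects nearly perfectly
under the scene's contrast assumptions (0.9866 / 0.9866 / 1.0 for
LR / RF / DNN); live-coral hotspots are confined to the north flank, and
sponge hotspot intensity — but not coral — tracks depth, the qualitative
pattern reported for real mounds.

Equivalent single-call form:

```r
library(mobia)
res <- run_pipeline(pipeline_config(seed = 1), outdir = "results/run1")
res$metrics$DNN$metrics$overall_accuracy
res$zonation$DNN
```

## Repository layout

```
R/                  package code: scene generator, segmentation (src/ C++),
                    features, classifiers, spatial statistics, I/O, pipeline
analysis/           numbered study drivers (see worked example)
scripts/            acceptance.R
tests/testthat/     unit, property and acceptance suites with independent
                    naive oracles (exhaustive merging, double-loop GLCM/Gi*)
vignettes/          methods vignette: model, assumptions, design decisions
```
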