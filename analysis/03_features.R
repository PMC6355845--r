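#!/usr/bin/env Rscript
# Stage 3 — per-object features.
#
# Builds the object feature table: spectral means + brightness from the
# mosaic, Haralick texture (GLCM homogeneity / entropy / mean at 32 grey
# levels) from backscatter, shape descriptors from the segment geometry,
# and terrain (depth, Horn slope/aspect, curvature) from the bathymetry.
# The ground-truth majority class of every object is attached for training.

suppressPackageStartupMessages(library(mobia))

outdir <- "results/analysis"
segmap <- readRDS(file.path(outdir, "segmap.rds"))
mosaic <- read_raster(file.path(outdir, "mosaic.tif"))
bathy <- read_raster(file.path(outdir, "bathy.tif"))
bs <- read_raster(file.path(outdir, "backscatter.tif"))
cmap <- read_raster(file.path(outdir, "class_map.tif"))

feats <- build_feature_table(segmap, mosaic, bathy, bs)
feats$true_class <- majority_labels(segmap, cmap)
data.table::fwrite(feats, file.path(outdir, "features.csv"))

cat("Feature table:", nrow(feats), "objects x",
    length(feature_columns()), "features\n")
cat("Objects per ground-truth class:\n")
print(table(feats$true_class))
cat("Brightness by class (means):\n")
print(round(tapply(feats$brightness, feats$true_class, mean), 1))
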