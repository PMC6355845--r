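#!/usr/bin/env Rscript
# Stage 4 — supervised classification and accuracy assessment.
#
# Samples 150 training objects per mapped class (with replacement, with a
# warning, for classes the desk-scale scene cannot supply 150 of), splits
# the pool 15% train / 85% test stratified by class, trains multinomial
# logistic regression (LR), random forest (RF) and the two-hidden-layer
# network (DNN), and reports the confusion matrix and micro/macro metrics
# of each on the held-out objects. Full-scene predictions are saved for
# the spatial statistics stage.

suppressPackageStartupMessages(library(mobia))

seed <- as.integer(Sys.getenv("MOBIA_SEED", "1"))
outdir <- "results/analysis"
feats <- data.table::fread(file.path(outdir, "features.csv"))
truth <- feats$true_class
feats$true_class <- NULL
feats$glcm_degenerate <- as.logical(feats$glcm_degenerate)
feats$aspect_flat <- as.logical(feats$aspect_flat)

scheme <- class_scheme()
pool <- suppressWarnings(make_training_set(
  feats, truth, per_class = 150, seed = derive_seed(seed, "sampling")))
sp <- split_train_test(pool, 0.15, seed = derive_seed(seed, "split"))
cat("Training pool:", length(pool$labels), "objects; train",
    length(sp$train$labels), "/ test", length(sp$test$labels), "\n\n")

all_pred <- data.table::data.table(segment_id = feats$segment_id)
for (mk in c("LR", "RF", "DNN")) {
  mdl <- train_classifier(mk, sp$train, seed = derive_seed(seed, mk))
  ev <- evaluate_classification(predict_classes(mdl, sp$test$features)$class,
                                sp$test$labels)
  cat("==", mk, "held-out metrics\n")
  print(round(unlist(ev$metrics), 4))
  write.csv(ev$confusion, file.path(outdir, paste0("confusion_", mk, ".csv")))
  jsonlite::write_json(ev$metrics,
                       file.path(outdir, paste0("metrics_", mk, ".json")),
                       auto_unbox = TRUE, digits = NA)
  all_pred[[paste0("class_", mk)]] <- predict_classes(mdl, feats)$class
}
data.table::fwrite(all_pred, file.path(outdir, "predictions.csv"))
cat("\nPer-object predictions written for", nrow(all_pred), "objects\n")
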