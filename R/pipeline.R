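#' Run the full facies-mapping pipeline
#'
#' Executes simulate -> segment -> features -> sample/split -> train ->
#' classify -> evaluate -> spatial statistics, writing every stage product
#' plus a manifest (config, seed, file checksums) into `outdir`. Rerunning
#' with the same config and seed reproduces all numeric outputs; with
#' `resume = TRUE`, stages whose outputs already exist under a matching
#' config hash are skipped and their products reloaded where needed.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if needed).
#' @param resume reuse existing stage outputs when the manifest's config
#'   hash matches.
#' @return list with the in-memory products: scene, segmap, features,
#'   labels, models, predictions, metrics, zonation, hotspots, scatter,
#'   polar, manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = tempfile("mobia_run_"),
                         resume = FALSE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cfg_hash <- config_hash(config)
  manifest_path <- file.path(outdir, "manifest.json")
  old_manifest <- if (resume && file.exists(manifest_path))
    jsonlite::read_json(manifest_path, simplifyVector = TRUE) else NULL
  can_resume <- function(files) {
    !is.null(old_manifest) && identical(old_manifest$config_hash, cfg_hash) &&
      all(file.exists(file.path(outdir, files)))
  }
  stage_log <- list()
  note <- function(stage, ...) {
    msg <- sprintf(...)
    stage_log[[stage]] <<- msg
    message("[", stage, "] ", msg)
  }

  # --- simulate -------------------------------------------------------
  spec <- do.call(scene_spec, c(config$scene, list(seed = config$seed)))
  scene_files <- c("bathy.tif", "class_map.tif", "mosaic.tif", "backscatter.tif",
                   "mound_boundary.geojson")
  scene <- tryCatch(
    simulate_scene(spec, config$boundary_slope_deg),
    error = function(e) stop("stage simulate failed: ", conditionMessage(e)))
  if (!can_resume(scene_files)) {
    write_raster(scene$bathy, file.path(outdir, "bathy.tif"))
    write_raster(scene$class_map, file.path(outdir, "class_map.tif"))
    write_raster(scene$mosaic, file.path(outdir, "mosaic.tif"))
    write_raster(scene$backscatter, file.path(outdir, "backscatter.tif"))
    if (!is.null(scene$boundary))
      write_vector(list(list(segment_id = 1L, rings = list(scene$boundary))),
                   file.path(outdir, "mound_boundary.geojson"))
  }
  note("simulate", "scene %gx%g m, seed %d", spec$width_m, spec$height_m,
       config$seed)

  # --- segment --------------------------------------------------------
  params <- do.call(segmentation_params, config$segmentation)
  segmap <- tryCatch(segment_mosaic(scene$mosaic, params),
                     error = function(e) stop("stage segment failed: ",
                                              conditionMessage(e)))
  if (!can_resume("segments.tif"))
    write_raster(segmap$labels, file.path(outdir, "segments.tif"))
  note("segment", "%d segments at scale %g", n_segments(segmap), params$scale)

  # --- features -------------------------------------------------------
  feats <- tryCatch(
    build_feature_table(segmap, scene$mosaic, scene$bathy, scene$backscatter,
                        config$glcm_levels),
    error = function(e) stop("stage features failed: ", conditionMessage(e)))
  truth <- majority_labels(segmap, scene$class_map)
  if (!can_resume("features.csv")) {
    out_feats <- data.table::copy(feats)
    out_feats$true_class <- truth
    data.table::fwrite(out_feats, file.path(outdir, "features.csv"))
  }
  note("features", "%d objects x %d columns", nrow(feats), ncol(feats) - 1L)

  # --- sample / split / train / evaluate ------------------------------
  scheme <- class_scheme()
  pool <- make_training_set(feats, truth, per_class = config$per_class,
                            seed = derive_seed(config$seed, "sampling"),
                            scheme = scheme)
  sp <- split_train_test(pool, config$train_fraction,
                         seed = derive_seed(config$seed, "split"))
  models <- list(); metrics <- list(); predictions <- list()
  for (mk in config$models) {
    mdl <- train_classifier(mk, sp$train,
                            seed = derive_seed(config$seed, paste0("train_", mk)),
                            scheme = scheme)
    models[[mk]] <- mdl
    test_pred <- predict_classes(mdl, sp$test$features)
    ev <- evaluate_classification(test_pred$class, sp$test$labels, scheme)
    metrics[[mk]] <- ev
    predictions[[mk]] <- predict_classes(mdl, feats)
    jsonlite::write_json(
      list(model = mk, metrics = ev$metrics,
           confusion = as.data.frame(as.table(ev$confusion))),
      file.path(outdir, paste0("metrics_", mk, ".json")),
      auto_unbox = TRUE, digits = NA)
    utils::write.csv(ev$confusion,
                     file.path(outdir, paste0("confusion_", mk, ".csv")))
    note(paste0("train_", mk), "overall accuracy %.4f on held-out test",
         ev$metrics$overall_accuracy)
  }

  # --- spatial statistics --------------------------------------------
  zonation <- list(); hotspots <- list(); scatter <- list()
  polar <- NULL
  for (mk in config$models) {
    objs <- classified_objects(segmap, predictions[[mk]]$class, scene$boundary)
    zonation[[mk]] <- zonation_stats(objs, scheme)
    data.table::fwrite(zonation[[mk]], file.path(outdir,
                                                 paste0("zonation_", mk, ".csv")))
  }
  primary <- config$models[length(config$models)]
  pred_raster <- prediction_raster(segmap, predictions[[primary]]$class, scheme)
  for (tc in config$hotspot$classes) {
    hf <- tryCatch(
      hotspot_field(pred_raster, tc, config$hotspot$cell_size,
                    config$hotspot$band_distance),
      error = function(e) { note(paste0("hotspot_", tc), "skipped: %s",
                                 conditionMessage(e)); NULL })
    if (is.null(hf)) next
    hotspots[[tc]] <- hf
    data.table::fwrite(hf, file.path(outdir, paste0("hotspot_", tc, ".csv")))
    write_hotspot_geojson(hf, config$hotspot$cell_size,
                          file.path(outdir, paste0("hotspot_", tc, ".geojson")))
    scatter[[tc]] <- zscore_depth_scatter(hf, scene$bathy,
                                          config$hotspot$cell_size)
  }
  polar <- aspect_polar(segmap, predictions[[primary]]$class, scene$bathy,
                        target = config$hotspot$classes)

  # --- manifest -------------------------------------------------------
  files <- list.files(outdir, recursive = TRUE)
  files <- setdiff(files, "manifest.json")
  manifest <- list(
    config_hash = cfg_hash, seed = config$seed,
    config = unclass(config),
    stage_log = stage_log,
    checksums = as.list(tools::md5sum(file.path(outdir, files))))
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)

  list(scene = scene, segmap = segmap, features = feats, labels = truth,
       models = models, predictions = predictions, metrics = metrics,
       zonation = zonation, hotspots = hotspots, scatter = scatter,
       polar = polar, manifest = manifest, outdir = outdir)
}

#' Per-pixel predicted class raster from per-segment predictions
#'
#' @param segmap a `segment_map`.
#' @param classes predicted codes aligned with `segmap$stats$segment_id`.
#' @param scheme a [class_scheme()].
#' @return single-band `raster_grid` of class ids.
#' @export
prediction_raster <- function(segmap, classes, scheme = class_scheme()) {
  ids <- match(classes, scheme$codes_all)
  lab <- rg_band(segmap$labels, 1L)
  lut <- integer(max(segmap$stats$segment_id))
  lut[segmap$stats$segment_id] <- ids
  raster_grid(matrix(lut[lab], nrow(lab), ncol(lab)),
              segmap$labels$origin_x, segmap$labels$origin_y,
              segmap$labels$cell_size, band_names = "predicted_class")
}

# fishnet cells as polygons with z / conf attributes
write_hotspot_geojson <- function(field, cell_size, path) {
  polys <- lapply(seq_len(nrow(field)), function(i) {
    x0 <- field$x[i] - cell_size / 2; x1 <- field$x[i] + cell_size / 2
    y0 <- field$y[i] - cell_size / 2; y1 <- field$y[i] + cell_size / 2
    list(segment_id = i,
         rings = list(list(x = c(x0, x1, x1, x0, x0),
                           y = c(y0, y0, y1, y1, y0))))
  })
  write_vector(polys, path,
               properties = data.frame(value = field$value, z = field$z,
                                       conf = field$conf))
}

# stable hash of a config (used by the manifest / resume logic)
config_hash <- function(config) {
  j <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  f <- tempfile(); writeLines(j, f)
  h <- unname(tools::md5sum(f))
  unlink(f)
  h
}
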