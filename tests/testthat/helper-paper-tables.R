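# Published per-class zonation blocks (areas m^2, object counts, printed
# percentage and mean-object-area cells) for the three classifiers, used as
# worked examples of the zonation arithmetic. `moa_consistent` marks the
# printed mean-object-area cells that equal round(total_area/n_objects, 2);
# the remaining printed cells contradict their own row inputs and are not
# asserted.
zonation_blocks <- function() {
  cls <- c("CRUB", "DC", "HEMS", "HESDR", "SPG", "LCN", "OTHER")
  list(
    DNN = data.frame(
      class = cls,
      total_area = c(676.12, 199.38, 703.39, 549.40, 46.22, 81.94, 76.98),
      n_objects = c(3680, 1641, 3197, 2000, 739, 1041, 1630),
      mound_area = c(474.37, 199.37, 433.87, 324.01, 56.62, 32.38, 66.21),
      pct_printed = c(28.98, 8.54, 30.14, 23.54, 1.98, 3.51, 3.30),
      moa_printed = c(0.18, 0.12, 0.22, 0.27, 0.04, 0.07, 0.04),
      pctm_printed = c(29.89, 12.56, 27.34, 20.42, 3.57, 2.04, 4.17),
      moa_consistent = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)),
    LR = data.frame(
      class = cls,
      total_area = c(235.67, 354.44, 809.45, 767.45, 44.67, 69.36, 52.39),
      n_objects = c(1567, 2521, 3952, 2841, 824, 1105, 118),
      mound_area = c(169.24, 354.44, 506.74, 410.05, 43.34, 57.94, 45.08),
      pct_printed = c(10.10, 15.19, 34.69, 32.89, 1.91, 2.97, 2.25),
      moa_printed = c(0.15, 0.14, 0.20, 0.27, 0.05, 0.06, 0.04),
      pctm_printed = c(10.67, 22.34, 31.93, 25.84, 2.73, 3.65, 2.84),
      moa_consistent = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE)),
    RF = data.frame(
      class = cls,
      total_area = c(449.11, 300.98, 693.42, 696.60, 44.41, 94.01, 54.90),
      n_objects = c(2273, 2224, 3187, 2734, 1308, 852, 1350),
      mound_area = c(297.74, 299.24, 460.60, 369.75, 36.96, 69.52, 53.02),
      pct_printed = c(19.25, 12.90, 29.72, 29.85, 1.90, 4.03, 2.35),
      moa_printed = c(0.19, 0.13, 0.21, 0.25, 0.07, 0.05, 0.03),
      pctm_printed = c(18.76, 18.86, 29.03, 23.30, 2.33, 4.38, 3.34),
      moa_consistent = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE)))
}

# Full default-scene pipeline for one seed, reduced to the summary numbers
# the acceptance checks need (heavy rasters dropped; results cached).
full_run_summary <- function(seed) {
  key <- paste0("fullrun_", seed)
  if (is.null(fixture_env[[key]])) {
    res <- suppressWarnings(suppressMessages(run_pipeline(
      pipeline_config(seed = seed),
      outdir = file.path(tempdir(), paste0("acc_run_", seed)))))
    summit <- {
      z <- rg_band(res$scene$bathy, 1)
      rc <- which(z == max(z), arr.ind = TRUE)[1, ]
      pixel_to_world(res$scene$bathy, rc[1], rc[2])
    }
    fixture_env[[key]] <- list(
      seed = seed,
      overall = vapply(res$metrics, function(m) m$metrics$overall_accuracy, 0),
      metrics = lapply(res$metrics, `[[`, "metrics"),
      hot_lcn = res$hotspots$LCN,
      hot_spg = res$hotspots$SPG,
      spg_r = if (!is.null(res$scatter$SPG)) res$scatter$SPG$r else NA_real_,
      zonation = res$zonation,
      polar = res$polar,
      summit = summit,
      height_m = res$scene$spec$height_m,
      manifest = res$manifest)
  }
  fixture_env[[key]]
}
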