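#' Segmentation parameters
#'
#' Parameters of the multiresolution region-merging segmentation. `scale`
#' bounds the heterogeneity increase a merge may cause (a merge is permitted
#' while the weighted spectral + shape cost stays below `scale^2`, so scale
#' is in the units familiar from object-based image analysis tools);
#' `color_weight` splits the cost between spectral and shape heterogeneity,
#' and `compactness_weight` splits the shape term between compactness and
#' smoothness. Band weights default to equal.
#'
#' @param scale positive scale parameter (default 400).
#' @param color_weight weight on spectral heterogeneity in `[0, 1]`
#'   (default 0.9, i.e. shape weight 0.1).
#' @param compactness_weight weight on the compactness part of the shape
#'   term in `[0, 1]` (default 0.5).
#' @param band_weights optional nonnegative per-band weights; normalized to
#'   sum to 1.
#' @return object of class `segmentation_params`.
#' @export
segmentation_params <- function(scale = 400, color_weight = 0.9,
                                compactness_weight = 0.5, band_weights = NULL) {
  if (!is.numeric(scale) || scale <= 0) stop("scale must be positive")
  if (color_weight < 0 || color_weight > 1) stop("color_weight must be in [0,1]")
  if (compactness_weight < 0 || compactness_weight > 1)
    stop("compactness_weight must be in [0,1]")
  if (!is.null(band_weights)) {
    if (any(band_weights < 0) || sum(band_weights) <= 0)
      stop("band_weights must be nonnegative with positive sum")
    band_weights <- band_weights / sum(band_weights)
  }
  structure(list(scale = scale, color_weight = color_weight,
                 compactness_weight = compactness_weight,
                 band_weights = band_weights),
            class = "segmentation_params")
}

#' Segment a mosaic into image objects
#'
#' Iterative pairwise region merging from single pixels. The merge cost of
#' neighbouring regions a, b is
#' `f = color_weight * dh_color + (1 - color_weight) * dh_shape` where
#' `dh_color` is the band-weighted increase in `n * sd`,
#' `dh_shape = compactness_weight * dh_cmpct + (1 - compactness_weight) *
#' dh_smooth` with `h_cmpct = n e / sqrt(n)` and `h_smooth = n e / bboxperim`
#' (perimeter and bounding-box perimeter in pixel-edge units). A merge is
#' permitted iff `f < scale^2`. Merging proceeds by deterministic
#' raster-order sweeps with local mutual best fitting until no permitted
#' merge remains, so the result is a pure function of the input and
#' parameters.
#'
#' @param mosaic `raster_grid` with one or more bands of finite values.
#' @param params a [segmentation_params()].
#' @return object of class `segment_map`: list with `labels` (raster of
#'   segment ids 1..K, each segment 4-connected), `stats` (data.table:
#'   segment_id, n, perimeter_px, bbox, per-band sum/sum-of-squares) and
#'   `adjacency` (data.table a, b, shared edge counts).
#' @export
segment_mosaic <- function(mosaic, params = segmentation_params()) {
  v <- mosaic$values
  if (length(v) == 0) stop("empty raster")
  if (!all(is.finite(v))) stop("mosaic values must be finite")
  nb <- rg_nbands(mosaic)
  bw <- params$band_weights
  if (is.null(bw)) bw <- rep(1 / nb, nb)
  if (length(bw) != nb) stop("band_weights length must match band count")
  res <- cpp_segment(as.numeric(v), rg_nrow(mosaic), rg_ncol(mosaic), nb,
                     params$scale, params$color_weight,
                     params$compactness_weight, as.numeric(bw))
  labels <- raster_grid(res$labels, mosaic$origin_x, mosaic$origin_y,
                        mosaic$cell_size, band_names = "segment_id")
  stats <- data.table::data.table(
    segment_id = res$segment_id, n = res$n, perimeter_px = res$perimeter,
    rmin = res$rmin, rmax = res$rmax, cmin = res$cmin, cmax = res$cmax)
  bs <- res$band_sum; bq <- res$band_sumsq
  for (k in seq_len(nb)) {
    stats[[paste0("sum_", mosaic$band_names[k])]] <- bs[, k]
    stats[[paste0("sumsq_", mosaic$band_names[k])]] <- bq[, k]
  }
  adjacency <- data.table::data.table(a = res$edge_a, b = res$edge_b,
                                      shared = res$edge_shared)
  structure(list(labels = labels, stats = stats, adjacency = adjacency,
                 params = params, band_names = mosaic$band_names),
            class = "segment_map")
}

#' @export
print.segment_map <- function(x, ...) {
  cat(sprintf("segment_map: %d segments over %d x %d px (scale %g)\n",
              nrow(x$stats), rg_nrow(x$labels), rg_ncol(x$labels),
              x$params$scale))
  invisible(x)
}

#' Number of segments
#' @param segmap a `segment_map`.
#' @export
n_segments <- function(segmap) nrow(segmap$stats)

# mean per-band standard deviation of each segment (from incremental stats)
segment_mean_sd <- function(segmap) {
  st <- segmap$stats
  bands <- segmap$band_names
  sds <- sapply(bands, function(bn) {
    s <- st[[paste0("sum_", bn)]]; q <- st[[paste0("sumsq_", bn)]]
    v <- q / st$n - (s / st$n)^2
    sqrt(pmax(v, 0))
  })
  if (is.null(dim(sds))) sds <- matrix(sds, nrow = nrow(st))
  rowMeans(sds)
}

#' Estimation-of-scale-parameter (ESP) curve
#'
#' Runs the segmentation across an increasing sequence of scales and
#' reports local variance (LV; the mean over segments of the segment's mean
#' per-band standard deviation) and its rate of change
#' `ROC_i = 100 * (LV_i - LV_{i-1}) / LV_{i-1}`. Local ROC maxima are
#' returned as candidate scales; choosing among them is left to the analyst.
#'
#' @param mosaic `raster_grid`.
#' @param scales strictly increasing positive scales (>= 2 values).
#' @param params base [segmentation_params()]; `scale` is overridden.
#' @return object of class `esp_curve`: data.frame `scale`, `lv`, `roc_lv`,
#'   `n_segments`, with attribute `candidates` (scales at local ROC maxima).
#' @export
esp_scale <- function(mosaic, scales, params = segmentation_params()) {
  if (length(scales) < 2) stop("need at least 2 scales")
  if (any(scales <= 0) || any(diff(scales) <= 0))
    stop("scales must be strictly increasing and positive")
  lv <- nseg <- numeric(length(scales))
  for (i in seq_along(scales)) {
    p <- params; p$scale <- scales[i]
    sm <- segment_mosaic(mosaic, p)
    lv[i] <- mean(segment_mean_sd(sm))
    nseg[i] <- n_segments(sm)
  }
  roc <- c(NA_real_, 100 * diff(lv) / head(lv, -1))
  roc[!is.finite(roc)] <- NA_real_
  out <- data.frame(scale = scales, lv = lv, roc_lv = roc, n_segments = nseg)
  r <- roc; nlen <- length(r)
  prev <- c(NA, r[-nlen]); nxt <- c(r[-1], NA)
  is_max <- !is.na(r) & (is.na(prev) | r >= prev) & (is.na(nxt) | r >= nxt)
  cand <- scales[which(is_max)]
  attr(out, "candidates") <- cand
  class(out) <- c("esp_curve", "data.frame")
  out
}
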