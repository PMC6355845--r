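#' Per-object areas and mound membership from a classified segment map
#'
#' Builds the per-object table that the zonation statistics summarise:
#' object area (pixel count x cell^2) and the area of the object inside
#' the mound boundary, computed by pixel-centre membership against the
#' mound polygon (area-based intersection in pixel units).
#'
#' @param segmap a `segment_map`.
#' @param classes character class codes aligned with
#'   `segmap$stats$segment_id` (e.g. predicted classes).
#' @param mound mound polygon (`list(x, y)` ring) or `NULL` (mound areas 0).
#' @return data.table: segment_id, class, area, mound_area (m^2).
#' @export
classified_objects <- function(segmap, classes, mound = NULL) {
  st <- segmap$stats
  stopifnot(length(classes) == nrow(st))
  cell <- segmap$labels$cell_size
  out <- data.table::data.table(segment_id = st$segment_id, class = classes,
                                area = st$n * cell^2, mound_area = 0)
  if (!is.null(mound)) {
    lab <- rg_band(segmap$labels, 1L)
    nr <- nrow(lab); nc <- ncol(lab)
    g <- segmap$labels
    # mound membership per pixel, evaluated row-block-wise to bound memory
    counts <- numeric(nrow(st))
    rings <- if (!is.null(mound$x)) list(mound) else mound
    xs <- g$origin_x + (seq_len(nc) - 0.5) * cell
    block <- max(1L, floor(2e6 / nc))
    for (r0 in seq(1L, nr, by = block)) {
      r1 <- min(nr, r0 + block - 1L)
      rows <- r0:r1
      ys <- g$origin_y - (rows - 0.5) * cell
      px <- rep(xs, each = length(rows))
      py <- rep(ys, times = nc)
      ins <- point_in_rings(px, py, rings)
      if (any(ins)) {
        segs <- as.vector(lab[rows, , drop = FALSE])[ins]
        tb <- tabulate(segs, nbins = max(st$segment_id))
        counts <- counts + tb[st$segment_id]
      }
    }
    out$mound_area <- counts * cell^2
  }
  out[]
}

#' Zonation statistics from per-class totals
#'
#' Computes the derived columns of the zonation area table from per-class
#' totals: percentage of total area, mean object area, and percentage of
#' the mound-enclosed area. Values are kept in full precision; rounding to
#' 2 decimals happens only in the `printed_*` presentation columns.
#'
#' @param totals data.frame with columns `class`, `total_area` (m^2),
#'   `n_objects`, `mound_area` (m^2).
#' @return data.table with pct_total, mean_object_area, pct_mound plus
#'   rounded presentation columns and a totals row (`class == "TOTAL"`).
#' @export
zonation_from_totals <- function(totals) {
  t <- data.table::as.data.table(totals)
  req <- c("class", "total_area", "n_objects", "mound_area")
  if (!all(req %in% names(t))) stop("totals needs columns: ", paste(req, collapse = ", "))
  if (any(t$mound_area > t$total_area + 1e-9))
    warning("mound-enclosed area exceeds class total area for: ",
            paste(t$class[t$mound_area > t$total_area + 1e-9], collapse = ", "))
  ta <- sum(t$total_area); ma <- sum(t$mound_area)
  t$pct_total <- 100 * t$total_area / ta
  t$mean_object_area <- t$total_area / t$n_objects
  t$pct_mound <- if (ma > 0) 100 * t$mound_area / ma else 0
  tot <- data.table::data.table(
    class = "TOTAL", total_area = ta, n_objects = sum(t$n_objects),
    mound_area = ma, pct_total = 100,
    mean_object_area = ta / sum(t$n_objects), pct_mound = if (ma > 0) 100 else 0)
  out <- rbind(t, tot)
  for (cn in c("pct_total", "mean_object_area", "pct_mound"))
    out[[paste0("printed_", cn)]] <- round(out[[cn]], 2)
  out[]
}

#' Zonation area table from classified objects
#'
#' Aggregates per-object areas by class and derives the percentage and
#' mean-object-area columns.
#'
#' @param objects data.table from [classified_objects()] (columns class,
#'   area, mound_area; one row per object).
#' @param scheme a [class_scheme()]; classes are reported in scheme order
#'   (including OTHER when present).
#' @return data.table as for [zonation_from_totals()].
#' @export
zonation_stats <- function(objects, scheme = class_scheme()) {
  o <- data.table::as.data.table(objects)
  if (any(!is.finite(o$area)) || any(o$area < 0))
    stop("invalid object area for segment_id ",
         paste(o$segment_id[!is.finite(o$area) | o$area < 0], collapse = ", "))
  tt <- o[, .(total_area = sum(area), n_objects = .N,
              mound_area = sum(mound_area)), by = class]
  ord <- match(tt$class, scheme$codes_all)
  tt <- tt[order(ord)]
  zonation_from_totals(tt)
}

#' Getis-Ord Gi* hotspot field
#'
#' Lays a fishnet of square cells over the scene, scores every cell with
#' the summed area of target-class objects it contains, and computes the
#' Gi* statistic with binary fixed-distance-band weights (self included):
#' cells whose centres lie within `band_distance` of cell i's centre are
#' its neighbours. Confidence bins from |Z|: 1.645 (90), 1.960 (95),
#' 2.576 (99).
#'
#' @param values matrix of cell values (fishnet rows x cols), or use
#'   [hotspot_field()] to build it from a classified raster.
#' @param cell_size fishnet cell edge (m).
#' @param band_distance fixed distance band (m, >= cell_size).
#' @return data.table: row, col, x, y (cell centres), value, z, conf.
#' @export
gi_star <- function(values, cell_size, band_distance) {
  if (cell_size <= 0) stop("cell_size must be positive")
  if (band_distance < cell_size) stop("band_distance must be >= cell_size")
  nr <- nrow(values); nc <- ncol(values)
  n <- nr * nc
  if (n < 2) stop("need at least 2 fishnet cells")
  x <- as.vector(values)
  xbar <- mean(x)
  s <- sqrt(mean(x^2) - xbar^2)
  if (s == 0) stop("constant field: Gi* undefined (zero variance)")
  ctr_c <- (col(values) - 0.5) * cell_size
  ctr_r <- (row(values) - 0.5) * cell_size
  cx <- as.vector(ctr_c); cy <- as.vector(ctr_r)
  z <- numeric(n)
  for (i in seq_len(n)) {
    w <- (cx - cx[i])^2 + (cy - cy[i])^2 <= band_distance^2
    sw <- sum(w)
    num <- sum(x[w]) - xbar * sw
    den <- s * sqrt((n * sw - sw^2) / (n - 1))
    z[i] <- num / den
  }
  conf <- cut(abs(z), c(-Inf, 1.645, 1.960, 2.576, Inf),
              labels = c("none", "90", "95", "99"))
  data.table::data.table(
    row = as.vector(row(values)), col = as.vector(col(values)),
    value = x, z = z, conf = as.character(conf))
}

#' Hotspot field of a target class over a classified raster
#'
#' Builds the fishnet cell values (summed target-class area per cell, in
#' m^2, exact in pixel units) from a per-pixel class raster and runs
#' [gi_star()].
#'
#' @param class_raster single-band `raster_grid` of class ids or codes
#'   (see `codes`); typically per-pixel predicted classes.
#' @param target_class class code (e.g. "LCN").
#' @param cell_size fishnet cell (m), default 1.
#' @param band_distance distance band (m), default 3.
#' @param codes character vector mapping raster values to codes (default
#'   the scheme's `codes_all`).
#' @return data.table as [gi_star()], plus `x`, `y` world cell centres.
#' @export
hotspot_field <- function(class_raster, target_class, cell_size = 1,
                          band_distance = 3, codes = class_scheme()$codes_all) {
  lab <- rg_band(class_raster, 1L)
  target_id <- match(target_class, codes)
  if (is.na(target_id)) stop("unknown target class ", target_class)
  cell <- class_raster$cell_size
  nrf <- ceiling(nrow(lab) * cell / cell_size)
  ncf <- ceiling(ncol(lab) * cell / cell_size)
  # fishnet row/col of each raster pixel (centre-based)
  pr <- floor(((row(lab) - 0.5) * cell) / cell_size) + 1L
  pc <- floor(((col(lab) - 0.5) * cell) / cell_size) + 1L
  hit <- lab == target_id
  vals <- matrix(0, nrf, ncf)
  if (any(hit)) {
    dt <- data.table::data.table(r = pr[hit], c = pc[hit])
    agg <- dt[, .N, by = .(r, c)]
    vals[cbind(agg$r, agg$c)] <- agg$N * cell^2
  }
  out <- gi_star(vals, cell_size, band_distance)
  out$x <- class_raster$origin_x + (out$col - 0.5) * cell_size
  out$y <- class_raster$origin_y - (out$row - 0.5) * cell_size
  out[]
}

#' Hotspot Z-score vs depth scatter
#'
#' Pairs every fishnet cell's Gi* Z-score with the mean depth of the
#' bathymetry cells whose centres fall inside it, and reports the Pearson
#' correlation.
#'
#' @param field data.table from [hotspot_field()] (needs x, y, z).
#' @param bathy depth `raster_grid`.
#' @param cell_size fishnet cell (m) used to build the field.
#' @return list(series = data.table(x, y, z, mean_depth), r = Pearson r).
#' @export
zscore_depth_scatter <- function(field, bathy, cell_size = 1) {
  if (nrow(field) < 3) stop("insufficient data: need >= 3 cells")
  zb <- rg_band(bathy, 1L)
  bx <- bathy$origin_x + (col(zb) - 0.5) * bathy$cell_size
  by <- bathy$origin_y - (row(zb) - 0.5) * bathy$cell_size
  dt <- data.table::data.table(
    r = floor((bathy$origin_y - as.vector(by)) / cell_size) + 1L,
    c = floor((as.vector(bx) - bathy$origin_x) / cell_size) + 1L,
    depth = as.vector(zb))
  agg <- dt[, .(mean_depth = mean(depth)), by = .(r, c)]
  ser <- merge(data.table::as.data.table(field), agg,
               by.x = c("row", "col"), by.y = c("r", "c"))
  ok <- is.finite(ser$z) & is.finite(ser$mean_depth)
  ser <- ser[ok]
  if (nrow(ser) < 3) stop("insufficient data: need >= 3 cells")
  list(series = ser, r = stats::cor(ser$mean_depth, ser$z))
}

#' Aspect polar histogram of classified objects
#'
#' Distribution of target-class objects over bathymetric aspect bins:
#' aspect is looked up at each object's centroid on the terrain aspect
#' grid; flat-flagged centroids are excluded and counted separately. Bins
#' of width `360 / n_bins` start at north.
#'
#' @param segmap a `segment_map`.
#' @param classes character class codes aligned with segments.
#' @param bathy depth `raster_grid`.
#' @param target character vector of target codes (default LCN and SPG).
#' @param n_bins number of aspect bins (default 36).
#' @return list per target class: data.table(bin_start, bin_mid, count,
#'   area_weighted) plus `n_flat`; empty histogram with a warning when a
#'   class has no objects.
#' @export
aspect_polar <- function(segmap, classes, bathy, target = c("LCN", "SPG"),
                         n_bins = 36L) {
  terr <- terrain_derivatives(bathy)
  asp <- rg_band(terr$aspect, 1L)
  cen <- segment_centroids(segmap)
  w <- pixel_to_world(segmap$labels, cen$r, cen$c)
  rc <- world_to_pixel(bathy, w$x, w$y)
  rr <- pmin(pmax(rc$r, 1L), rg_nrow(bathy))
  cc <- pmin(pmax(rc$c, 1L), rg_ncol(bathy))
  a_cen <- asp[cbind(rr, cc)]
  st <- segmap$stats
  cell2 <- segmap$labels$cell_size^2
  width <- 360 / n_bins
  out <- list()
  for (tc in target) {
    sel <- which(classes == tc)
    if (!length(sel)) {
      warning("no objects of class ", tc)
      out[[tc]] <- list(hist = data.table::data.table(
        bin_start = (seq_len(n_bins) - 1) * width,
        bin_mid = (seq_len(n_bins) - 0.5) * width,
        count = 0L, area_weighted = 0), n_flat = 0L)
      next
    }
    av <- a_cen[sel]
    flat <- !is.finite(av)
    bins <- floor((av[!flat] %% 360) / width) + 1L
    cnt <- tabulate(bins, n_bins)
    aw <- numeric(n_bins)
    ar <- st$n[sel][!flat] * cell2
    for (b in unique(bins)) aw[b] <- sum(ar[bins == b])
    out[[tc]] <- list(hist = data.table::data.table(
      bin_start = (seq_len(n_bins) - 1) * width,
      bin_mid = (seq_len(n_bins) - 0.5) * width,
      count = cnt, area_weighted = aw), n_flat = sum(flat))
  }
  out
}
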