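# Independent oracle implementations used by the tests: naive,
# recompute-everything versions of the algorithms, sharing no code with the
# package implementations.

# ---- segmentation oracle ---------------------------------------------------
# Mutual-best-fitting region merging where every quantity is recomputed from
# raw pixels at every step (no incremental statistics, no adjacency
# bookkeeping). Regions are sets of 1-based column-major pixel indices; a
# region's id is its minimum pixel index, matching the implementation's
# merge-into-lower-id rule.
oracle_segment <- function(values, scale, color_weight = 0.9,
                           compactness_weight = 0.5, band_weights = NULL) {
  if (length(dim(values)) == 2L) values <- array(values, c(dim(values), 1L))
  nr <- dim(values)[1]; nc <- dim(values)[2]; nb <- dim(values)[3]
  bw <- band_weights
  if (is.null(bw)) bw <- rep(1 / nb, nb)
  regions <- as.list(seq_len(nr * nc))

  rc_of <- function(p) cbind((p - 1L) %% nr + 1L, (p - 1L) %/% nr + 1L)
  region_stats <- function(px) {
    rc <- rc_of(px)
    n <- length(px)
    e <- 0
    pset <- px
    for (p in px) {
      r <- (p - 1L) %% nr + 1L; c <- (p - 1L) %/% nr + 1L
      for (q in list(c(r - 1L, c), c(r + 1L, c), c(r, c - 1L), c(r, c + 1L))) {
        if (q[1] < 1 || q[1] > nr || q[2] < 1 || q[2] > nc) e <- e + 1
        else if (!((q[1] + (q[2] - 1L) * nr) %in% pset)) e <- e + 1
      }
    }
    sds <- numeric(nb)
    for (b in seq_len(nb)) {
      vals <- values[, , b][px]
      sds[b] <- sqrt(max(mean(vals^2) - mean(vals)^2, 0))
    }
    list(n = n, e = e, sds = sds,
         bbox = c(range(rc[, 1]), range(rc[, 2])))
  }
  cost <- function(pa, pb) {
    sa <- region_stats(pa); sb <- region_stats(pb); sab <- region_stats(c(pa, pb))
    dcol <- 0
    for (b in seq_len(nb))
      dcol <- dcol + bw[b] * (sab$n * sab$sds[b] - sa$n * sa$sds[b] - sb$n * sb$sds[b])
    cm <- function(s) sqrt(s$n) * s$e
    sm <- function(s) s$n * s$e /
      (2 * ((s$bbox[2] - s$bbox[1] + 1) + (s$bbox[4] - s$bbox[3] + 1)))
    dshape <- compactness_weight * (cm(sab) - cm(sa) - cm(sb)) +
      (1 - compactness_weight) * (sm(sab) - sm(sa) - sm(sb))
    color_weight * dcol + (1 - color_weight) * dshape
  }
  adjacent <- function(pa, pb) {
    ra <- rc_of(pa); rb <- rc_of(pb)
    for (i in seq_len(nrow(ra)))
      for (j in seq_len(nrow(rb)))
        if (abs(ra[i, 1] - rb[j, 1]) + abs(ra[i, 2] - rb[j, 2]) == 1L) return(TRUE)
    FALSE
  }

  thresh <- scale^2
  best_of <- function(a) {
    nbrs <- which(vapply(seq_along(regions), function(k)
      k != a && adjacent(regions[[a]], regions[[k]]), TRUE))
    if (!length(nbrs)) return(NULL)
    costs <- vapply(nbrs, function(k) cost(regions[[a]], regions[[k]]), 0)
    nbr_ids <- vapply(nbrs, function(k) min(regions[[k]]), 0L)
    ord <- order(costs, nbr_ids)
    list(idx = nbrs[ord[1]], cost = costs[ord[1]])
  }
  repeat {
    merged_any <- FALSE
    # one sweep: visit region ids in ascending order (snapshot), skipping
    # ids merged away earlier in the same sweep; merges take effect
    # immediately for later visits
    ids <- sort(vapply(regions, min, 0L))
    for (id in ids) {
      a <- which(vapply(regions, function(p) min(p) == id, TRUE))
      if (length(a) != 1L) next  # id no longer a region head
      ba <- best_of(a)
      if (is.null(ba) || ba$cost >= thresh) next
      b <- ba$idx
      bb <- best_of(b)
      if (is.null(bb) || bb$idx != a) next
      keep <- min(a, b)  # irrelevant which list slot survives; id = min px
      regions[[keep]] <- c(regions[[a]], regions[[b]])
      regions[[max(a, b)]] <- NULL
      merged_any <- TRUE
    }
    if (!merged_any) break
  }
  lab <- matrix(0L, nr, nc)
  for (k in seq_along(regions)) lab[regions[[k]]] <- k
  # compact in column-major first-occurrence order, like the implementation
  remap <- integer(length(regions)); nxt <- 1L
  out <- matrix(0L, nr, nc)
  for (p in seq_len(nr * nc)) {
    k <- lab[p]
    if (remap[k] == 0L) { remap[k] <- nxt; nxt <- nxt + 1L }
    out[p] <- remap[k]
  }
  out
}

# ---- GLCM oracle -----------------------------------------------------------
# Double-loop co-occurrence over all pixel pairs of one segment's footprint.
oracle_glcm <- function(lev, segmask, G) {
  offsets <- list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
  nr <- nrow(lev); nc <- ncol(lev)
  mats <- list()
  for (o in offsets) {
    M <- matrix(0, G, G)
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      r2 <- r + o[1]; c2 <- c + o[2]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (!segmask[r, c] || !segmask[r2, c2]) next
      i <- lev[r, c] + 1L; j <- lev[r2, c2] + 1L
      M[i, j] <- M[i, j] + 1
      M[j, i] <- M[j, i] + 1
    }
    if (sum(M) > 0) mats[[length(mats) + 1L]] <- M / sum(M)
  }
  if (!length(mats)) return(NULL)
  P <- Reduce(`+`, mats) / length(mats)
  ij <- expand.grid(i = 0:(G - 1), j = 0:(G - 1))
  p <- as.vector(P)
  list(homogeneity = sum(p / (1 + (ij$i - ij$j)^2)),
       entropy = -sum(ifelse(p > 0, p * log(p), 0)),
       mean = sum(ij$i * p))
}

# ---- Gi* oracle ------------------------------------------------------------
oracle_gi_star <- function(values, cell_size, band_distance) {
  nr <- nrow(values); nc <- ncol(values)
  n <- nr * nc
  x <- as.vector(values)
  xbar <- sum(x) / n
  s <- sqrt(sum(x^2) / n - xbar^2)
  cx <- (as.vector(col(values)) - 0.5) * cell_size
  cy <- (as.vector(row(values)) - 0.5) * cell_size
  z <- numeric(n)
  for (i in seq_len(n)) {
    sw <- 0; swx <- 0; sw2 <- 0
    for (j in seq_len(n)) {
      d <- sqrt((cx[i] - cx[j])^2 + (cy[i] - cy[j])^2)
      if (d <= band_distance) { sw <- sw + 1; swx <- swx + x[j]; sw2 <- sw2 + 1 }
    }
    z[i] <- (swx - xbar * sw) / (s * sqrt((n * sw2 - sw^2) / (n - 1)))
  }
  z
}

# ---- metrics oracle --------------------------------------------------------
oracle_metrics <- function(pred, truth, codes) {
  n <- length(truth)
  acc <- sum(pred == truth) / n
  prec <- rec <- bacc <- numeric(length(codes))
  tps <- fps <- fns <- 0
  for (k in seq_along(codes)) {
    cl <- codes[k]
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    tn <- n - tp - fp - fn
    prec[k] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec[k] <- if (tp + fn > 0) tp / (tp + fn) else 0
    bacc[k] <- (tp + tn) / n
    tps <- tps + tp; fps <- fps + fp; fns <- fns + fn
  }
  list(overall_accuracy = acc, average_accuracy = mean(bacc),
       micro_precision = tps / (tps + fps), macro_precision = mean(prec),
       micro_recall = tps / (tps + fns), macro_recall = mean(rec))
}

# ---- shared fixtures (computed once per test run) --------------------------
fixture_env <- new.env()

# a reduced scene (3 x 4 m) that keeps the full structure at ~1/10 the
# pixel count of the default, for unit tests that need a realistic scene
small_scene <- function(seed = 11) {
  key <- paste0("scene_", seed)
  if (is.null(fixture_env[[key]])) {
    sp <- scene_spec(width_m = 6, height_m = 8, mosaic_cell = 0.02,
                     bathy_cell = 0.25, mound_sigma_x = 1.2,
                     mound_sigma_y = 1.7, n_lcn = 8, n_spg = 10, n_peb = 18,
                     n_other = 2, seed = seed)
    fixture_env[[key]] <- simulate_scene(sp)
  }
  fixture_env[[key]]
}

# scale 150 suits the reduced scene's 2 cm pixels: the cost of absorbing a
# patch grows with its pixel count, so the adequate-segmentation scale
# shrinks with the pixel-count of a given object (ESP logic)
small_segmap <- function(seed = 11) {
  key <- paste0("segmap_", seed)
  if (is.null(fixture_env[[key]])) {
    sc <- small_scene(seed)
    fixture_env[[key]] <- segment_mosaic(sc$mosaic,
                                         segmentation_params(scale = 150))
  }
  fixture_env[[key]]
}

# minimal stand-in scheme for metric tests with arbitrary class codes
toy_scheme <- function(codes) {
  structure(list(codes = codes, codes_all = codes), class = "class_scheme")
}

# helper: a segment map from an explicit label matrix (bypasses merging)
segmap_from_labels <- function(lab, cell = 1, origin_y = nrow(lab) * cell,
                               values = NULL) {
  nb <- if (is.null(values)) 1L else dim(values)[3]
  if (is.null(values)) values <- array(0, c(dim(lab), 1))
  ids <- sort(unique(as.vector(lab)))
  stopifnot(identical(ids, seq_along(ids)))
  st <- data.table::data.table(segment_id = ids)
  n <- e <- rmin <- rmax <- cmin <- cmax <- numeric(length(ids))
  for (k in ids) {
    idx <- which(lab == k, arr.ind = TRUE)
    n[k] <- nrow(idx)
    rmin[k] <- min(idx[, 1]); rmax[k] <- max(idx[, 1])
    cmin[k] <- min(idx[, 2]); cmax[k] <- max(idx[, 2])
    # exposed 4-neighbour edges
    e[k] <- 0
    for (i in seq_len(nrow(idx))) {
      r <- idx[i, 1]; c <- idx[i, 2]
      for (q in list(c(r - 1, c), c(r + 1, c), c(r, c - 1), c(r, c + 1))) {
        out <- q[1] < 1 || q[1] > nrow(lab) || q[2] < 1 || q[2] > ncol(lab)
        if (out || lab[q[1], q[2]] != k) e[k] <- e[k] + 1
      }
    }
  }
  st$n <- n; st$perimeter_px <- e
  st$rmin <- rmin; st$rmax <- rmax; st$cmin <- cmin; st$cmax <- cmax
  for (b in seq_len(nb)) {
    st[[paste0("sum_band_", b)]] <- vapply(ids, function(k) sum(values[, , b][lab == k]), 0)
    st[[paste0("sumsq_band_", b)]] <- vapply(ids, function(k) sum(values[, , b][lab == k]^2), 0)
  }
  structure(list(
    labels = raster_grid(lab, 0, origin_y, cell, band_names = "segment_id"),
    stats = st, adjacency = data.table::data.table(),
    params = segmentation_params(), band_names = paste0("band_", seq_len(nb))),
    class = "segment_map")
}
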