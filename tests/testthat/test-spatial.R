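test_that("zonation percentages and mean object areas follow their definitions", {
  # worked example: seven facies areas (m^2) and object counts
  totals <- data.frame(
    class = c("CRUB", "DC", "HEMS", "HESDR", "SPG", "LCN", "OTHER"),
    total_area = c(676.12, 199.38, 703.39, 549.40, 46.22, 81.94, 76.98),
    n_objects = c(3680, 1641, 3197, 2000, 739, 1041, 1630),
    mound_area = c(474.37, 199.37, 433.87, 324.01, 46.22, 32.38, 66.21))
  z <- zonation_from_totals(totals)
  expect_equal(z$printed_pct_total[z$class == "CRUB"], 28.98)
  expect_equal(z$printed_mean_object_area[z$class == "CRUB"], 0.18)
  expect_equal(z$printed_pct_total[z$class == "HEMS"], 30.14)
  expect_equal(z$printed_mean_object_area[z$class == "HEMS"], 0.22)
  expect_equal(z$total_area[z$class == "TOTAL"], 2333.43)
  # percentage columns sum to 100 within rounding
  expect_lt(abs(sum(z$pct_total[z$class != "TOTAL"]) - 100), 1e-9)
  expect_lt(abs(sum(z$printed_pct_total[z$class != "TOTAL"]) - 100), 0.05)
})

test_that("a single object covering the scene gives 100% everywhere", {
  o <- data.table::data.table(segment_id = 1L, class = "HEMS",
                              area = 192, mound_area = 40)
  z <- zonation_stats(o)
  expect_equal(z$pct_total, c(100, 100))
  expect_equal(z$pct_mound, c(100, 100))
})

test_that("mound-enclosed area exceeding a class total is rejected as inconsistent", {
  totals <- data.frame(class = c("SPG", "HEMS"),
                       total_area = c(46.22, 100),
                       n_objects = c(10, 10),
                       mound_area = c(56.62, 50))
  expect_warning(zonation_from_totals(totals), "exceeds")
})

test_that("classified object areas are exact pixel sums and intersect the mound", {
  sc <- small_scene()
  sm <- small_segmap()
  truth <- majority_labels(sm, sc$class_map)
  objs <- classified_objects(sm, truth, sc$boundary)
  cell2 <- sm$labels$cell_size^2
  expect_equal(objs$area, sm$stats$n * cell2)
  expect_true(all(objs$mound_area <= objs$area + 1e-9))
  expect_true(any(objs$mound_area > 0))
  z <- zonation_stats(objs)
  expect_lt(abs(sum(z$pct_total[z$class != "TOTAL"]) - 100), 1e-9)
  expect_equal(z$total_area[z$class == "TOTAL"],
               rg_nrow(sm$labels) * rg_ncol(sm$labels) * cell2)
})

test_that("Gi* matches a double-loop oracle and flags degenerate fields", {
  expect_error(gi_star(matrix(5, 4, 4), 1, 2), "zero variance")
  # single nonzero interior cell: its Z is positive and maximal (interior
  # placement keeps every covering neighbourhood the same size, so the
  # mass-bearing cells tie at the maximum)
  v <- matrix(0, 12, 12); v[6, 6] <- 10
  f <- gi_star(v, 1, 1.5)
  z_at <- f$z[f$row == 6 & f$col == 6]
  expect_gt(z_at, 0)
  expect_equal(z_at, max(f$z))
  # random fields vs oracle
  set.seed(30)
  for (case in 1:4) {
    v <- matrix(rexp(36), 6, 6)
    f <- gi_star(v, 1, 2.5)
    expect_equal(f$z, oracle_gi_star(v, 1, 2.5), tolerance = 1e-10)
  }
  # confidence bins follow the 1.645 / 1.960 / 2.576 thresholds everywhere
  want <- as.character(cut(abs(f$z), c(-Inf, 1.645, 1.960, 2.576, Inf),
                           labels = c("none", "90", "95", "99")))
  expect_identical(f$conf, want)
})

test_that("spatially shuffled fields rarely reach 99% confidence", {
  set.seed(31)
  base <- matrix(rexp(100), 10, 10)
  frac <- numeric(20)
  for (i in 1:20) {
    v <- matrix(sample(base), 10, 10)
    f <- gi_star(v, 1, 3)
    frac[i] <- mean(abs(f$z) > 2.576)
  }
  expect_lte(mean(frac), 0.05)
})

test_that("Z-depth correlation is 1 when Z mirrors depth and ~0 when shuffled", {
  nr <- 12; nc <- 12
  depth <- matrix(-976 + 0.1 * col(matrix(0, nr, nc)), nr, nc)
  bathy <- raster_grid(depth, origin_y = nr, cell_size = 1)
  field <- data.table::data.table(
    row = as.vector(row(depth)), col = as.vector(col(depth)),
    x = as.vector(col(depth)) - 0.5, y = nr - as.vector(row(depth)) + 0.5,
    value = 0, z = as.vector(depth), conf = "none")
  out <- zscore_depth_scatter(field, bathy, cell_size = 1)
  expect_equal(out$r, 1, tolerance = 1e-12)
  # seeded shuffle: permutation interval covers 0
  set.seed(32)
  rs <- replicate(200, {
    f2 <- data.table::copy(field)
    f2$z <- sample(f2$z)
    zscore_depth_scatter(f2, bathy, cell_size = 1)$r
  })
  expect_lt(quantile(rs, 0.025), 0)
  expect_gt(quantile(rs, 0.975), 0)
  expect_error(zscore_depth_scatter(field[1:2], bathy, 1), "insufficient")
})

test_that("aspect histograms concentrate where the generator put the organisms", {
  # uniform north-facing slope: all objects in the bin containing 0 deg
  n <- 40
  z <- matrix(rep(-976 - 0.2 * (seq_len(n) - 1) * 0.5, times = n), n, n)
  bathy <- raster_grid(z, origin_y = n * 0.5, cell_size = 0.5)
  lab <- matrix(rep(1:4, each = 100), 20, 20)
  sm <- segmap_from_labels(lab, cell = 1, origin_y = 20)
  classes <- c("LCN", "LCN", "SPG", "HEMS")
  # depth decreases southward (row increases) -> downslope south... flip so north
  z2 <- matrix(rep(-976 + 0.2 * (seq_len(n) - 1) * 0.5, times = n), n, n)
  bathy2 <- raster_grid(z2, origin_y = n * 0.5, cell_size = 0.5)
  ap <- aspect_polar(sm, classes, bathy2, target = c("LCN"), n_bins = 36)
  h <- ap$LCN$hist
  expect_equal(sum(h$count), 2)
  expect_equal(h$count[1], 2L)   # first bin starts at north
  expect_equal(sum(h$count), 2L + 0L)
  # counts sum to number of non-flat target objects
  expect_equal(sum(h$count) + ap$LCN$n_flat, 2L)
  # empty class warns
  expect_warning(aspect_polar(sm, classes, bathy2, target = "PEB"), "no objects")
})

test_that("synthetic-scene hotspots sit where the zonation rules placed the classes", {
  sc <- small_scene()
  sm <- small_segmap()
  truth <- majority_labels(sm, sc$class_map)
  pr <- prediction_raster(sm, truth)
  lcn <- hotspot_field(pr, "LCN", cell_size = 1, band_distance = 3)
  hot <- lcn[lcn$conf == "99"]
  expect_gt(nrow(hot), 0)
  # north half of the 6x8 scene is y > 4
  expect_gt(mean(hot$y), 4)
  spg <- hotspot_field(pr, "SPG", cell_size = 1, band_distance = 3)
  sct <- zscore_depth_scatter(spg, sc$bathy, 1)
  expect_gt(sct$r, 0)  # sponges near the shallow summit: hotter when shallower
})
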