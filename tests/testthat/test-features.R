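
test_that("spectral means and brightness match direct aggregation", {
  # constant colour
  v <- array(0, c(4, 4, 3))
  v[, , 1] <- 10; v[, , 2] <- 20; v[, , 3] <- 30
  sm <- segmap_from_labels(matrix(1L, 4, 4))
  mo <- raster_grid(v, origin_y = 4, band_names = c("red", "green", "blue"))
  sp <- spectral_features(sm, mo)
  expect_equal(sp$mean_red, 10)
  expect_equal(sp$mean_green, 20)
  expect_equal(sp$mean_blue, 30)
  expect_equal(sp$brightness, 60)

  # 2-pixel segment (0,0,0) and (255,255,255): brightness 3 * 127.5
  lab <- matrix(c(1L, 1L, 2L, 2L), 2, 2)
  v2 <- array(0, c(2, 2, 3)); v2[1, 2, ] <- 255; v2[2, 2, ] <- 255
  v2[2, 1, ] <- 255
  sm2 <- segmap_from_labels(lab)
  mo2 <- raster_grid(v2, origin_y = 2, band_names = c("red", "green", "blue"))
  sp2 <- spectral_features(sm2, mo2)
  expect_equal(sp2$brightness[1], 382.5)  # (0+255)/2 per band, summed

  # random segments equal naive per-pixel oracle
  set.seed(77)
  lab3 <- matrix(sample(1:3, 36, replace = TRUE), 6, 6)
  for (k in 1:3) if (!any(lab3 == k)) lab3[k] <- k
  lab3 <- matrix(as.integer(factor(lab3)), 6, 6)
  v3 <- array(runif(108) * 255, c(6, 6, 3))
  sm3 <- segmap_from_labels(lab3)
  mo3 <- raster_grid(v3, origin_y = 6, band_names = c("red", "green", "blue"))
  sp3 <- spectral_features(sm3, mo3)
  for (k in sort(unique(as.vector(lab3)))) {
    expect_equal(sp3$mean_red[k], mean(v3[, , 1][lab3 == k]))
    expect_equal(sp3$brightness[k],
                 mean(v3[, , 1][lab3 == k]) + mean(v3[, , 2][lab3 == k]) +
                   mean(v3[, , 3][lab3 == k]))
  }
  expect_error(spectral_features(sm, raster_grid(matrix(1, 4, 4))), "3-band")
})

test_that("GLCM features match hand-enumerated and brute-force oracles", {
  # constant segment: homogeneity 1, entropy 0
  sm <- segmap_from_labels(matrix(1L, 4, 4))
  g <- raster_grid(matrix(5, 4, 4), origin_y = 4)
  tx <- texture_features(sm, g)
  expect_equal(tx$glcm_homogeneity, 1)
  expect_equal(tx$glcm_entropy, 0)

  # 2x2 block with levels [[0,1],[0,1]] at G = 2: hand-enumerated pairs
  # H: 2 pairs (0,1); V: 1 pair (0,0), 1 pair (1,1); D,AD: 1 pair (0,1) each.
  lev <- matrix(c(0, 0, 1, 1), 2, 2)   # column-major: col1 = 0s, col2 = 1s
  smb <- segmap_from_labels(matrix(1L, 2, 2))
  gb <- raster_grid(lev, origin_y = 2)
  txb <- texture_features(smb, gb, levels = 2L)
  oh <- oracle_glcm(lev, matrix(TRUE, 2, 2), 2L)
  expect_equal(txb$glcm_homogeneity, oh$homogeneity, tolerance = 1e-12)
  expect_equal(txb$glcm_entropy, oh$entropy, tolerance = 1e-12)
  expect_equal(txb$glcm_mean, oh$mean, tolerance = 1e-12)
  # hand values: P_H = off-diag only -> hom 1/2; P_V = diag only -> hom 1;
  # diagonals off-diag -> 1/2 each (d=1 offsets at |i-j|=1 have 1/(1+1))
  expect_equal(oh$homogeneity, mean(c(0.5, 1, 0.5, 0.5)))

  # random 6x6 patches, multiple segments, vs double-loop oracle
  set.seed(88)
  for (case in 1:4) {
    lab <- matrix(sample(1:2, 36, replace = TRUE), 6, 6)
    lab <- matrix(as.integer(factor(lab)), 6, 6)
    v <- matrix(runif(36) * 100, 6, 6)
    smr <- segmap_from_labels(lab)
    gr <- raster_grid(v, origin_y = 6)
    txr <- texture_features(smr, gr, levels = 8L)
    rng <- range(v)
    lv <- pmin(floor((v - rng[1]) / diff(rng) * 8), 7)
    for (k in sort(unique(as.vector(lab)))) {
      o <- oracle_glcm(lv, lab == k, 8L)
      if (is.null(o)) next
      i <- match(k, txr$segment_id)
      expect_equal(txr$glcm_homogeneity[i], o$homogeneity, tolerance = 1e-12)
      expect_equal(txr$glcm_entropy[i], o$entropy, tolerance = 1e-12)
      expect_equal(txr$glcm_mean[i], o$mean, tolerance = 1e-12)
    }
  }
})

test_that("degenerate footprints fall back to single-cell texture values", {
  # two segments; segment 2 occupies one pixel -> one intensity cell
  lab <- matrix(1L, 3, 3); lab[2, 2] <- 2L
  sm <- segmap_from_labels(lab)
  g <- raster_grid(matrix(1:9, 3, 3), origin_y = 3)
  tx <- texture_features(sm, g, levels = 4L)
  i <- match(2L, tx$segment_id)
  expect_true(tx$glcm_degenerate[i])
  expect_equal(tx$glcm_homogeneity[i], 1)
  expect_equal(tx$glcm_entropy[i], 0)
})

test_that("shape features have their closed-form values on canonical shapes", {
  # single pixel
  sm1 <- segmap_from_labels(matrix(1L, 1, 1))
  s1 <- shape_features(sm1)
  expect_equal(s1$shape_index, 1)
  expect_equal(s1$roundness, 4 * pi / 16)
  expect_equal(s1$asymmetry, 0)
  expect_equal(s1$area, 1)
  expect_equal(s1$border_length, 4)

  # 10x10 square: e = 40, shape_index 1, rectangular fit ~ 1
  sm2 <- segmap_from_labels(matrix(1L, 10, 10))
  s2 <- shape_features(sm2)
  expect_equal(s2$shape_index, 1)
  expect_equal(s2$border_index, 1)
  expect_gt(s2$rectangular_fit, 0.95)
  expect_equal(s2$main_direction, 0)  # isotropic: defined as north

  # 1x20 east-west bar
  sm3 <- segmap_from_labels(matrix(1L, 1, 20))
  s3 <- shape_features(sm3)
  expect_equal(s3$main_direction, 90)
  expect_gt(s3$asymmetry, 0.95)
  expect_lt(s3$elliptic_fit, s3$rectangular_fit)

  # rotating the bar by 90 degrees rotates main_direction by 90 (mod 180)
  sm4 <- segmap_from_labels(matrix(1L, 20, 1))
  s4 <- shape_features(sm4)
  expect_equal((s3$main_direction - s4$main_direction) %% 180, 90)
})

test_that("dimensionless shape metrics survive x2 pixel replication", {
  set.seed(99)
  lab <- matrix(1L, 8, 8)
  lab[3:6, 2:7] <- 2L; lab[5:8, 5:8] <- 3L
  lab <- matrix(as.integer(factor(lab)), 8, 8)
  sm <- segmap_from_labels(lab)
  s <- shape_features(sm)
  lab2 <- lab[rep(1:8, each = 2), rep(1:8, each = 2)]
  sm2 <- segmap_from_labels(lab2, cell = 0.5)
  s2 <- shape_features(sm2)
  for (col in c("shape_index", "roundness", "compactness", "asymmetry",
                "rectangular_fit", "elliptic_fit")) {
    expect_equal(s2[[col]], s[[col]], tolerance = 0.02,
                 info = paste("column", col))
  }
  expect_equal(s2$area, s$area)  # metric area is resolution-independent
})

test_that("bathymetric features recover analytic plane and bell geometry", {
  n <- 20
  x <- (seq_len(n) - 0.5) * 0.5
  z <- matrix(rep(-976 + 0.1 * x, each = n), n, n)
  bathy <- raster_grid(z, origin_y = n * 0.5, cell_size = 0.5)
  # segment 1 sits in the grid interior so Horn edge replication does not
  # bias its aggregate; segment 2 absorbs the borders
  lab <- matrix(2L, 40, 40)
  lab[6:34, 6:20] <- 1L
  sm <- segmap_from_labels(lab, cell = 0.25, origin_y = 10)
  bf <- bathy_features(sm, bathy)
  expect_equal(bf$slope[1], atan(0.1) * 180 / pi, tolerance = 1e-6)
  expect_equal(bf$aspect[1], 270, tolerance = 1e-6)
  expect_equal(bf$mean_depth[1], mean(z[3:17, 3:10]), tolerance = 1e-9)
  expect_false(any(bf$aspect_flat))

  # flat: slope 0, aspect flagged
  bflat <- raster_grid(matrix(-976, n, n), origin_y = 10, cell_size = 0.5)
  bf2 <- bathy_features(sm, bflat)
  expect_equal(bf2$slope, c(0, 0))
  expect_true(all(bf2$aspect_flat))

  # bell: segment north of the summit has aspect near 0/360
  sp <- scene_spec(width_m = 6, height_m = 6, mosaic_cell = 0.05,
                   bathy_cell = 0.25, mound_sigma_x = 1, mound_sigma_y = 1.4,
                   bathy_noise_sd = 0, regional_slope = c(x = 0, y = 0),
                   seed = 1)
  b <- generate_bathymetry(sp)
  lab3 <- matrix(2L, 120, 120)
  lab3[30:45, 55:65] <- 1L  # due north of centre
  sm3 <- segmap_from_labels(lab3, cell = 0.05, origin_y = 6)
  bf3 <- bathy_features(sm3, b)
  expect_lt(angle_diff_deg(bf3$aspect[1], 0), 10)
})

test_that("the assembled feature table is column-complete and composes", {
  lab <- matrix(1L, 10, 10); lab[, 6:10] <- 2L
  v <- array(runif(300) * 255, c(10, 10, 3))
  sm <- segmap_from_labels(lab, cell = 0.1, origin_y = 1, values = v)
  mo <- raster_grid(v, origin_y = 1, cell_size = 0.1,
                    band_names = c("red", "green", "blue"))
  bathy <- raster_grid(matrix(-976 + runif(16), 4, 4), origin_y = 1,
                       cell_size = 0.25)
  ft <- suppressMessages(build_feature_table(sm, mo, bathy))
  expect_equal(nrow(ft), 2)
  expect_true(all(feature_columns() %in% names(ft)))
  expect_length(feature_columns(), 22)
  # column-wise equality with individually invoked operations
  sp <- spectral_features(sm, mo)
  expect_equal(ft$mean_red, sp$mean_red)
  sh <- shape_features(sm)
  expect_equal(ft$shape_index, sh$shape_index)
  bf <- bathy_features(sm, bathy)
  expect_equal(ft$mean_depth, bf$mean_depth)
})

test_that("on the synthetic scene live coral is brighter than sediment objects", {
  sc <- small_scene()
  sm <- small_segmap()
  ft <- build_feature_table(sm, sc$mosaic, sc$bathy, sc$backscatter)
  truth <- majority_labels(sm, sc$class_map)
  expect_gt(mean(ft$brightness[truth == "LCN"]),
            mean(ft$brightness[truth == "HEMS"]))
})
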