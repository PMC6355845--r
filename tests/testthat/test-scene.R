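# The scene generator defines the study conditions for the whole pipeline;
# these tests pin its contracts: analytic limits, zonation rules,
# determinism and internal consistency.

flat_spec <- function(...) scene_spec(
  width_m = 4, height_m = 4, mosaic_cell = 0.02, bathy_cell = 0.5,
  mound_height = 0, bathy_noise_sd = 0, regional_slope = c(x = 0, y = 0),
  n_lcn = 0, n_spg = 0, n_peb = 0, n_other = 0, seed = 7, ...)

test_that("flat scene: every bathymetry cell equals the base depth", {
  b <- generate_bathymetry(flat_spec())
  expect_true(all(rg_band(b, 1) == -976))
})

test_that("noise-free bell peaks at base_depth + mound_height at the centre cell", {
  # odd cell count so a cell centre coincides with the mound centre
  sp <- scene_spec(width_m = 2.5, height_m = 2.5, mosaic_cell = 0.025,
                   bathy_cell = 0.5, mound_height = 4, bathy_noise_sd = 0,
                   regional_slope = c(x = 0, y = 0),
                   mound_sigma_x = 0.6, mound_sigma_y = 0.8, seed = 1)
  b <- generate_bathymetry(sp)
  z <- rg_band(b, 1)
  expect_equal(max(z), -972.0)
  expect_equal(unname(which(z == max(z), arr.ind = TRUE)[1, ]), c(3, 3))
})

test_that("generators are bit-identical under one seed and differ across seeds", {
  mk <- function(seed) {
    sp <- scene_spec(width_m = 4, height_m = 4, mosaic_cell = 0.02,
                     bathy_cell = 0.25, mound_sigma_x = 0.8,
                     mound_sigma_y = 1.1, n_lcn = 4, n_spg = 5, n_peb = 8,
                     n_other = 1, seed = seed)
    b <- generate_bathymetry(sp)
    cm <- generate_class_map(sp, b)
    list(b = b, cm = cm, mo = render_mosaic(cm, sp),
         bs = generate_backscatter(cm, sp))
  }
  a <- mk(7); b <- mk(7); c <- mk(8)
  expect_identical(a$b$values, b$b$values)
  expect_identical(a$cm$values, b$cm$values)
  expect_identical(a$mo$values, b$mo$values)
  expect_identical(a$bs$values, b$bs$values)
  expect_false(identical(a$b$values, c$b$values))
  expect_false(identical(a$mo$values, c$mo$values))
})

test_that("zero biogenic patch counts leave only sediment classes", {
  sp <- flat_spec()
  b <- generate_bathymetry(sp)
  cm <- generate_class_map(sp, b)
  ids <- sort(unique(as.vector(rg_band(cm, 1))))
  ct <- class_table()
  expect_true(all(ct$hierarchy[match(ids, ct$id)] == "Sediment"))
})

test_that("live-coral patch centres lie in the configured north aspect sector", {
  sc <- small_scene()
  p <- attr(sc$class_map, "patches")
  lcn <- p[p$class == "LCN", ]
  expect_gte(nrow(lcn), sc$spec$min_patches)
  terr <- terrain_derivatives(sc$bathy)
  asp <- rg_band(terr$aspect, 1)
  rc <- world_to_pixel(sc$bathy, lcn$x, lcn$yn)
  a <- asp[cbind(rc$r, rc$c)]
  expect_true(all(is.finite(a)))
  expect_true(all(angle_diff_deg(a, 0) <= sc$spec$north_sector_halfwidth))
})

test_that("reported class fractions equal fractions recomputed from the raster", {
  sc <- small_scene()
  fr <- attr(sc$class_map, "class_fractions")
  v <- as.vector(rg_band(sc$class_map, 1))
  recomputed <- tabulate(v, 8) / length(v)
  expect_identical(unname(fr), recomputed)
  expect_equal(sum(fr), 1)
})

test_that("single-class map with zero noise renders the exact class colour", {
  sp <- scene_spec(width_m = 1, height_m = 1, mosaic_cell = 0.02,
                   bathy_cell = 0.25, noise_sd = 0, texture_amp = 0, seed = 1)
  ct <- class_table()
  lab <- raster_grid(matrix(ct$id[ct$code == "HEMS"], 50, 50),
                     origin_y = 1, cell_size = 0.02)
  mo <- render_mosaic(lab, sp)
  hems <- ct[ct$code == "HEMS", ]
  expect_true(all(mo$values[, , 1] == hems$r))
  expect_true(all(mo$values[, , 2] == hems$g))
  expect_true(all(mo$values[, , 3] == hems$b))
})

test_that("per-class mean mosaic colour stays within the noise level of the spec", {
  sc <- small_scene()
  ct <- class_table()
  lab <- rg_band(sc$class_map, 1)
  for (id in sort(unique(as.vector(lab)))) {
    m <- lab == id
    if (sum(m) < 500) next
    for (b in 1:3) {
      got <- mean(sc$mosaic$values[, , b][m])
      want <- ct[ct$id == id, c("r", "g", "b")][[b]]
      expect_lt(abs(got - want), sc$spec$noise_sd)
    }
  }
})

test_that("backscatter is brighter over coral rubble than over hemipelagic sediment", {
  sc <- small_scene()
  ct <- class_table()
  tmpl <- sc$backscatter
  labc <- rg_band(rg_resample_nn(sc$class_map, tmpl), 1)
  bs <- rg_band(sc$backscatter, 1)
  expect_gt(mean(bs[labc == ct$id[ct$code == "CRUB"]]),
            mean(bs[labc == ct$id[ct$code == "HEMS"]]))
  # single-class map with zero noise gives a constant raster
  sp0 <- scene_spec(width_m = 1, height_m = 1, mosaic_cell = 0.02,
                    bathy_cell = 0.25, noise_sd = 0, seed = 1)
  lab0 <- raster_grid(matrix(4, 50, 50), origin_y = 1, cell_size = 0.02)
  bs0 <- generate_backscatter(lab0, sp0)
  expect_true(all(rg_band(bs0, 1) == ct$bs_mean[4]))
})

test_that("all scene rasters share the same world extent", {
  sc <- small_scene()
  for (g in list(sc$class_map, sc$mosaic, sc$backscatter))
    expect_equal(rg_extent(g), rg_extent(sc$bathy))
})

test_that("mound boundary: flat scene errors, bell matches analytic contour", {
  expect_error(mound_boundary(generate_bathymetry(flat_spec()), 10),
               "empty boundary")
  sp <- scene_spec(width_m = 8, height_m = 8, mosaic_cell = 0.02,
                   bathy_cell = 0.1, mound_height = 4, bathy_noise_sd = 0,
                   regional_slope = c(x = 0, y = 0),
                   mound_sigma_x = 1.2, mound_sigma_y = 1.2, seed = 1)
  b <- generate_bathymetry(sp)
  thr <- 10
  mb <- mound_boundary(b, thr)
  # outer radius of the slope contour: |dz/dr| = h r / s^2 exp(-r^2/2s^2)
  h <- 4; s <- 1.2
  f <- function(r) h * r / s^2 * exp(-r^2 / (2 * s^2)) - tan(thr * pi / 180)
  r_out <- uniroot(f, c(s, 6 * s))$root
  analytic <- pi * r_out^2
  expect_lt(abs(attr(mb, "area_m2") - analytic) / analytic, 0.10)
  # the shallowest cell lies inside the boundary polygon
  z <- rg_band(b, 1)
  am <- which(z == max(z), arr.ind = TRUE)[1, ]
  w <- pixel_to_world(b, am[1], am[2])
  expect_true(point_in_rings(w$x, w$y, list(mb)))
})

test_that("a scene too small to host the patch classes errors out", {
  sp <- scene_spec(width_m = 1, height_m = 1, mosaic_cell = 0.02,
                   bathy_cell = 0.5, mound_height = 0, n_lcn = 5,
                   seed = 1)
  b <- generate_bathymetry(sp)
  expect_error(generate_class_map(sp, b), "scene too small|configuration")
})
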