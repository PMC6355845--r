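#' Synthetic benthic scene specification
#'
#' Describes a desk-scale stand-in for a reef-scale cold-water coral mound
#' survey: an ovoid mound (Gaussian bell, elongated north-south) rising from
#' a gently sloping seabed, imaged by a fine RGB photo-mosaic and a much
#' coarser bathymetry/backscatter grid. Defaults give a 12 x 16 m scene with
#' an 8 mm mosaic (1500 x 2000 px) and 0.25 m bathymetry, preserving the
#' two-orders-of-magnitude resolution gap between survey mosaic and
#' multibeam products without multi-gigapixel rasters.
#'
#' The facies scheme has seven mapped classes plus a rare unclassified one:
#' live coral framework (LCN), dead coral framework (DC), sponges (SPG),
#' hemipelagic sediment (HEMS), hemipelagic sediment with dropstones
#' (HESDR), coral rubble (CRUB), dropstones/pebbles (PEB) and OTHER
#' (shadows etc., excluded from training). Zonation follows the typical
#' mound pattern: a DC/CRUB-covered mound core, live coral patches
#' restricted to the north-facing flank, sponges around the summit and
#' upper west flank, and HEMS/HESDR off-mound with dropstones/pebbles
#' preferentially to the south.
#'
#' @param width_m,height_m scene extent (m), east-west and north-south.
#' @param mosaic_cell,bathy_cell pixel sizes (m) of the mosaic and the
#'   bathymetry/backscatter grids; extents must divide into whole pixels and
#'   `mosaic_cell <= bathy_cell`.
#' @param base_depth background depth (m, negative down).
#' @param mound_height mound relief (m, > 0; 0 disables the mound).
#' @param mound_sigma_x,mound_sigma_y Gaussian half-widths (m); the default
#'   `sigma_y > sigma_x` gives the current-aligned ovoid shape.
#' @param regional_slope length-2 numeric `c(x, y)`: depth gain per metre
#'   east and per metre north (positive y makes the south deeper).
#' @param bathy_noise_sd sd (m) of smoothed bathymetric noise.
#' @param noise_sd sd of per-pixel RGB noise (8-bit units).
#' @param texture_amp global multiplier on class texture amplitudes.
#' @param n_lcn,n_spg,n_peb,n_other patch counts per patchy class.
#' @param min_patches minimum patches required for each requested patchy
#'   class; placement failure below this is a configuration error.
#' @param north_sector_halfwidth half-width (degrees) of the north aspect
#'   sector to which live-coral patches are restricted.
#' @param mound_core_frac fraction of `mound_height` above which a cell
#'   counts as mound core (DC/CRUB background, biogenic patch host).
#' @param seed integer seed; all generator randomness derives from it.
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(width_m = 12, height_m = 16,
                       mosaic_cell = 0.008, bathy_cell = 0.25,
                       base_depth = -976, mound_height = 4,
                       mound_sigma_x = 2.2, mound_sigma_y = 3.2,
                       regional_slope = c(x = 0, y = 0.03),
                       bathy_noise_sd = 0.02,
                       noise_sd = 8, texture_amp = 1,
                       n_lcn = 25, n_spg = 30, n_peb = 60, n_other = 4,
                       min_patches = 3,
                       north_sector_halfwidth = 45,
                       mound_core_frac = 0.10,
                       seed = 1L) {
  if (mosaic_cell <= 0 || bathy_cell <= 0) stop("cell sizes must be positive")
  if (mosaic_cell > bathy_cell) stop("mosaic_cell must be <= bathy_cell")
  if (base_depth >= 0) stop("base_depth must be negative (metres below sea level)")
  if (mound_height < 0) stop("mound_height must be >= 0")
  for (cs in c(mosaic_cell, bathy_cell)) {
    if (abs(width_m / cs - round(width_m / cs)) > 1e-9 ||
        abs(height_m / cs - round(height_m / cs)) > 1e-9)
      stop("scene extent must divide into whole pixels at every cell size")
  }
  structure(list(
    width_m = width_m, height_m = height_m,
    mosaic_cell = mosaic_cell, bathy_cell = bathy_cell,
    base_depth = base_depth, mound_height = mound_height,
    mound_sigma_x = mound_sigma_x, mound_sigma_y = mound_sigma_y,
    regional_slope = c(x = unname(regional_slope[1]), y = unname(regional_slope[2])),
    bathy_noise_sd = bathy_noise_sd,
    noise_sd = noise_sd, texture_amp = texture_amp,
    n_lcn = n_lcn, n_spg = n_spg, n_peb = n_peb, n_other = n_other,
    min_patches = min_patches,
    north_sector_halfwidth = north_sector_halfwidth,
    mound_core_frac = mound_core_frac,
    seed = as.integer(seed)
  ), class = "scene_spec")
}

#' Facies class table
#'
#' Class codes, integer raster ids, hierarchy tags, display colours (8-bit
#' RGB used by the renderer), texture style and amplitude, and backscatter
#' intensity statistics (hard substrates brighter than sediments).
#'
#' @return data.frame, one row per class (OTHER last).
#' @export
class_table <- function() {
  data.frame(
    code = c("LCN", "DC", "SPG", "HEMS", "HESDR", "CRUB", "PEB", "OTHER"),
    id = 1:8,
    name = c("live coral framework", "dead coral framework", "sponges",
             "hemipelagic sediment", "hemipelagic sediment with dropstones",
             "coral rubble", "dropstones/pebbles", "other/unclassified"),
    hierarchy = c("Biogenic", "Biogenic", "Biogenic", "Sediment", "Sediment",
                  "Biogenic", "Sediment", "Other"),
    r = c(235, 150, 240, 152, 122, 185, 50, 25),
    g = c(190, 148, 230, 130, 106, 168, 48, 25),
    b = c(185, 142, 170, 100, 86, 138, 46, 28),
    texture = c("blotch", "blotch", "fine", "none", "blotch", "speckle",
                "speckle", "none"),
    tex_amp = c(12, 10, 10, 3, 8, 10, 6, 2),
    bs_mean = c(175, 190, 150, 90, 120, 200, 210, 80),
    bs_sd = c(14, 14, 12, 8, 9, 14, 14, 8),
    stringsAsFactors = FALSE
  )
}

# Gaussian bell relief (m) evaluated at world coordinates (x east from the
# west edge, yn north from the south edge); centred in the scene.
scene_bell <- function(spec, x, yn) {
  cx <- spec$width_m / 2; cy <- spec$height_m / 2
  spec$mound_height * exp(-((x - cx)^2 / (2 * spec$mound_sigma_x^2) +
                              (yn - cy)^2 / (2 * spec$mound_sigma_y^2)))
}

# Cell-centre coordinate vectors for a grid of the scene at `cell` metres.
scene_axes <- function(spec, cell) {
  nc <- round(spec$width_m / cell); nr <- round(spec$height_m / cell)
  list(nr = nr, nc = nc,
       x = (seq_len(nc) - 0.5) * cell,            # east from west edge
       yn = spec$height_m - (seq_len(nr) - 0.5) * cell)  # north from south edge
}

# Smooth unit-variance noise field: white noise blurred by `passes` rounds
# of a 3x3 box filter (replicated edges), then standardised.
smooth_field <- function(nr, nc, passes = 2L) {
  f <- matrix(stats::rnorm(nr * nc), nr, nc)
  for (i in seq_len(passes)) {
    p <- pad_edge1(f)
    f <- (p[1:nr, 1:nc] + p[1:nr, 2:(nc + 1)] + p[1:nr, 3:(nc + 2)] +
          p[2:(nr + 1), 1:nc] + p[2:(nr + 1), 2:(nc + 1)] + p[2:(nr + 1), 3:(nc + 2)] +
          p[3:(nr + 2), 1:nc] + p[3:(nr + 2), 2:(nc + 1)] + p[3:(nr + 2), 3:(nc + 2)]) / 9
  }
  s <- stats::sd(f)
  if (s > 0) f <- (f - mean(f)) / s
  f
}

#' Generate the bathymetry grid
#'
#' Depth plane = base depth + regional planar slope + Gaussian bell mound +
#' smoothed seeded noise, on the `bathy_cell` grid. Deterministic for a
#' fixed spec seed. The shallowest (numerically largest) cell lies on the
#' mound when one is present.
#'
#' @param spec a [scene_spec()].
#' @return single-band `raster_grid` of depth (m, negative down).
#' @export
generate_bathymetry <- function(spec) {
  ax <- scene_axes(spec, spec$bathy_cell)
  xm <- matrix(ax$x, ax$nr, ax$nc, byrow = TRUE)
  ym <- matrix(ax$yn, ax$nr, ax$nc)
  z <- spec$base_depth +
    spec$regional_slope[["x"]] * (xm - spec$width_m / 2) +
    spec$regional_slope[["y"]] * (ym - spec$height_m / 2) +
    scene_bell(spec, xm, ym)
  if (spec$bathy_noise_sd > 0) {
    z <- z + with_seed(derive_seed(spec$seed, "bathymetry"),
                       smooth_field(ax$nr, ax$nc, passes = 2L)) * spec$bathy_noise_sd
  }
  raster_grid(z, origin_x = 0, origin_y = spec$height_m,
              cell_size = spec$bathy_cell, band_names = "depth")
}

# Paint a filled rotated ellipse (world coords, semi-axes in m) with value
# `id` into label matrix `lab` laid out on a grid of `cell` metres.
# Optional `only_over`: restrict painting to pixels currently holding one of
# these ids. Returns the updated matrix.
paint_ellipse <- function(lab, cell, height_m, cx, cyn, a, b, theta_deg, id,
                          only_over = NULL) {
  nr <- nrow(lab); nc <- ncol(lab)
  rad <- max(a, b)
  c0 <- max(1L, floor((cx - rad) / cell) + 1L); c1 <- min(nc, ceiling((cx + rad) / cell))
  ry0 <- height_m - (cyn + rad); ry1 <- height_m - (cyn - rad)
  r0 <- max(1L, floor(ry0 / cell) + 1L); r1 <- min(nr, ceiling(ry1 / cell))
  if (c1 < c0 || r1 < r0) return(lab)
  xs <- (c0:c1 - 0.5) * cell - cx
  ys <- (height_m - (r0:r1 - 0.5) * cell) - cyn
  th <- theta_deg * pi / 180
  xm <- matrix(xs, length(ys), length(xs), byrow = TRUE)
  ym <- matrix(ys, length(ys), length(xs))
  u <- xm * cos(th) + ym * sin(th)
  v <- -xm * sin(th) + ym * cos(th)
  m <- (u / a)^2 + (v / b)^2 <= 1
  if (!is.null(only_over)) m <- m & matrix(lab[r0:r1, c0:c1] %in% only_over, nrow(m))
  sub <- lab[r0:r1, c0:c1]; sub[m] <- id; lab[r0:r1, c0:c1] <- sub
  lab
}

#' Generate the ground-truth facies map
#'
#' Builds the label raster on the mosaic grid from the bathymetry and the
#' zonation rules: DC/CRUB background on the mound core, live-coral patches
#' only where the bathymetric aspect falls in the configured north sector,
#' sponge patches near the summit and upper west flank, HEMS/HESDR
#' off-mound with dropstone/pebble patches weighted to the south, and a few
#' shadow streaks for OTHER. Patch geometry is seeded and recorded.
#'
#' @param spec a [scene_spec()].
#' @param bathy output of [generate_bathymetry()] for the same spec.
#' @return single-band `raster_grid` of class ids (see [class_table()]),
#'   with attributes `patches` (data.frame: class, x, yn, a, b, theta) and
#'   `class_fractions` (named fractions recomputed from the emitted raster).
#' @export
generate_class_map <- function(spec, bathy) {
  ct <- class_table()
  id_of <- function(code) ct$id[match(code, ct$code)]
  ax <- scene_axes(spec, spec$mosaic_cell)
  if (ax$nr < 4 || ax$nc < 4) stop("scene too small for class map generation")

  terr <- terrain_derivatives(bathy)
  aspect_b <- rg_band(terr$aspect, 1L)
  bx <- scene_axes(spec, spec$bathy_cell)

  xm <- matrix(ax$x, ax$nr, ax$nc, byrow = TRUE)
  ym <- matrix(ax$yn, ax$nr, ax$nc)
  bell <- scene_bell(spec, xm, ym)
  core <- spec$mound_core_frac * spec$mound_height
  mound <- spec$mound_height > 0 & bell > core

  sd_ <- derive_seed(spec$seed, "class_map")
  with_seed(sd_, {
    # --- backgrounds ---------------------------------------------------
    # coarse mixing fields generated at bathy resolution, replicated up
    f1 <- smooth_field(bx$nr, bx$nc, 3L)
    f2 <- smooth_field(bx$nr, bx$nc, 3L)
    up <- function(f) {
      ri <- pmin(bx$nr, floor((seq_len(ax$nr) - 0.5) * bx$nr / ax$nr) + 1L)
      ci <- pmin(bx$nc, floor((seq_len(ax$nc) - 0.5) * bx$nc / ax$nc) + 1L)
      f[ri, ci]
    }
    lab <- matrix(id_of("HEMS"), ax$nr, ax$nc)
    southness <- (spec$height_m - ym) / spec$height_m     # 0 north .. 1 south
    offm <- !mound
    hesdr <- offm & (up(f2) + 1.5 * (southness - 0.5) > 0)
    lab[hesdr] <- id_of("HESDR")
    if (any(mound)) {
      crub <- mound & (up(f1) > -0.2)   # rubble slightly favoured over DC
      lab[mound] <- id_of("DC")
      lab[crub] <- id_of("CRUB")
    }

    patches <- list()
    add_patch <- function(code, cx, cyn, a, b, th)
      patches[[length(patches) + 1L]] <<- data.frame(
        class = code, x = cx, yn = cyn, a = a, b = b, theta = th)

    # class at the mosaic pixel under each bathy cell centre (patch hosts:
    # live coral and sponges settle on dead framework, not loose rubble)
    host_class <- function() {
      rr <- pmin(ax$nr, floor((seq_len(bx$nr) - 0.5) * ax$nr / bx$nr) + 1L)
      cc <- pmin(ax$nc, floor((seq_len(bx$nc) - 0.5) * ax$nc / bx$nc) + 1L)
      matrix(lab[rr, cc], bx$nr, bx$nc)
    }

    # --- live coral: north-sector flank cells on dead framework ---------
    if (spec$n_lcn > 0) {
      sect <- angle_diff_deg(aspect_b, 0) <= spec$north_sector_halfwidth
      bell_b <- scene_bell(spec, matrix(bx$x, bx$nr, bx$nc, byrow = TRUE),
                           matrix(bx$yn, bx$nr, bx$nc))
      ok <- sect & !is.na(aspect_b) & bell_b > core
      on_dc <- ok & host_class() == id_of("DC")
      if (sum(on_dc) >= spec$min_patches) ok <- on_dc
      cand <- which(ok, arr.ind = TRUE)
      if (nrow(cand) < spec$min_patches)
        stop("scene too small: no north-sector mound cells to host live coral")
      pick <- cand[sample.int(nrow(cand), spec$n_lcn, replace = nrow(cand) < spec$n_lcn), ,
                   drop = FALSE]
      for (i in seq_len(nrow(pick))) {
        cx <- (pick[i, 2] - 0.5 + stats::runif(1, -0.4, 0.4)) * spec$bathy_cell
        cyn <- spec$height_m - (pick[i, 1] - 0.5 + stats::runif(1, -0.4, 0.4)) * spec$bathy_cell
        a <- stats::runif(1, 0.25, 0.40); b <- a * stats::runif(1, 0.6, 1)
        th <- stats::runif(1, 0, 180)
        lab <- paint_ellipse(lab, spec$mosaic_cell, spec$height_m, cx, cyn, a, b,
                             th, id_of("LCN"))
        add_patch("LCN", cx, cyn, a, b, th)
      }
    }

    # --- sponges: summit and upper west flank ---------------------------
    if (spec$n_spg > 0) {
      if (!any(mound)) stop("scene configuration: sponges require a mound")
      bell_b <- scene_bell(spec, matrix(bx$x, bx$nr, bx$nc, byrow = TRUE),
                           matrix(bx$yn, bx$nr, bx$nc))
      west <- matrix(bx$x, bx$nr, bx$nc, byrow = TRUE) < spec$width_m / 2
      ok <- bell_b > 0.45 * spec$mound_height |
        (bell_b > core & west &
           angle_diff_deg(aspect_b, 270) <= 60 & !is.na(aspect_b))
      on_dc <- ok & host_class() == id_of("DC")
      if (sum(on_dc) >= spec$min_patches) ok <- on_dc
      cand <- which(ok, arr.ind = TRUE)
      if (nrow(cand) < spec$min_patches)
        stop("scene too small: no summit/west-flank cells to host sponges")
      pick <- cand[sample.int(nrow(cand), spec$n_spg, replace = nrow(cand) < spec$n_spg), ,
                   drop = FALSE]
      for (i in seq_len(nrow(pick))) {
        cx <- (pick[i, 2] - 0.5 + stats::runif(1, -0.4, 0.4)) * spec$bathy_cell
        cyn <- spec$height_m - (pick[i, 1] - 0.5 + stats::runif(1, -0.4, 0.4)) * spec$bathy_cell
        a <- stats::runif(1, 0.15, 0.28); b <- a * stats::runif(1, 0.8, 1)
        th <- stats::runif(1, 0, 180)
        lab <- paint_ellipse(lab, spec$mosaic_cell, spec$height_m, cx, cyn, a, b,
                             th, id_of("SPG"))
        add_patch("SPG", cx, cyn, a, b, th)
      }
    }

    # --- dropstones / pebbles: off-mound, south-weighted ----------------
    if (spec$n_peb > 0) {
      offc <- which(offm[seq(1, ax$nr, by = 25), seq(1, ax$nc, by = 25), drop = FALSE],
                    arr.ind = TRUE)   # subsampled candidate lattice (0.2 m)
      if (nrow(offc) < spec$min_patches)
        stop("scene too small: no off-mound cells to host pebbles")
      row_of <- function(i) (i - 1) * 25 + 1
      cyn_c <- spec$height_m - (row_of(offc[, 1]) - 0.5) * spec$mosaic_cell
      w <- 1 + 3 * (spec$height_m - cyn_c) / spec$height_m
      pick <- offc[sample.int(nrow(offc), spec$n_peb, prob = w,
                              replace = nrow(offc) < spec$n_peb), , drop = FALSE]
      for (i in seq_len(nrow(pick))) {
        cx <- (row_of(pick[i, 2]) - 0.5 + stats::runif(1, -12, 12)) * spec$mosaic_cell
        cyn <- spec$height_m - (row_of(pick[i, 1]) - 0.5 + stats::runif(1, -12, 12)) * spec$mosaic_cell
        a <- stats::runif(1, 0.12, 0.25); b <- a * stats::runif(1, 0.7, 1)
        th <- stats::runif(1, 0, 180)
        lab <- paint_ellipse(lab, spec$mosaic_cell, spec$height_m, cx, cyn, a, b,
                             th, id_of("PEB"),
                             only_over = id_of(c("HEMS", "HESDR")))
        add_patch("PEB", cx, cyn, a, b, th)
      }
    }

    # --- shadows and other rare objects ---------------------------------
    if (spec$n_other > 0) {
      for (i in seq_len(spec$n_other)) {
        cx <- stats::runif(1, 0.05, 0.95) * spec$width_m
        cyn <- stats::runif(1, 0.05, 0.95) * spec$height_m
        a <- stats::runif(1, 0.4, 0.8); b <- stats::runif(1, 0.03, 0.05)
        th <- stats::runif(1, 0, 180)
        lab <- paint_ellipse(lab, spec$mosaic_cell, spec$height_m, cx, cyn, a, b,
                             th, id_of("OTHER"))
        add_patch("OTHER", cx, cyn, a, b, th)
      }
    }
  })

  patch_df <- if (length(patches)) do.call(rbind, patches) else
    data.frame(class = character(), x = numeric(), yn = numeric(),
               a = numeric(), b = numeric(), theta = numeric())
  requested <- c(LCN = spec$n_lcn, SPG = spec$n_spg, PEB = spec$n_peb,
                 OTHER = spec$n_other)
  present <- ct$code[ct$id %in% unique(as.vector(lab))]
  for (code in names(requested)) {
    if (requested[[code]] >= spec$min_patches && !(code %in% present))
      stop(sprintf("scene too small: class %s was requested but fully overpainted", code))
  }

  g <- raster_grid(lab, origin_x = 0, origin_y = spec$height_m,
                   cell_size = spec$mosaic_cell, band_names = "class_id")
  tab <- tabulate(as.vector(lab), nbins = 8L)
  fr <- tab / sum(tab); names(fr) <- ct$code
  attr(g, "patches") <- patch_df
  attr(g, "class_fractions") <- fr
  g
}

#' Render the RGB video-mosaic analogue
#'
#' Each class is drawn with its configured mean colour plus a zero-mean,
#' class-specific texture (smooth for sediments, speckle for rubble and
#' pebbles, coarse blotch for coral frameworks and dropstone fields, fine
#' bright mottle for sponges) plus Gaussian pixel noise, clamped to 8 bits.
#' Because textures and noise are zero-mean, per-class mean colour over the
#' ground-truth masks stays within the noise level of the configured colours.
#'
#' @param class_map label raster from [generate_class_map()] (nearest-
#'   neighbour upsampled first if on a coarser grid than the mosaic).
#' @param spec a [scene_spec()].
#' @return 3-band 8-bit `raster_grid` (`red`, `green`, `blue`).
#' @export
render_mosaic <- function(class_map, spec) {
  ct <- class_table()
  ax <- scene_axes(spec, spec$mosaic_cell)
  if (rg_nrow(class_map) != ax$nr || rg_ncol(class_map) != ax$nc) {
    template <- raster_grid(matrix(0, ax$nr, ax$nc), 0, spec$height_m, spec$mosaic_cell)
    class_map <- rg_resample_nn(class_map, template)
  }
  lab <- rg_band(class_map, 1L)
  ids <- sort(unique(as.vector(lab)))
  if (!all(ids %in% ct$id)) stop("unknown class id in class map")
  nr <- nrow(lab); nc <- ncol(lab)

  with_seed(derive_seed(spec$seed, "mosaic"), {
    # shared standardized texture fields
    tex <- list(none = matrix(0, nr, nc))
    styles <- unique(ct$texture[ct$id %in% ids])
    if ("speckle" %in% styles) tex$speckle <- matrix(stats::rnorm(nr * nc), nr, nc)
    if ("blotch" %in% styles || "fine" %in% styles) {
      # blotch: noise at 1/8 resolution (~6 cm grain); fine: 1/4 (~3 cm)
      mk <- function(k) {
        f <- smooth_field(ceiling(nr / k), ceiling(nc / k), 1L)
        f <- f[rep(seq_len(nrow(f)), each = k), rep(seq_len(ncol(f)), each = k)]
        f[seq_len(nr), seq_len(nc)]
      }
      if ("blotch" %in% styles) tex$blotch <- mk(8L)
      if ("fine" %in% styles) tex$fine <- mk(4L)
    }
    out <- array(0, c(nr, nc, 3L))
    for (id in ids) {
      m <- lab == id
      row <- ct[ct$id == id, ]
      t_amp <- spec$texture_amp * row$tex_amp
      tfield <- tex[[row$texture]][m] * t_amp
      base <- c(row$r, row$g, row$b)
      for (b in 1:3) {
        nz <- if (spec$noise_sd > 0) stats::rnorm(sum(m), 0, spec$noise_sd) else 0
        plane <- out[, , b]
        plane[m] <- base[b] + tfield + nz
        out[, , b] <- plane
      }
    }
    out <- round(pmin(pmax(out, 0), 255))
  }) -> out
  raster_grid(out, origin_x = 0, origin_y = spec$height_m,
              cell_size = spec$mosaic_cell, band_names = c("red", "green", "blue"))
}

#' Generate the backscatter intensity grid
#'
#' Single-band intensity raster on the bathymetry grid: per-class mean
#' intensity (hard substrates -- rubble, pebbles, coral framework -- brighter
#' than sediments) plus seeded Gaussian noise with class-specific variance.
#'
#' @param class_map label raster from [generate_class_map()].
#' @param spec a [scene_spec()].
#' @return single-band `raster_grid` named `backscatter`.
#' @export
generate_backscatter <- function(class_map, spec) {
  ct <- class_table()
  ax <- scene_axes(spec, spec$bathy_cell)
  template <- raster_grid(matrix(0, ax$nr, ax$nc), 0, spec$height_m, spec$bathy_cell)
  labc <- rg_band(rg_resample_nn(class_map, template), 1L)
  ids <- sort(unique(as.vector(labc)))
  if (!all(ids %in% ct$id)) stop("unknown class id in class map")
  with_seed(derive_seed(spec$seed, "backscatter"), {
    bs <- matrix(0, ax$nr, ax$nc)
    for (id in ids) {
      m <- labc == id
      row <- ct[ct$id == id, ]
      nz <- if (row$bs_sd > 0 && spec$noise_sd > 0)
        stats::rnorm(sum(m), 0, row$bs_sd) else 0
      bs[m] <- row$bs_mean + nz
    }
    bs
  }) -> bs
  raster_grid(bs, origin_x = 0, origin_y = spec$height_m,
              cell_size = spec$bathy_cell, band_names = "backscatter")
}

#' Delimit the mound by its topographic break
#'
#' Computes Horn slope on the bathymetry, takes the connected region where
#' slope exceeds the threshold (the steep mound flank), keeps the largest
#' connected component, fills enclosed holes (so the low-slope summit is
#' inside), and traces the filled region's outer boundary as a polygon in
#' world coordinates.
#'
#' @param bathy single-band depth `raster_grid`.
#' @param slope_threshold_deg slope (degrees) defining the break; > 0.
#' @return a polygon as `list(x, y)` of the closed outer ring (world m),
#'   with attribute `area_m2` (area of the filled pixel region).
#' @export
mound_boundary <- function(bathy, slope_threshold_deg = 10) {
  if (slope_threshold_deg <= 0) stop("slope threshold must be positive")
  slope <- rg_band(terrain_derivatives(bathy)$slope, 1L)
  mask <- slope > slope_threshold_deg
  if (!any(mask)) stop("empty boundary: no cell exceeds the slope threshold")
  comp <- label_components(mask)
  sizes <- tabulate(comp[comp > 0])
  big <- which.max(sizes)
  filled <- fill_holes(comp == big)
  rings <- mask_rings(filled, bathy)
  outer <- rings[[which.max(vapply(rings, function(r) abs(ring_signed_area(r)), 0))]]
  out <- list(x = outer$x, y = outer$y)
  attr(out, "area_m2") <- sum(filled) * bathy$cell_size^2
  class(out) <- "mound_polygon"
  out
}

#' Generate a full synthetic scene
#'
#' Convenience wrapper running the bathymetry, facies map, mosaic and
#' backscatter generators plus the mound boundary tracer.
#'
#' @param spec a [scene_spec()].
#' @param boundary_slope_deg slope threshold handed to [mound_boundary()];
#'   set `NULL` to skip the boundary (e.g. for flat scenes).
#' @return list with `spec`, `bathy`, `class_map`, `mosaic`, `backscatter`,
#'   `boundary`.
#' @export
simulate_scene <- function(spec = scene_spec(), boundary_slope_deg = 10) {
  bathy <- generate_bathymetry(spec)
  cmap <- generate_class_map(spec, bathy)
  mosaic <- render_mosaic(cmap, spec)
  bs <- generate_backscatter(cmap, spec)
  boundary <- if (!is.null(boundary_slope_deg))
    mound_boundary(bathy, boundary_slope_deg) else NULL
  list(spec = spec, bathy = bathy, class_map = cmap, mosaic = mosaic,
       backscatter = bs, boundary = boundary)
}

# 4-connected component labelling of a logical matrix (0 = background).
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  comp <- matrix(0L, nr, nc)
  cur <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (comp[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    comp[start] <- cur
    while (length(stack)) {
      p <- stack[length(stack)]; stack <- stack[-length(stack)]
      r <- (p - 1L) %% nr + 1L; c <- (p - 1L) %/% nr + 1L
      for (q in c(if (r > 1) p - 1L, if (r < nr) p + 1L,
                  if (c > 1) p - nr, if (c < nc) p + nr)) {
        if (mask[q] && comp[q] == 0L) { comp[q] <- cur; stack <- c(stack, q) }
      }
    }
  }
  comp
}

# Fill holes: background components not touching the border become foreground.
fill_holes <- function(mask) {
  bg <- label_components(!mask)
  border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  border <- border[border > 0]
  mask | (bg > 0 & !(bg %in% border))
}
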