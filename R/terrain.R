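#' Terrain derivatives of a bathymetry grid
#'
#' Slope and aspect follow Horn's 3x3 weighted-difference method; curvature
#' is the Laplacian of depth. Depth is stored as negative metres below sea
#' level (elevation convention), so "up" is toward less negative values and
#' the mound summit is the grid maximum.
#'
#' Aspect is the compass direction of steepest *descent* (downslope),
#' degrees clockwise from grid north in `[0, 360)`. Cells flatter than
#' `flat_tol` degrees of slope carry `NA` aspect (flat flag).
#'
#' Edges are handled by replicating the border row/column before applying
#' the stencil.
#'
#' @param bathy single-band `raster_grid` of depth (m, negative down).
#' @param flat_tol slope (degrees) below which a cell is treated as flat
#'   for aspect purposes.
#' @return list of three single-band `raster_grid`s: `slope` (degrees,
#'   `[0, 90]`), `aspect` (degrees from north, `[0, 360)` or `NA` when flat)
#'   and `curvature` (Laplacian of depth, 1/m).
#' @export
terrain_derivatives <- function(bathy, flat_tol = 1e-6) {
  z <- rg_band(bathy, 1L)
  cell <- bathy$cell_size
  zp <- pad_edge1(z)
  nr <- nrow(z); nc <- ncol(z)
  ri <- seq_len(nr) + 1L; ci <- seq_len(nc) + 1L
  # neighbours named by compass position around each cell
  nw <- zp[ri - 1L, ci - 1L]; n_ <- zp[ri - 1L, ci]; ne <- zp[ri - 1L, ci + 1L]
  w_ <- zp[ri, ci - 1L];                              e_ <- zp[ri, ci + 1L]
  sw <- zp[ri + 1L, ci - 1L]; s_ <- zp[ri + 1L, ci]; se <- zp[ri + 1L, ci + 1L]
  # Horn gradients: x east, y north (row index grows southward)
  gx <- ((ne + 2 * e_ + se) - (nw + 2 * w_ + sw)) / (8 * cell)
  gy <- ((nw + 2 * n_ + ne) - (sw + 2 * s_ + se)) / (8 * cell)
  slope <- atan(sqrt(gx^2 + gy^2)) * 180 / pi
  # downslope vector is -grad(z); azimuth measured clockwise from north
  az <- atan2(-gx, -gy) * 180 / pi
  az <- (az + 360) %% 360
  az[slope < flat_tol] <- NA_real_
  # 5-point Laplacian with replicated edges
  curv <- (e_ + w_ + n_ + s_ - 4 * z) / cell^2
  g <- function(m, nm) raster_grid(m, bathy$origin_x, bathy$origin_y, cell,
                                   NA_real_, nm)
  list(slope = g(slope, "slope"), aspect = g(az, "aspect"),
       curvature = g(curv, "curvature"))
}

#' Circular mean of aspect angles
#'
#' @param deg angles in degrees; `NA`s removed.
#' @return mean direction in `[0, 360)`, or `NA` if no finite input.
#' @export
circular_mean_deg <- function(deg) {
  deg <- deg[is.finite(deg)]
  if (length(deg) == 0L) return(NA_real_)
  rad <- deg * pi / 180
  m <- atan2(mean(sin(rad)), mean(cos(rad))) * 180 / pi
  (m + 360) %% 360
}

#' Smallest absolute angular difference between two directions (degrees)
#' @param a,b directions in degrees.
#' @return difference in `[0, 180]`.
#' @export
angle_diff_deg <- function(a, b) {
  d <- abs((a - b) %% 360)
  pmin(d, 360 - d)
}
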