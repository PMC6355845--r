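#' Georeferenced raster grid
#'
#' A minimal in-memory raster: a matrix (single band) or a rows x cols x bands
#' array, with planar metric georeferencing. The coordinate convention is
#' UTM-like: `origin_x`, `origin_y` locate the *upper-left corner* of the
#' grid in metres, the column index grows eastward and the row index grows
#' southward. Pixel `(r, c)` (1-based) covers the half-open square
#' `[origin_x + (c-1)*cell, origin_x + c*cell) x (origin_y - r*cell,
#' origin_y - (r-1)*cell]`.
#'
#' @param values numeric matrix (rows x cols) or 3-D array (rows x cols x bands).
#' @param origin_x,origin_y world coordinates (m) of the upper-left corner.
#' @param cell_size pixel edge length in metres; must be positive.
#' @param nodata sentinel value marking missing cells (default `NA`).
#' @param band_names optional character vector, one name per band.
#' @return an object of class `raster_grid`.
#' @export
raster_grid <- function(values, origin_x = 0, origin_y = 0, cell_size = 1,
                        nodata = NA_real_, band_names = NULL) {
  if (!is.numeric(values) && !is.logical(values) && !is.integer(values))
    stop("raster values must be numeric")
  if (is.null(dim(values))) stop("raster values must be a matrix or 3-D array")
  nd <- length(dim(values))
  if (nd == 2L) values <- array(values, c(dim(values), 1L))
  if (length(dim(values)) != 3L) stop("raster values must be 2-D or 3-D")
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("cell_size must be a single positive number")
  if (dim(values)[1] < 1L || dim(values)[2] < 1L)
    stop("raster must have at least one row and one column")
  nb <- dim(values)[3]
  if (is.null(band_names)) band_names <- paste0("band_", seq_len(nb))
  if (length(band_names) != nb) stop("band_names length must equal band count")
  structure(
    list(values = values, origin_x = origin_x, origin_y = origin_y,
         cell_size = cell_size, nodata = nodata, band_names = band_names),
    class = "raster_grid"
  )
}

#' @export
print.raster_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("raster_grid: %d x %d px, %d band(s) [%s]\n", d[1], d[2], d[3],
              paste(x$band_names, collapse = ", ")))
  cat(sprintf("  cell %g m, origin (%.3f, %.3f), extent %g x %g m\n",
              x$cell_size, x$origin_x, x$origin_y,
              d[2] * x$cell_size, d[1] * x$cell_size))
  invisible(x)
}

#' @rdname raster_grid
#' @param x a `raster_grid`.
#' @export
rg_nrow <- function(x) dim(x$values)[1]

#' @rdname raster_grid
#' @export
rg_ncol <- function(x) dim(x$values)[2]

#' @rdname raster_grid
#' @export
rg_nbands <- function(x) dim(x$values)[3]

#' Single band as a matrix
#' @param x a `raster_grid`.
#' @param band band index or name.
#' @export
rg_band <- function(x, band = 1L) {
  if (is.character(band)) band <- match(band, x$band_names)
  if (is.na(band) || band < 1L || band > rg_nbands(x)) stop("unknown band")
  m <- x$values[, , band, drop = FALSE]
  dim(m) <- dim(m)[1:2]
  m
}

#' World extent of a raster
#' @param x a `raster_grid`.
#' @return named vector `xmin, xmax, ymin, ymax` (m).
#' @export
rg_extent <- function(x) {
  c(xmin = x$origin_x,
    xmax = x$origin_x + rg_ncol(x) * x$cell_size,
    ymin = x$origin_y - rg_nrow(x) * x$cell_size,
    ymax = x$origin_y)
}

#' Pixel centre to world coordinates
#'
#' @param x a `raster_grid`.
#' @param r,c 1-based row/column indices (vectors).
#' @return data.frame with `x`, `y` world coordinates of pixel centres (m).
#' @export
pixel_to_world <- function(x, r, c) {
  data.frame(x = x$origin_x + (c - 0.5) * x$cell_size,
             y = x$origin_y - (r - 0.5) * x$cell_size)
}

#' World coordinates to pixel indices
#'
#' Uses the half-open pixel footprint, so a point on a shared pixel edge
#' belongs to the pixel to its east/south.
#'
#' @param x a `raster_grid`.
#' @param wx,wy world coordinates (m).
#' @return data.frame with 1-based `r`, `c`; indices may fall outside the grid.
#' @export
world_to_pixel <- function(x, wx, wy) {
  data.frame(r = as.integer(floor((x$origin_y - wy) / x$cell_size)) + 1L,
             c = as.integer(floor((wx - x$origin_x) / x$cell_size)) + 1L)
}

#' Nearest-neighbour resampling of a raster onto another grid geometry
#'
#' Every target cell takes the value of the source cell containing its
#' centre (clamped to the source extent for sub-cell overhang).
#'
#' @param x source `raster_grid`.
#' @param template `raster_grid` providing the target geometry.
#' @return a `raster_grid` on the template geometry with `x`'s bands.
#' @export
rg_resample_nn <- function(x, template) {
  nr <- rg_nrow(template); nc <- rg_ncol(template)
  ctr_x <- template$origin_x + (seq_len(nc) - 0.5) * template$cell_size
  ctr_y <- template$origin_y - (seq_len(nr) - 0.5) * template$cell_size
  sc <- pmin(pmax(floor((ctr_x - x$origin_x) / x$cell_size) + 1L, 1L), rg_ncol(x))
  sr <- pmin(pmax(floor((x$origin_y - ctr_y) / x$cell_size) + 1L, 1L), rg_nrow(x))
  nb <- rg_nbands(x)
  out <- array(0, c(nr, nc, nb))
  for (b in seq_len(nb)) out[, , b] <- x$values[, , b][cbind(rep(sr, nc), rep(sc, each = nr))]
  raster_grid(out, template$origin_x, template$origin_y, template$cell_size,
              nodata = x$nodata, band_names = x$band_names)
}

#' Luminance (Rec. 601) of an RGB raster
#' @param x a 3-band `raster_grid`.
#' @return single-band `raster_grid` named `luminance`.
#' @export
rg_luminance <- function(x) {
  if (rg_nbands(x) != 3L) stop("luminance requires a 3-band RGB raster")
  lum <- 0.299 * x$values[, , 1] + 0.587 * x$values[, , 2] + 0.114 * x$values[, , 3]
  raster_grid(lum, x$origin_x, x$origin_y, x$cell_size, x$nodata, "luminance")
}

# Replicate-pad a matrix by one cell on every side (edge clamping for
# 3x3 stencils).
pad_edge1 <- function(m) {
  m2 <- m[c(1, seq_len(nrow(m)), nrow(m)), c(1, seq_len(ncol(m)), ncol(m))]
  m2
}
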