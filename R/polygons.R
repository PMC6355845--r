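# Polygon plumbing: tracing pixel-boundary rings from raster masks,
# shoelace areas, even-odd point-in-polygon, and rasterization. Rings are
# closed coordinate sequences (first vertex repeated last) in world metres.

# Trace boundary rings of a logical mask laid out on `grid` (a raster_grid
# supplying georeferencing). Returns a list of rings, each `list(x, y)`.
# Edges are directed so that mask interior lies on a fixed side; at
# checkerboard vertices the walk takes the interior-side turn, so rings
# never cross and even-odd rasterization reproduces the mask exactly.
mask_rings <- function(mask, grid, r_off = 0L, c_off = 0L) {
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(list())
  r <- idx[, 1]; c <- idx[, 2]
  at <- function(rr, cc) {
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    v <- logical(length(rr)); v[ok] <- mask[cbind(rr[ok], cc[ok])]
    v
  }
  # directed edges in pixel-corner coordinates (x = col, y = row, y down)
  sx <- ex <- sy <- ey <- numeric(0)
  add <- function(keep, x0, y0, x1, y1) {
    sx <<- c(sx, x0[keep]); sy <<- c(sy, y0[keep])
    ex <<- c(ex, x1[keep]); ey <<- c(ey, y1[keep])
  }
  add(!at(r - 1L, c), c - 1, r - 1, c, r - 1)        # top: eastward
  add(!at(r, c + 1L), c, r - 1, c, r)                # right: southward
  add(!at(r + 1L, c), c, r, c - 1, r)                # bottom: westward
  add(!at(r, c - 1L), c - 1, r, c - 1, r - 1)        # left: northward
  ne <- length(sx)
  key <- function(x, y) x + y * (nc + 1)
  starts <- key(sx, sy)
  ord <- order(starts)
  skeys <- starts[ord]
  used <- logical(ne)
  lookup <- function(k) {
    i <- findInterval(k, skeys)
    out <- integer(0)
    while (i >= 1 && i <= ne && skeys[i] == k) { out <- c(out, ord[i]); i <- i - 1L }
    out
  }
  rings <- list()
  for (e0 in seq_len(ne)) {
    if (used[e0]) next
    rx <- sx[e0]; ry <- sy[e0]
    cur <- e0
    ring_x <- sx[e0]; ring_y <- sy[e0]
    repeat {
      used[cur] <- TRUE
      ring_x <- c(ring_x, ex[cur]); ring_y <- c(ring_y, ey[cur])
      if (ex[cur] == rx && ey[cur] == ry) break
      cand <- lookup(key(ex[cur], ey[cur]))
      cand <- cand[!used[cand]]
      if (length(cand) == 0L) stop("ring tracing failed (open chain)")
      if (length(cand) > 1L) {
        din <- c(ex[cur] - sx[cur], ey[cur] - sy[cur])
        crossz <- vapply(cand, function(j)
          din[1] * (ey[j] - sy[j]) - din[2] * (ex[j] - sx[j]), 0)
        cand <- cand[which.max(crossz)]
      }
      cur <- cand[1]
    }
    rings[[length(rings) + 1L]] <- list(
      x = grid$origin_x + (c_off + ring_x) * grid$cell_size,
      y = grid$origin_y - (r_off + ring_y) * grid$cell_size)
  }
  rings
}

# Shoelace signed area of one closed ring (world coordinates).
ring_signed_area <- function(ring) {
  x <- ring$x; y <- ring$y
  n <- length(x)
  sum(x[-n] * y[-1] - x[-1] * y[-n]) / 2
}

#' Total area enclosed by a set of rings (holes subtract)
#'
#' Rings traced by the package's boundary tracer carry opposite orientations
#' for outer rings and holes, so the absolute value of the summed signed
#' areas is the enclosed area.
#'
#' @param rings list of rings (`list(x, y)` each).
#' @return area in m^2.
#' @export
polygon_area <- function(rings) {
  if (!length(rings)) return(0)
  abs(sum(vapply(rings, ring_signed_area, 0)))
}

#' Even-odd point-in-polygon test
#'
#' @param px,py point coordinates (vectors, world m).
#' @param rings list of rings (`list(x, y)` each); holes included.
#' @return logical vector: inside by the even-odd rule.
#' @export
point_in_rings <- function(px, py, rings) {
  inside <- logical(length(px))
  for (ring in rings) {
    x <- ring$x; y <- ring$y
    n <- length(x) - 1L
    for (i in seq_len(n)) {
      x1 <- x[i]; y1 <- y[i]; x2 <- x[i + 1L]; y2 <- y[i + 1L]
      if (y1 == y2) next
      crosses <- ((y1 > py) != (y2 > py)) &
        (px < x1 + (py - y1) * (x2 - x1) / (y2 - y1))
      inside <- xor(inside, crosses)
    }
  }
  inside
}

#' Vectorize a segment map into per-segment polygons
#'
#' One polygon (outer ring plus holes) per segment, tracing pixel
#' boundaries in world coordinates. Polygon areas sum exactly to the
#' raster area in pixel units.
#'
#' @param segmap a `segment_map` (see [segment_mosaic()]).
#' @return list with one element per segment id:
#'   `list(segment_id, rings, area_m2)`.
#' @export
segments_to_polygons <- function(segmap) {
  labels <- rg_band(segmap$labels, 1L)
  grid <- segmap$labels
  st <- segmap$stats
  out <- vector("list", nrow(st))
  for (i in seq_len(nrow(st))) {
    r0 <- st$rmin[i]; r1 <- st$rmax[i]; c0 <- st$cmin[i]; c1 <- st$cmax[i]
    m <- labels[r0:r1, c0:c1, drop = FALSE] == st$segment_id[i]
    rings <- mask_rings(m, grid, r_off = r0 - 1L, c_off = c0 - 1L)
    out[[i]] <- list(segment_id = st$segment_id[i], rings = rings,
                     area_m2 = polygon_area(rings))
  }
  out
}

#' Rasterize polygons back to a label grid
#'
#' Pixel centres are tested against each polygon's rings by the even-odd
#' rule; later polygons overwrite earlier ones where they overlap.
#'
#' @param polys list as returned by [segments_to_polygons()].
#' @param template `raster_grid` supplying the target geometry.
#' @return single-band `raster_grid` of polygon ids (0 = none).
#' @export
rasterize_polygons <- function(polys, template) {
  nr <- rg_nrow(template); nc <- rg_ncol(template)
  lab <- matrix(0, nr, nc)
  cx <- template$origin_x + (seq_len(nc) - 0.5) * template$cell_size
  cy <- template$origin_y - (seq_len(nr) - 0.5) * template$cell_size
  pxm <- matrix(cx, nr, nc, byrow = TRUE)
  pym <- matrix(cy, nr, nc)
  for (p in polys) {
    xs <- range(unlist(lapply(p$rings, `[[`, "x")))
    ys <- range(unlist(lapply(p$rings, `[[`, "y")))
    box <- pxm >= xs[1] & pxm <= xs[2] & pym >= ys[1] & pym <= ys[2]
    sel <- which(box)
    if (!length(sel)) next
    ins <- point_in_rings(pxm[sel], pym[sel], p$rings)
    lab[sel[ins]] <- p$segment_id
  }
  raster_grid(lab, template$origin_x, template$origin_y, template$cell_size,
              band_names = "polygon_id")
}
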