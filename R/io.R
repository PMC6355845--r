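# Raster and vector I/O. Rasters are stored as TIFF (via the tiff package)
# with a JSON sidecar (<path>.aux.json) carrying georeferencing, nodata,
# band names and the value scaling: 8-bit storage is exact for integer
# rasters in [0, 255]; other rasters are min-max scaled into 32-bit floats,
# so round-trips are exact for integer data and float32-precision
# otherwise. Vectors are GeoJSON.

#' Write a raster to TIFF + JSON sidecar
#'
#' @param grid a `raster_grid`.
#' @param path output path (`.tif`); the sidecar goes to `<path>.aux.json`.
#' @return `path`, invisibly.
#' @export
write_raster <- function(grid, path) {
  v <- grid$values
  if (any(!is.finite(v))) {
    if (!is.finite(grid$nodata)) stop("raster has non-finite values and no nodata")
    v[!is.finite(v)] <- grid$nodata
  }
  int8 <- all(v == round(v)) && min(v) >= 0 && max(v) <= 255
  nb <- dim(v)[3]
  if (int8) {
    enc <- list(bits = 8L, scale = rep(255, nb), offset = rep(0, nb))
    arr <- v / 255
  } else {
    lo <- apply(v, 3, min); hi <- apply(v, 3, max)
    scl <- ifelse(hi > lo, hi - lo, 1)
    enc <- list(bits = 32L, scale = scl, offset = lo)
    arr <- array(0, dim(v))
    for (b in seq_len(nb)) arr[, , b] <- (v[, , b] - lo[b]) / scl[b]
  }
  a <- if (nb == 1L) arr[, , 1] else arr
  tiff::writeTIFF(a, path, bits.per.sample = enc$bits, compression = "LZW")
  meta <- list(origin_x = grid$origin_x, origin_y = grid$origin_y,
               cell_size = grid$cell_size, nodata = grid$nodata,
               band_names = grid$band_names, encoding = enc)
  jsonlite::write_json(meta, paste0(path, ".aux.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a raster written by [write_raster()]
#'
#' @param path TIFF path; `<path>.aux.json` must exist (no silent default
#'   georeferencing).
#' @return a `raster_grid`.
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop("no such raster file: ", path)
  sidecar <- paste0(path, ".aux.json")
  if (!file.exists(sidecar))
    stop("missing georeference sidecar for ", path, " (", sidecar, ")")
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  a <- tiff::readTIFF(path)
  if (length(dim(a)) == 2L) a <- array(a, c(dim(a), 1L))
  enc <- meta$encoding
  v <- array(0, dim(a))
  for (b in seq_len(dim(a)[3]))
    v[, , b] <- a[, , b] * enc$scale[b] + enc$offset[b]
  if (enc$bits == 8L) v <- round(v)
  nodata <- if (is.null(meta$nodata)) NA_real_ else meta$nodata
  raster_grid(v, meta$origin_x, meta$origin_y, meta$cell_size,
              nodata, meta$band_names)
}

#' Write polygons with attributes as GeoJSON
#'
#' Each element of `polys` is `list(segment_id, rings)`; the ring with the
#' largest absolute area becomes the polygon shell, remaining rings its
#' holes. `properties` rows (matched by position) become feature
#' properties together with `segment_id`.
#'
#' @param polys list as from [segments_to_polygons()].
#' @param path output `.geojson` path.
#' @param properties optional data.frame, one row per polygon.
#' @return `path`, invisibly.
#' @export
write_vector <- function(polys, path, properties = NULL) {
  feats <- lapply(seq_along(polys), function(i) {
    p <- polys[[i]]
    rings <- p$rings
    if (!length(rings)) return(NULL)
    ord <- order(-vapply(rings, function(r) abs(ring_signed_area(r)), 0))
    coords <- lapply(rings[ord], function(r) {
      lapply(seq_along(r$x), function(k) c(r$x[k], r$y[k]))
    })
    props <- list(segment_id = p$segment_id)
    if (!is.null(properties)) props <- c(props, as.list(properties[i, , drop = FALSE]))
    list(type = "Feature",
         geometry = list(type = "Polygon", coordinates = coords),
         properties = props)
  })
  feats <- feats[!vapply(feats, is.null, TRUE)]
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a GeoJSON polygon layer written by [write_vector()]
#'
#' @param path `.geojson` path.
#' @return list(polys = list(segment_id, rings), properties = data.frame).
#' @export
read_vector <- function(path) {
  if (!file.exists(path)) stop("no such vector file: ", path)
  fc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(fc$type) || fc$type != "FeatureCollection")
    stop("not a GeoJSON FeatureCollection: ", path)
  polys <- list(); props <- list()
  for (f in fc$features) {
    rings <- lapply(f$geometry$coordinates, function(rc) {
      xy <- do.call(rbind, lapply(rc, unlist))
      list(x = xy[, 1], y = xy[, 2])
    })
    polys[[length(polys) + 1L]] <- list(
      segment_id = f$properties$segment_id, rings = rings)
    props[[length(props) + 1L]] <- f$properties
  }
  properties <- if (length(props))
    data.table::rbindlist(lapply(props, function(p)
      as.data.frame(p[names(p) != "segment_id"], stringsAsFactors = FALSE)),
      fill = TRUE)
  else NULL
  list(polys = polys, properties = properties)
}

#' Pipeline configuration
#'
#' Serializable description of a full run: scene parameters, segmentation
#' parameters, feature/texture options, classifier settings, sampling and
#' split parameters, hotspot parameters, global seed. Unknown keys are
#' rejected so configs stay forward-compatible.
#'
#' @param scene named list of [scene_spec()] arguments.
#' @param segmentation named list of [segmentation_params()] arguments.
#' @param glcm_levels grey levels for texture features.
#' @param models character subset of c("LR", "RF", "DNN").
#' @param per_class training samples per class.
#' @param train_fraction stratified split fraction.
#' @param hotspot named list: cell_size, band_distance, classes.
#' @param boundary_slope_deg mound boundary slope threshold (degrees).
#' @param seed global integer seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(scene = list(), segmentation = list(),
                            glcm_levels = 32L,
                            models = c("LR", "RF", "DNN"),
                            per_class = 150L, train_fraction = 0.15,
                            hotspot = list(cell_size = 1, band_distance = 3,
                                           classes = c("LCN", "SPG")),
                            boundary_slope_deg = 10, seed = 1L) {
  known_scene <- names(formals(scene_spec))
  if (length(scene) && !all(names(scene) %in% known_scene))
    stop("unknown scene keys: ",
         paste(setdiff(names(scene), known_scene), collapse = ", "))
  known_seg <- names(formals(segmentation_params))
  if (length(segmentation) && !all(names(segmentation) %in% known_seg))
    stop("unknown segmentation keys: ",
         paste(setdiff(names(segmentation), known_seg), collapse = ", "))
  stopifnot(all(models %in% c("LR", "RF", "DNN")))
  structure(list(scene = scene, segmentation = segmentation,
                 glcm_levels = glcm_levels, models = models,
                 per_class = per_class, train_fraction = train_fraction,
                 hotspot = hotspot, boundary_slope_deg = boundary_slope_deg,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Write / read a pipeline config as YAML
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @return `path` invisibly / the config.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}
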