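# Light-weight planar polygon support: polygons are lists of rings (closed
# coordinate matrices, first ring outer, later rings holes), grouped into
# features with ids. Containment uses even-odd ray casting, so holes and
# multipolygons need no special casing.

#' Build a polygon set
#'
#' @param ids character/vector of feature ids (unique).
#' @param rings_list for each feature, a list of rings; each ring a 2-column
#'   (x, y) matrix. Multipolygon parts are simply additional rings.
#' @return object of class `bupop_polygons`.
#' @export
polygon_set <- function(ids, rings_list) {
  stop_if(length(ids) != length(rings_list), "one ring list per id")
  stop_if(anyDuplicated(ids) > 0, "polygon ids must be unique")
  for (i in seq_along(rings_list)) {
    for (r in rings_list[[i]]) {
      stop_if(!is.matrix(r) || ncol(r) != 2 || nrow(r) < 3,
              "invalid geometry for polygon '", ids[i],
              "': rings need >= 3 (x,y) points")
      stop_if(any(!is.finite(r)), "invalid geometry for polygon '", ids[i],
              "': non-finite coordinates")
    }
  }
  structure(list(ids = as.character(ids), rings = rings_list),
            class = "bupop_polygons")
}

on_segment <- function(px, py, x1, y1, x2, y2, eps = 1e-12) {
  cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
  if (abs(cross) > eps * (abs(x2 - x1) + abs(y2 - y1) + 1)) return(FALSE)
  px >= min(x1, x2) - eps && px <= max(x1, x2) + eps &&
    py >= min(y1, y2) - eps && py <= max(y1, y2) + eps
}

point_in_rings <- function(px, py, rings) {
  inside <- FALSE
  for (r in rings) {
    n <- nrow(r)
    j <- n
    for (i in seq_len(n)) {
      x1 <- r[j, 1]; y1 <- r[j, 2]; x2 <- r[i, 1]; y2 <- r[i, 2]
      if (on_segment(px, py, x1, y1, x2, y2)) return(TRUE)  # boundary counts
      if ((y1 > py) != (y2 > py)) {
        xint <- x1 + (py - y1) / (y2 - y1) * (x2 - x1)
        if (px < xint) inside <- !inside
      }
      j <- i
    }
  }
  inside
}

#' Read polygons from a GeoJSON file
#'
#' Supports FeatureCollections of Polygon and MultiPolygon geometries; the
#' feature id is taken from `properties[[id_field]]` (fallback: feature
#' `id`, then running index).
#'
#' @param path GeoJSON file.
#' @param id_field property carrying the area identifier.
#' @return a `bupop_polygons`.
#' @export
read_geojson_polygons <- function(path, id_field = "id") {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  stop_if(!identical(gj$type, "FeatureCollection"),
          "expected a GeoJSON FeatureCollection")
  ids <- character(0)
  rings <- list()
  for (k in seq_along(gj$features)) {
    f <- gj$features[[k]]
    id <- f$properties[[id_field]] %||% f$id %||% as.character(k)
    geom <- f$geometry
    ring_of <- function(coords)
      do.call(rbind, lapply(coords, function(pt) c(pt[[1]], pt[[2]])))
    rr <- switch(geom$type,
      Polygon = lapply(geom$coordinates, ring_of),
      MultiPolygon = unlist(lapply(geom$coordinates, function(poly)
        lapply(poly, ring_of)), recursive = FALSE),
      stop("unsupported geometry type: ", geom$type, call. = FALSE))
    ids <- c(ids, as.character(id))
    rings <- c(rings, list(rr))
  }
  polygon_set(ids, rings)
}

#' Write polygons to a GeoJSON file
#'
#' @param polys a `bupop_polygons`.
#' @param path output file.
#' @param properties optional data.frame of extra per-feature properties.
#' @param id_field property name for the feature id.
#' @export
write_geojson_polygons <- function(polys, path, properties = NULL,
                                   id_field = "id") {
  feats <- lapply(seq_along(polys$ids), function(k) {
    props <- list()
    props[[id_field]] <- polys$ids[k]
    if (!is.null(properties))
      for (nm in names(properties)) props[[nm]] <- properties[[nm]][k]
    coords <- lapply(polys$rings[[k]], function(r)
      lapply(seq_len(nrow(r)), function(i) c(r[i, 1], r[i, 2])))
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon", coordinates = coords))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
}

#' Write a raster layer (plus georeference sidecar) to TIFF
#'
#' Writes the matrix as a 32-bit float TIFF (requires the `tiff` package)
#' and the affine transform as a JSON sidecar next to it. NA cells are
#' written as the no-data value -1.
#'
#' @param layer numeric matrix (rows = lattice rows).
#' @param transform affine transform list (as attached to grids).
#' @param path output `.tif` path.
#' @export
write_raster_tiff <- function(layer, transform, path) {
  stop_if(!requireNamespace("tiff", quietly = TRUE),
          "the 'tiff' package is required to write TIFF rasters")
  x <- layer
  x[is.na(x)] <- -1
  # the float writer expects [0, 1]; store the affine value mapping alongside
  offset <- min(x)
  scale <- max(max(x) - offset, 1e-12)
  tiff::writeTIFF((x - offset) / scale, path, bits.per.sample = 32L)
  jsonlite::write_json(c(transform, list(value_offset = offset,
                                         value_scale = scale, nodata = -1)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
}
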