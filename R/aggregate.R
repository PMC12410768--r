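#' Assign settled grid cells to areas by cell-centre inclusion
#'
#' Each settled cell belongs to at most one area: polygons are scanned in
#' their stable input order and the first polygon containing the cell
#' centre wins (boundary points count as inside, so a centre exactly on a
#' shared boundary is assigned to the earlier polygon — documented
#' first-wins rule). Cells outside all polygons stay unassigned. Cell
#' counts are whole-cell integers, so no areal weighting is applied.
#'
#' @param grid grid-cell table with centre coordinates `x`, `y`.
#' @param polygons a `bupop_polygons` (validated geometry).
#' @return tibble `cell_id`, `area_id` (NA when unassigned).
#' @export
assign_cells <- function(grid, polygons) {
  stopifnot(inherits(polygons, "bupop_polygons"))
  area <- rep(NA_character_, nrow(grid))
  for (k in seq_along(polygons$ids)) {
    rings <- polygons$rings[[k]]
    # cheap bounding-box prefilter
    bb <- do.call(rbind, rings)
    cand <- which(is.na(area) &
                    grid$x >= min(bb[, 1]) & grid$x <= max(bb[, 1]) &
                    grid$y >= min(bb[, 2]) & grid$y <= max(bb[, 2]))
    for (j in cand)
      if (point_in_rings(grid$x[j], grid$y[j], rings))
        area[j] <- polygons$ids[k]
  }
  tibble::tibble(cell_id = grid$cell_id, area_id = area)
}

#' Aggregate per-draw cell populations to areas
#'
#' Sums the posterior predictive population draws over the member cells of
#' each area, draw by draw (never summaries of summaries), then summarizes
#' the per-area draw vectors: posterior mean, 2.5/97.5 percentile interval
#' and the uncertainty level, defined as the CI width divided by the mean,
#' in percent (reported NA where the mean is 0).
#'
#' @param pred a `bupop_prediction`.
#' @param mapping cell-to-area tibble from [assign_cells()] (or any
#'   data.frame with `cell_id`, `area_id`).
#' @return object of class `bupop_areas`: tibble with `area_id`, `mean`,
#'   `ci_low`, `ci_high`, `uncertainty_pct`, `n_cells`; the per-area draw
#'   matrix is attached as attribute `draws` (areas x draws).
#' @export
aggregate_draws <- function(pred, mapping) {
  stopifnot(inherits(pred, "bupop_prediction"))
  m <- mapping[!is.na(mapping$area_id), , drop = FALSE]
  idx <- match(m$cell_id, pred$cell_id)
  stop_if(anyNA(idx), "mapping refers to cells absent from the prediction")
  ids <- unique(m$area_id)
  draws <- do.call(rbind, lapply(ids, function(a) {
    rows <- idx[m$area_id == a]
    if (length(rows) == 1) pred$P[rows, ] else colSums(pred$P[rows, , drop = FALSE])
  }))
  rownames(draws) <- ids
  qs <- unname(t(apply(draws, 1, posterior_quantile)))
  mean_ <- unname(rowMeans(draws))
  out <- tibble::tibble(
    area_id = ids, mean = mean_, ci_low = qs[, 1], ci_high = qs[, 2],
    uncertainty_pct = ifelse(mean_ > 0, (qs[, 2] - qs[, 1]) / mean_ * 100,
                             NA_real_),
    n_cells = as.integer(unname(table(m$area_id)[ids])))
  attr(out, "draws") <- draws
  class(out) <- c("bupop_areas", class(out))
  out
}

#' Rectangular-block area and zone polygons for a synthetic grid
#'
#' Partitions the grid lattice into `nx x ny` rectangular "health areas"
#' and groups blocks of them into "health zones" (nested levels), returning
#' GeoJSON-ready polygon sets. Useful for pipeline runs and aggregation
#' tests on synthetic landscapes.
#'
#' @param grid a grid table with a `transform` attribute.
#' @param nx,ny number of area blocks along x and y.
#' @param zone_every group `zone_every` x `zone_every` areas per zone.
#' @return list with `areas`, `zones` (both `bupop_polygons`) and
#'   `area_to_zone` lookup tibble.
#' @export
make_block_areas <- function(grid, nx = 4, ny = 4, zone_every = 2) {
  tr <- attr(grid, "transform")
  w <- tr$ncol / nx
  h <- tr$nrow / ny
  ids <- character(0); rings <- list(); zone_of <- character(0)
  for (iy in seq_len(ny)) for (ix in seq_len(nx)) {
    x0 <- (ix - 1) * w; x1 <- ix * w
    y0 <- (iy - 1) * h; y1 <- iy * h
    ids <- c(ids, sprintf("area_%02d_%02d", ix, iy))
    rings <- c(rings, list(list(cbind(c(x0, x1, x1, x0, x0),
                                      c(y0, y0, y1, y1, y0)))))
    zone_of <- c(zone_of, sprintf("zone_%d_%d", ceiling(ix / zone_every),
                                  ceiling(iy / zone_every)))
  }
  zids <- unique(zone_of)
  zrings <- lapply(zids, function(z) {
    parts <- rings[zone_of == z]
    unlist(parts, recursive = FALSE)  # union as multipart rings
  })
  list(areas = polygon_set(ids, rings),
       zones = polygon_set(zids, zrings),
       area_to_zone = tibble::tibble(area_id = ids, zone_id = zone_of))
}
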