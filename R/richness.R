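# Equal-area species richness gridding.
#
# The grid lives in a cylindrical equal-area (Behrmann, standard parallel
# 30 deg) projection on the authalic sphere, so every cell covers the same
# area on the ground. Cells are half-open squares anchored at the projected
# origin (0, 0): cell (i, j) covers [i*s, (i+1)*s) x [j*s, (j+1)*s) km.

COS_SP30 <- sqrt(3) / 2  # cos(30 deg), the Behrmann standard parallel

#' Behrmann equal-area projection
#'
#' Forward projection onto the authalic sphere:
#' `x = R * lambda * cos(30)`, `y = R * sin(phi) / cos(30)` with `lambda`,
#' `phi` in radians and `R = 6371.0088` km.
#'
#' @param lat,lon decimal degrees (vectors).
#' @return list with numeric vectors `x`, `y` in kilometres.
#' @export
behrmann_project <- function(lat, lon) {
  rad <- pi / 180
  list(x = EARTH_RADIUS_KM * (lon * rad) * COS_SP30,
       y = EARTH_RADIUS_KM * sin(lat * rad) / COS_SP30)
}

#' @rdname behrmann_project
#' @param x,y projected kilometres.
#' @export
behrmann_unproject <- function(x, y) {
  rad <- pi / 180
  s <- pmin(pmax(y * COS_SP30 / EARTH_RADIUS_KM, -1), 1)
  list(lat = asin(s) / rad,
       lon = x / (EARTH_RADIUS_KM * COS_SP30) / rad)
}

#' Assign points to equal-area grid cells
#'
#' Deterministic half-open binning of projected coordinates: a point on a
#' cell's lower/left edge belongs to that cell, one on the upper/right edge
#' to the next.
#'
#' @param lat,lon decimal degrees (vectors).
#' @param cell_km cell side length in kilometres.
#' @return data frame with integer columns `cell_x`, `cell_y`.
#' @export
assign_cell <- function(lat, lon, cell_km = 100) {
  stopifnot(cell_km > 0)
  p <- behrmann_project(lat, lon)
  data.frame(cell_x = as.integer(floor(p$x / cell_km)),
             cell_y = as.integer(floor(p$y / cell_km)))
}

#' Gridded species richness
#'
#' Counts the number of distinct species with at least one record in each
#' occupied equal-area cell. Cells without records are not materialized;
#' they have richness 0 by convention, which [richness_difference()]
#' honours.
#'
#' @param records data frame of occurrence records.
#' @param cell_km cell side length in kilometres (default 100).
#' @return a `richness_grid` data frame: `cell_x`, `cell_y`, `center_lat`,
#'   `center_lon`, `richness`, sorted by cell index; `cell_km` is attached
#'   as an attribute.
#' @export
richness <- function(records, cell_km = 100) {
  cells <- assign_cell(records$latitude, records$longitude, cell_km)
  key <- paste(cells$cell_x, cells$cell_y, sep = ":")
  df <- unique(data.frame(key = key, cell_x = cells$cell_x,
                          cell_y = cells$cell_y,
                          species = records$species,
                          stringsAsFactors = FALSE))
  if (nrow(df) == 0L) {
    out <- data.frame(cell_x = integer(), cell_y = integer(),
                      center_lat = numeric(), center_lon = numeric(),
                      richness = integer())
  } else {
    counts <- stats::aggregate(species ~ key + cell_x + cell_y, data = df,
                               FUN = length)
    ctr <- behrmann_unproject((counts$cell_x + 0.5) * cell_km,
                              (counts$cell_y + 0.5) * cell_km)
    out <- data.frame(cell_x = counts$cell_x, cell_y = counts$cell_y,
                      center_lat = ctr$lat, center_lon = ctr$lon,
                      richness = as.integer(counts$species))
    out <- out[order(out$cell_x, out$cell_y), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "cell_km") <- cell_km
  class(out) <- c("richness_grid", "data.frame")
  out
}

#' Per-cell richness difference
#'
#' `raw - filtered`, over the union of occupied cells (absent cells count
#' as 0). Requires both grids to use the same cell size.
#'
#' @param raw,filtered `richness_grid`s from [richness()].
#' @return data frame `cell_x`, `cell_y`, `center_lat`, `center_lon`,
#'   `raw`, `filtered`, `difference`.
#' @export
richness_difference <- function(raw, filtered) {
  if (!identical(attr(raw, "cell_km"), attr(filtered, "cell_km")))
    stop("richness grids use different cell sizes", call. = FALSE)
  cell_km <- attr(raw, "cell_km")
  key <- function(g) paste(g$cell_x, g$cell_y, sep = ":")
  all_keys <- union(key(raw), key(filtered))
  r <- structure(raw$richness, names = key(raw))
  f <- structure(filtered$richness, names = key(filtered))
  rv <- ifelse(all_keys %in% names(r), r[all_keys], 0L)
  fv <- ifelse(all_keys %in% names(f), f[all_keys], 0L)
  xy <- do.call(rbind, strsplit(all_keys, ":", fixed = TRUE))
  cx <- as.integer(xy[, 1L]); cy <- as.integer(xy[, 2L])
  ctr <- behrmann_unproject((cx + 0.5) * cell_km, (cy + 0.5) * cell_km)
  out <- data.frame(cell_x = cx, cell_y = cy,
                    center_lat = ctr$lat, center_lon = ctr$lon,
                    raw = as.integer(rv), filtered = as.integer(fv),
                    difference = as.integer(rv - fv))
  out <- out[order(out$cell_x, out$cell_y), , drop = FALSE]
  rownames(out) <- NULL
  out
}
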