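# Automated preliminary IUCN Criterion B assessment.
#
# Per species: EOO (area of the convex hull of all records, km^2), AOO
# (occupied 2x2 km equal-area cells x 4 km^2), number of locations
# (occupied 10x10 km cells, a grid proxy for the threat-defined IUCN
# concept), and the resulting preliminary category. Category thresholds are
# the IUCN Criterion B guideline constants and live in configuration.

#' IUCN Criterion B thresholds
#'
#' Guideline constants: a species qualifies at a level under B1 when its EOO
#' is below the level's EOO threshold, or under B2 when its AOO is below the
#' AOO threshold, in either case together with a sufficiently small number
#' of locations. AOO is measured on a 2-km grid, locations on a 10-km grid.
#'
#' @param eoo_km2,aoo_km2,locations named numeric vectors with elements
#'   `CR`, `EN`, `VU` (strictly increasing severity thresholds).
#' @param aoo_cell_km,locations_cell_km grid cell sides in km.
#' @return a `criterion_b_thresholds` object.
#' @export
criterion_b_thresholds <- function(
    eoo_km2 = c(CR = 100, EN = 5000, VU = 20000),
    aoo_km2 = c(CR = 10, EN = 500, VU = 2000),
    locations = c(CR = 1, EN = 5, VU = 10),
    aoo_cell_km = 2, locations_cell_km = 10) {
  for (v in list(eoo_km2, aoo_km2, locations))
    stopifnot(all(c("CR", "EN", "VU") %in% names(v)),
              v[["CR"]] < v[["EN"]], v[["EN"]] < v[["VU"]])
  structure(list(eoo_km2 = eoo_km2, aoo_km2 = aoo_km2, locations = locations,
                 aoo_cell_km = aoo_cell_km,
                 locations_cell_km = locations_cell_km),
            class = "criterion_b_thresholds")
}

# Spherical polygon area (km^2) by the line-integral method on the sphere:
# sum over edges of (lam2 - lam1) * (2 + sin(phi1) + sin(phi2)) * R^2 / 2.
# Exact for edges along parallels and meridians; for short hull edges the
# deviation from the strict geodesic polygon is negligible at study scale.
spherical_polygon_area <- function(lat, lon) {
  n <- length(lat)
  if (n < 3L) return(0)
  rad <- pi / 180
  phi <- lat * rad; lam <- lon * rad
  phi2 <- c(phi[-1L], phi[1L]); lam2 <- c(lam[-1L], lam[1L])
  s <- sum((lam2 - lam) * (2 + sin(phi) + sin(phi2))) / 2
  abs(s) * EARTH_RADIUS_KM^2
}

#' Extent of occurrence (EOO)
#'
#' Area of the convex hull comprising all records of a species. The hull is
#' taken in the equal-area projection; its area is then computed as a
#' spherical polygon over the hull vertices. Fewer than 3 unique,
#' non-collinear points give an undefined EOO (`NA`).
#'
#' @param lat,lon decimal degrees; duplicated points are allowed.
#' @return area in km^2, or `NA_real_` when undefined.
#' @export
compute_eoo <- function(lat, lon) {
  pts <- unique(cbind(lon, lat))
  if (nrow(pts) < 3L) return(NA_real_)
  p <- behrmann_project(pts[, 2L], pts[, 1L])
  hull <- grDevices::chull(p$x, p$y)
  if (length(hull) < 3L) return(NA_real_)
  # collinear points: planar hull area ~ 0 relative to its extent
  hx <- p$x[hull]; hy <- p$y[hull]
  planar <- abs(sum(hx * c(hy[-1L], hy[1L]) - c(hx[-1L], hx[1L]) * hy)) / 2
  scale2 <- (diff(range(hx))^2 + diff(range(hy))^2)
  if (planar <= 1e-12 * max(scale2, 1)) return(NA_real_)
  spherical_polygon_area(pts[hull, 2L], pts[hull, 1L])
}

#' Area of occupancy (AOO)
#'
#' Number of occupied cells of the small-scale equal-area grid (default
#' 2 x 2 km, anchored like the richness grid) times the cell area.
#'
#' @param lat,lon decimal degrees.
#' @param thresholds a [criterion_b_thresholds()] (supplies the cell size).
#' @return area in km^2 (a multiple of the cell area; 0 only for no points).
#' @export
compute_aoo <- function(lat, lon, thresholds = criterion_b_thresholds()) {
  s <- thresholds$aoo_cell_km
  cells <- assign_cell(lat, lon, s)
  nrow(unique(cells)) * s^2
}

#' Number of locations (grid proxy)
#'
#' Count of occupied coarse equal-area cells (default 10 x 10 km). This is
#' the common grid approximation of the IUCN "locations" concept; true
#' locations are threat-defined and out of scope.
#'
#' @inheritParams compute_aoo
#' @return integer count.
#' @export
count_locations <- function(lat, lon, thresholds = criterion_b_thresholds()) {
  cells <- assign_cell(lat, lon, thresholds$locations_cell_km)
  nrow(unique(cells))
}

category_severity <- c(CR = 3L, EN = 2L, VU = 1L, NT_proxy = 0L)

#' Preliminary Criterion B category
#'
#' B1 assigns the most severe level at which `eoo < ` the EOO threshold and
#' `n_locations <= ` the locations threshold; B2 does the same with AOO.
#' The final category is the more severe of B1 and B2; if neither applies
#' the species is `NT_proxy` (not-threatened proxy, deliberately conflating
#' NT and LC). An undefined EOO (`NA`) restricts the assessment to B2.
#'
#' @param eoo km^2 or `NA`.
#' @param aoo km^2.
#' @param n_locations integer.
#' @param thresholds a [criterion_b_thresholds()].
#' @return one of `"CR"`, `"EN"`, `"VU"`, `"NT_proxy"`.
#' @export
assess_criterion_b <- function(eoo, aoo, n_locations,
                               thresholds = criterion_b_thresholds()) {
  best <- "NT_proxy"
  for (level in c("CR", "EN", "VU")) {
    loc_ok <- n_locations <= thresholds$locations[[level]]
    b1 <- !is.na(eoo) && eoo < thresholds$eoo_km2[[level]] && loc_ok
    b2 <- aoo < thresholds$aoo_km2[[level]] && loc_ok
    if (b1 || b2) { best <- level; break }
  }
  best
}

#' Assess every species in a data set
#'
#' @param records data frame of occurrence records (any number of species).
#' @param thresholds a [criterion_b_thresholds()].
#' @return data frame, one row per species with >= 1 record: `species`,
#'   `n_records`, `eoo_km2` (`NA` when undefined), `aoo_km2`,
#'   `n_locations`, `category`; sorted by species.
#' @export
assess_all <- function(records, thresholds = criterion_b_thresholds()) {
  species <- sort(unique(records$species))
  rows <- lapply(species, function(sp) {
    idx <- records$species == sp
    lat <- records$latitude[idx]; lon <- records$longitude[idx]
    eoo <- compute_eoo(lat, lon)
    aoo <- compute_aoo(lat, lon, thresholds)
    nloc <- count_locations(lat, lon, thresholds)
    data.frame(species = sp, n_records = sum(idx), eoo_km2 = eoo,
               aoo_km2 = aoo, n_locations = nloc,
               category = assess_criterion_b(eoo, aoo, nloc, thresholds),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(species = character(), n_records = integer(),
               eoo_km2 = numeric(), aoo_km2 = numeric(),
               n_locations = integer(), category = character())
  rownames(out) <- NULL
  out
}

#' Collapse categories to threatened / not threatened
#'
#' CR, EN and VU are threatened; `NT_proxy`, NT and LC are not; DD and NE
#' are `NA` (excluded from agreement comparisons rather than counted as
#' not threatened).
#'
#' @param category character vector of category tokens.
#' @return logical vector (`NA` for DD/NE).
#' @export
binarize_threatened <- function(category) {
  ifelse(category %in% c("CR", "EN", "VU"), TRUE,
         ifelse(category %in% c("NT_proxy", "NT", "LC"), FALSE, NA))
}

#' Agreement between automated and reference assessments
#'
#' Joins on the exact species string, drops species whose reference category
#' is DD or NE, and reports the percentage of species where the automated
#' and reference assessments agree on threatened (CR/EN/VU) versus not.
#'
#' @param auto data frame from [assess_all()].
#' @param ref data frame with columns `species`, `category` (reference, e.g.
#'   from [read_reference_assessments()]).
#' @return list: `n_overlap` (species in both), `n_compared` (after DD/NE
#'   exclusion), `n_match`, `match_pct` (`NA` when nothing comparable),
#'   `auto_category_counts`, `ref_category_counts`, and the per-species
#'   `detail` data frame.
#' @export
compare_with_reference <- function(auto, ref) {
  m <- merge(auto[, c("species", "category")], ref, by = "species",
             suffixes = c("_auto", "_ref"))
  detail <- data.frame(species = m$species,
                       category_auto = m$category_auto,
                       category_ref = m$category_ref,
                       threatened_auto = binarize_threatened(m$category_auto),
                       threatened_ref = binarize_threatened(m$category_ref),
                       stringsAsFactors = FALSE)
  comparable <- !is.na(detail$threatened_ref) & !is.na(detail$threatened_auto)
  n_match <- sum(detail$threatened_auto[comparable] ==
                   detail$threatened_ref[comparable])
  list(n_overlap = nrow(detail),
       n_compared = sum(comparable),
       n_match = n_match,
       match_pct = if (sum(comparable) == 0L) NA_real_ else
         100 * n_match / sum(comparable),
       auto_category_counts = table(detail$category_auto),
       ref_category_counts = table(detail$category_ref),
       detail = detail)
}

#' Per-group median range change after filtering
#'
#' For each species present in both assessments, the percentage change
#' `100 * (filtered - raw) / raw` of EOO and of AOO; then the median across
#' species within each group. Species with an undefined EOO in either data
#' set are excluded from the EOO median (but kept for AOO).
#'
#' @param raw,filtered data frames from [assess_all()] on the raw and the
#'   filtered records.
#' @param groups named character vector mapping species to group labels (or
#'   `NULL` for a single overall group).
#' @return data frame: `group`, `n_species`, `median_eoo_change_pct`,
#'   `median_aoo_change_pct`.
#' @export
range_change <- function(raw, filtered, groups = NULL) {
  m <- merge(raw, filtered, by = "species", suffixes = c("_raw", "_filt"))
  if (is.null(groups)) grp <- rep("all", nrow(m))
  else grp <- unname(groups[m$species])
  eoo_chg <- 100 * (m$eoo_km2_filt - m$eoo_km2_raw) / m$eoo_km2_raw
  aoo_chg <- 100 * (m$aoo_km2_filt - m$aoo_km2_raw) / m$aoo_km2_raw
  out <- do.call(rbind, lapply(sort(unique(grp)), function(g) {
    idx <- grp == g
    data.frame(group = g, n_species = sum(idx),
               median_eoo_change_pct =
                 stats::median(eoo_chg[idx], na.rm = TRUE),
               median_aoo_change_pct =
                 stats::median(aoo_chg[idx], na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
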