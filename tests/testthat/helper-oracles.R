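# Independent oracles and small fixture builders shared across tests.

# Winding-number point-in-polygon via summed subtended angles: inside iff
# the total angle around the point is ~ +/- 2*pi. Independent of the
# package's even-odd ray-casting implementation. Boundary points are not
# well-defined here; callers use random (interior/exterior) points.
oracle_point_in_polygon <- function(lon, lat, ring) {
  vx <- ring[, 1L] - lon
  vy <- ring[, 2L] - lat
  n <- nrow(ring)
  total <- 0
  for (j in seq_len(n - 1L)) {
    x1 <- vx[j]; y1 <- vy[j]; x2 <- vx[j + 1L]; y2 <- vy[j + 1L]
    total <- total + atan2(x1 * y2 - y1 * x2, x1 * x2 + y1 * y2)
  }
  abs(total) > pi
}

oracle_point_in_layer <- function(lon, lat, layer) {
  for (f in layer$features) {
    hits <- vapply(f$rings, function(r)
      oracle_point_in_polygon(lon, lat, r), logical(1))
    # even-odd over rings: outer minus holes
    if (sum(hits) %% 2L == 1L) return(TRUE)
  }
  FALSE
}

# Direct-comparison Criterion B oracle: evaluate B1 and B2 separately at
# each level, then return the more severe of the two.
oracle_criterion_b <- function(eoo, aoo, nloc, th = criterion_b_thresholds()) {
  sev <- c(NT_proxy = 0L, VU = 1L, EN = 2L, CR = 3L)
  level_of <- function(metric, limits) {
    out <- "NT_proxy"
    for (lv in c("VU", "EN", "CR"))  # ascending severity; keep the last hit
      if (!is.na(metric) && metric < limits[[lv]] &&
          nloc <= th$locations[[lv]])
        out <- lv
    out
  }
  b1 <- level_of(eoo, th$eoo_km2)
  b2 <- level_of(aoo, th$aoo_km2)
  names(sev)[match(max(sev[[b1]], sev[[b2]]), sev)]
}

# minimal record builder with clean defaults
mk_records <- function(lat, lon, species = "Aus bus", group = "g1",
                       id = NULL, year = 2000L, basis = "preserved_specimen",
                       count = 1L, rank = "species", uncertainty = NA_real_) {
  n <- length(lat)
  data.frame(
    record_id = if (is.null(id)) sprintf("r%04d", seq_len(n)) else id,
    species = rep_len(species, n), group_id = rep_len(group, n),
    latitude = lat, longitude = lon,
    coordinate_uncertainty_m = rep_len(uncertainty, n),
    basis_of_record = rep_len(basis, n), year = rep_len(year, n),
    individual_count = rep_len(count, n), taxon_rank = rep_len(rank, n),
    stringsAsFactors = FALSE)
}

# single-rectangle world: one land square with an urban square and one of
# each point feature, for hand-built filter scenarios
mk_mini_gazetteer <- function(capital_in_urban = FALSE) {
  ring <- function(lon0, lon1, lat0, lat1)
    cbind(lon = c(lon0, lon1, lon1, lon0, lon0),
          lat = c(lat0, lat0, lat1, lat1, lat0))
  cap <- if (capital_in_urban) c(10.5, 10.5) else c(5, 15)
  gazetteer(
    land = gaz_polygon_layer("land", list(ring(0, 20, 0, 20))),
    urban = gaz_polygon_layer("urban", list(ring(10, 11, 10, 11))),
    country_centroids = gaz_point_layer("country_centroids",
                                        data.frame(lon = 3, lat = 3)),
    province_centroids = gaz_point_layer("province_centroids",
                                         data.frame(lon = 17, lat = 3)),
    capitals = gaz_point_layer("capitals",
                               data.frame(lon = cap[1], lat = cap[2])),
    institutions = gaz_point_layer("institutions",
                                   data.frame(lon = 3, lat = 17)))
}

toy_realms <- function() {
  stats::setNames(c(rep("terrestrial", 4L), "marine"),
                  sprintf("group%02d", 1:5))
}
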