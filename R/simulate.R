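# Synthetic study system: a deterministic toy gazetteer world and
# occurrence data sets with planted, labelled contamination.
#
# The generator plants exactly one issue per contaminated record and keeps
# clean records away from every test trigger by a separation margin, so the
# ground truth is unambiguous and a correct filter recovers it exactly.

# Fixed toy world geometry (decimal degrees). One continental land rectangle
# inside the simulation window, two country halves, and per country one
# centroid, capital, institution and urban polygon, plus two province
# centroids. All reference points are pairwise hundreds of km apart, none is
# near the lat/lon diagonals or the origin, and (0, 0) lies on land, so a
# record planted on one trigger is flagged by that test alone.
toy_world <- list(
  window = c(min_lat = -30, max_lat = 30, min_lon = -40, max_lon = 40),
  land = c(min_lat = -22, max_lat = 22, min_lon = -30, max_lon = 30),
  country_centroids = data.frame(
    name = c("Westland", "Eastland"), lon = c(-15, 15), lat = c(-10, 9)),
  capitals = data.frame(
    name = c("West City", "East City"), lon = c(-25, 25), lat = c(5, -5)),
  institutions = data.frame(
    name = c("West Herbarium", "East Museum"), lon = c(-5, 5),
    lat = c(-18, 18)),
  province_centroids = data.frame(
    name = c("West South", "West North", "East South", "East North"),
    lon = c(-22, -8, 20, 28), lat = c(-15, 15, -16, 18)),
  urban = list(
    c(min_lat = 8, max_lat = 10, min_lon = -12, max_lon = -10),
    c(min_lat = -13, max_lat = -11, min_lon = 7, max_lon = 9)),
  urban_names = c("West Town", "East Town"),
  # rectangles of open sea inside the window, used for marine species ranges
  sea_bands = list(
    c(min_lat = 23, max_lat = 29.5, min_lon = -39, max_lon = 39),
    c(min_lat = -29.5, max_lat = -23, min_lon = -39, max_lon = 39),
    c(min_lat = -29, max_lat = 29, min_lon = 31, max_lon = 39.5),
    c(min_lat = -29, max_lat = 29, min_lon = -39.5, max_lon = -31))
)

rect_ring <- function(r) {
  m <- rbind(c(r[["min_lon"]], r[["min_lat"]]),
             c(r[["max_lon"]], r[["min_lat"]]),
             c(r[["max_lon"]], r[["max_lat"]]),
             c(r[["min_lon"]], r[["max_lat"]]),
             c(r[["min_lon"]], r[["min_lat"]]))
  colnames(m) <- c("lon", "lat")
  m
}

# geodesic area of a lat/lon-aligned rectangle on the authalic sphere
rect_area_km2 <- function(r) {
  rad <- pi / 180
  EARTH_RADIUS_KM^2 * (r[["max_lon"]] - r[["min_lon"]]) * rad *
    (sin(r[["max_lat"]] * rad) - sin(r[["min_lat"]] * rad))
}

#' Build the toy gazetteer world
#'
#' Deterministic: the layout is fixed, so identical calls (any seed) produce
#' identical layers. One continental land rectangle inside the simulation
#' window, two countries, and per country a centroid, a capital, a
#' biodiversity institution and an urban polygon, plus four province
#' centroids; everything else in the window is sea.
#'
#' @param seed ignored (kept so all generator entry points share a
#'   signature); the world is constant.
#' @return a [gazetteer()].
#' @export
make_toy_gazetteer <- function(seed = NULL) {
  w <- toy_world
  gazetteer(
    land = gaz_polygon_layer("land", list(rect_ring(w$land)), "Mainland"),
    country_centroids = gaz_point_layer("country_centroids",
                                        w$country_centroids),
    province_centroids = gaz_point_layer("province_centroids",
                                         w$province_centroids),
    capitals = gaz_point_layer("capitals", w$capitals),
    urban = gaz_polygon_layer("urban", lapply(w$urban, rect_ring),
                              w$urban_names),
    institutions = gaz_point_layer("institutions", w$institutions)
  )
}

plantable_issues <- c("zeros", "equal_latlon", "realm_mismatch",
                      "country_centroid", "province_centroid", "capital",
                      "urban", "institution", "year", "basis", "count",
                      "id_level", "precision", "duplicate")

# issues whose planted coordinates sit on land reference features; planting
# them in a marine group would collaterally trip the realm test
land_anchored_issues <- c("zeros", "country_centroid", "province_centroid",
                          "capital", "urban", "institution")

#' Specification of a synthetic occurrence data set
#'
#' Defaults emulate the shape of a multi-taxon aggregator download: several
#' study groups of terrestrial or marine realm, log-normally skewed records
#' per species (median 10, heavy tail), and a small contamination rate per
#' issue type.
#'
#' @param seed integer RNG seed.
#' @param n_groups number of study groups.
#' @param realms character vector of length `n_groups`
#'   (`"terrestrial"`/`"marine"`).
#' @param n_species species per group.
#' @param records_per_species list with `meanlog`, `sdlog`, `max`: records
#'   per species are `rlnorm(meanlog, sdlog)` rounded, clamped to
#'   \[1, max\].
#' @param contamination named numeric vector of per-issue planting rates
#'   (tokens from the quality tests); rates must sum to <= 1.
#' @param margin_km separation margin clean records keep from every point
#'   feature; must exceed the largest test buffer (default 30 km = 3 x the
#'   10 km capital buffer).
#' @return a `simulation_spec` object.
#' @export
simulation_spec <- function(seed = 1L,
                            n_groups = 5L,
                            realms = c(rep("terrestrial", 4L), "marine"),
                            n_species = 20L,
                            records_per_species = list(
                              meanlog = log(10),
                              sdlog = sqrt(2 * log(10)),
                              max = 2000L),
                            contamination = stats::setNames(
                              rep(0.03, length(plantable_issues)),
                              plantable_issues),
                            margin_km = 30) {
  realms <- rep_len(realms, n_groups)
  stopifnot(all(realms %in% c("terrestrial", "marine")),
            all(contamination >= 0), sum(contamination) <= 1,
            all(names(contamination) %in% plantable_issues),
            margin_km > 10)
  structure(list(seed = as.integer(seed), n_groups = as.integer(n_groups),
                 realms = realms, n_species = as.integer(n_species),
                 records_per_species = records_per_species,
                 contamination = contamination, margin_km = margin_km),
            class = "simulation_spec")
}

# all gazetteer reference points as one table (for margin checks)
all_gaz_points <- function(gaz) {
  pts <- lapply(c("country_centroids", "province_centroids", "capitals",
                  "institutions"), function(nm) gaz[[nm]]$features)
  do.call(rbind, pts)
}

# Vectorized clean-location predicate: TRUE where a point could be a clean
# record of the given realm (margin from every point feature, outside urban,
# right side of the coast, away from the origin box and the diagonals).
is_clean_location <- function(lat, lon, realm, gaz, margin_km,
                              pts = all_gaz_points(gaz)) {
  w <- toy_world$window
  ok <- lat >= w[["min_lat"]] & lat <= w[["max_lat"]] &
    lon >= w[["min_lon"]] & lon <= w[["max_lon"]]
  on_land <- point_in_layer(lat, lon, gaz$land)
  ok <- ok & if (realm == "terrestrial") on_land else !on_land
  ok <- ok & !point_in_layer(lat, lon, gaz$urban)
  near <- near_any_point(lat, lon,
                         gaz_point_layer("all", pts), margin_km)
  ok <- ok & !near
  ok <- ok & !(abs(lat) <= 0.55 & abs(lon) <= 0.55)
  ok & abs(lat - lon) > 0.01 & abs(lat + lon) > 0.01
}

round_key <- function(lat, lon, decimals = 4L) {
  paste(sprintf("%.*f", decimals, round(lat, decimals) + 0),
        sprintf("%.*f", decimals, round(lon, decimals) + 0), sep = ":")
}

# Rejection-sample n clean locations inside rect for the given realm,
# avoiding rounded-coordinate keys in `used`. Errors when the margin leaves
# no clean area.
sample_clean_points <- function(n, rect, realm, gaz, margin_km, used,
                                max_tries = 200L) {
  out_lat <- numeric(0); out_lon <- numeric(0)
  tries <- 0L
  while (length(out_lat) < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("separation margin leaves no clean area in range rectangle ",
           "(infeasible simulation spec)", call. = FALSE)
    m <- max(2L * (n - length(out_lat)), 16L)
    lat <- stats::runif(m, rect[["min_lat"]], rect[["max_lat"]])
    lon <- stats::runif(m, rect[["min_lon"]], rect[["max_lon"]])
    keep <- is_clean_location(lat, lon, realm, gaz, margin_km)
    lat <- lat[keep]; lon <- lon[keep]
    if (!length(lat)) next
    keys <- round_key(lat, lon)
    fresh <- !(keys %in% used) & !duplicated(keys)
    lat <- lat[fresh]; lon <- lon[fresh]; keys <- keys[fresh]
    take <- seq_len(min(length(lat), n - length(out_lat)))
    out_lat <- c(out_lat, lat[take]); out_lon <- c(out_lon, lon[take])
    used <- c(used, keys[take])
  }
  list(lat = out_lat, lon = out_lon, used = used)
}

# sample a random species range rectangle for a realm
sample_range_rect <- function(realm) {
  if (realm == "terrestrial") {
    base <- toy_world$land
    base <- c(min_lat = base[["min_lat"]] + 0.2,
              max_lat = base[["max_lat"]] - 0.2,
              min_lon = base[["min_lon"]] + 0.2,
              max_lon = base[["max_lon"]] - 0.2)
  } else {
    base <- toy_world$sea_bands[[sample.int(length(toy_world$sea_bands), 1L)]]
  }
  wlat <- stats::runif(1, 3, min(14, base[["max_lat"]] - base[["min_lat"]]))
  wlon <- stats::runif(1, 3, min(14, base[["max_lon"]] - base[["min_lon"]]))
  lat0 <- stats::runif(1, base[["min_lat"]], base[["max_lat"]] - wlat)
  lon0 <- stats::runif(1, base[["min_lon"]], base[["max_lon"]] - wlon)
  c(min_lat = lat0, max_lat = lat0 + wlat,
    min_lon = lon0, max_lon = lon0 + wlon)
}

clean_metadata <- function(n) {
  unc <- ifelse(stats::runif(n) < 0.7, NA_real_,
                stats::runif(n, 100, 50000))
  data.frame(
    coordinate_uncertainty_m = unc,
    basis_of_record = sample(setdiff(basis_levels,
                                     c("fossil_specimen", "unknown")),
                             n, replace = TRUE),
    year = sample(1950:2020, n, replace = TRUE),
    individual_count = sample(1:50, n, replace = TRUE),
    taxon_rank = rep("species", n),
    stringsAsFactors = FALSE)
}

# sample one coordinate pair along the lat/lon diagonal that is clean apart
# from the equality itself
sample_equal_latlon <- function(realm, gaz, margin_km, used) {
  for (i in 1:500) {
    t <- stats::runif(1, -29.3, 29.3)
    sgn <- sample(c(1, -1), 1L)
    lat <- t; lon <- sgn * t
    if (abs(lat) <= 0.55) next
    w <- toy_world$window
    on_land <- point_in_layer(lat, lon, gaz$land)
    if (on_land != (realm == "terrestrial")) next
    if (point_in_layer(lat, lon, gaz$urban)) next
    if (near_any_point(lat, lon, gaz_point_layer("all", all_gaz_points(gaz)),
                       margin_km)) next
    if (round_key(lat, lon) %in% used) next
    return(c(lat = lat, lon = lon))
  }
  stop("could not place an equal-lat/lon plant", call. = FALSE)
}

# sample one point in the opposite realm that trips only the realm test
sample_realm_swap <- function(realm, gaz, margin_km, used) {
  target <- if (realm == "terrestrial") "marine" else "terrestrial"
  w <- toy_world$window
  for (i in 1:500) {
    lat <- stats::runif(1, w[["min_lat"]], w[["max_lat"]])
    lon <- stats::runif(1, w[["min_lon"]], w[["max_lon"]])
    ok <- is_clean_location(lat, lon, target, gaz, margin_km)
    if (ok && !(round_key(lat, lon) %in% used))
      return(c(lat = lat, lon = lon))
  }
  stop("could not place a realm-swap plant", call. = FALSE)
}

# sample one point inside an urban polygon, away from diagonals/duplicates
sample_urban_point <- function(gaz, used) {
  for (i in 1:500) {
    r <- toy_world$urban[[sample.int(length(toy_world$urban), 1L)]]
    lat <- stats::runif(1, r[["min_lat"]], r[["max_lat"]])
    lon <- stats::runif(1, r[["min_lon"]], r[["max_lon"]])
    if (abs(lat - lon) <= 0.01 || abs(lat + lon) <= 0.01) next
    if (round_key(lat, lon) %in% used) next
    return(c(lat = lat, lon = lon))
  }
  stop("could not place an urban plant", call. = FALSE)
}

#' Simulate an occurrence data set with planted contamination
#'
#' Each species gets a random rectangular range on land (terrestrial groups)
#' or open sea (marine groups); clean records are sampled uniformly within
#' the range, keeping the separation margin from every gazetteer point,
#' staying outside urban areas and off the test triggers, and pairwise
#' distinct after coordinate rounding. Each contaminated record carries
#' exactly one issue, planted by its transform (coordinates moved onto a
#' trigger, or one meta-data field spoiled). Land-anchored plants (zeros,
#' centroids, capitals, institutions, urban) are only used in terrestrial
#' groups; in marine groups their contamination mass falls back to clean.
#'
#' @param spec a [simulation_spec()].
#' @param gaz the toy [gazetteer()] from [make_toy_gazetteer()].
#' @param seed RNG seed (defaults to `spec$seed`).
#' @return list with `records` (occurrence data frame), `truth` (data frame
#'   `record_id`, `issue`, `NA` for clean), and `ranges` (per species: the
#'   true range rectangle and its geodesic area in km^2).
#' @export
simulate_occurrences <- function(spec, gaz = make_toy_gazetteer(),
                                 seed = spec$seed) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(seed)
  rates <- spec$contamination
  tokens <- names(rates)
  rec_rows <- list(); truth_rows <- list(); range_rows <- list()
  next_id <- 1L
  new_ids <- function(n) {
    ids <- sprintf("r%08d", seq.int(next_id, length.out = n))
    next_id <<- next_id + n
    ids
  }
  for (g in seq_len(spec$n_groups)) {
    grp <- sprintf("group%02d", g)
    realm <- spec$realms[g]
    eligible <- tokens
    if (realm == "marine")
      eligible <- setdiff(eligible, land_anchored_issues)
    for (s in seq_len(spec$n_species)) {
      sp <- sprintf("Species %s_%03d", grp, s)
      rp <- spec$records_per_species
      n_i <- min(max(1L, as.integer(round(stats::rlnorm(1, rp$meanlog,
                                                        rp$sdlog)))),
                 as.integer(rp$max))
      # one issue (or clean) per record slot
      u <- stats::runif(n_i)
      cum <- cumsum(rates[tokens])
      issue <- rep(NA_character_, n_i)
      for (k in seq_along(tokens)) {
        lo <- if (k == 1L) 0 else cum[k - 1L]
        issue[u >= lo & u < cum[k]] <- tokens[k]
      }
      issue[!(issue %in% eligible)] <- NA_character_
      # guards that keep ground truth unambiguous
      if (sum(issue == "zeros", na.rm = TRUE) > 1L) {
        extra <- which(issue == "zeros")[-1L]
        issue[extra] <- NA_character_
      }
      for (tk in c("country_centroid", "province_centroid", "capital",
                   "institution")) {
        lyr <- switch(tk, country_centroid = "country_centroids",
                      province_centroid = "province_centroids",
                      capital = "capitals", institution = "institutions")
        avail <- gaz_n_features(gaz[[lyr]])
        hits <- which(issue == tk)
        if (length(hits) > avail)
          issue[hits[-seq_len(avail)]] <- NA_character_
      }
      if (all(issue == "duplicate", na.rm = TRUE) &&
          sum(is.na(issue)) == 0L)
        issue[1L] <- NA_character_  # a duplicate needs a clean original
      rect <- sample_range_rect(realm)
      range_rows[[length(range_rows) + 1L]] <- data.frame(
        species = sp, group_id = grp, realm = realm,
        min_lat = rect[["min_lat"]], max_lat = rect[["max_lat"]],
        min_lon = rect[["min_lon"]], max_lon = rect[["max_lon"]],
        area_km2 = rect_area_km2(rect), stringsAsFactors = FALSE)

      used <- character(0)
      # clean coordinates for clean slots and meta-data-issue slots
      meta_issues <- c("year", "basis", "count", "id_level", "precision")
      coord_clean <- which(is.na(issue) | issue %in% meta_issues)
      cp <- sample_clean_points(length(coord_clean), rect, realm, gaz,
                                spec$margin_km, used)
      used <- cp$used
      lat <- rep(NA_real_, n_i); lon <- rep(NA_real_, n_i)
      lat[coord_clean] <- cp$lat; lon[coord_clean] <- cp$lon
      md <- clean_metadata(n_i)
      # per-layer point pools for copy plants
      pools <- list(
        country_centroid = gaz$country_centroids$features,
        province_centroid = gaz$province_centroids$features,
        capital = gaz$capitals$features,
        institution = gaz$institutions$features)
      pool_next <- c(country_centroid = 1L, province_centroid = 1L,
                     capital = 1L, institution = 1L)
      dup_of <- rep(NA_integer_, n_i)
      for (i in seq_len(n_i)) {
        tk <- issue[i]
        if (is.na(tk) || tk %in% meta_issues) next
        if (tk == "zeros") {
          lat[i] <- 0; lon[i] <- 0
        } else if (tk == "equal_latlon") {
          p <- sample_equal_latlon(realm, gaz, spec$margin_km, used)
          lat[i] <- p[["lat"]]; lon[i] <- p[["lon"]]
          used <- c(used, round_key(lat[i], lon[i]))
        } else if (tk == "realm_mismatch") {
          p <- sample_realm_swap(realm, gaz, spec$margin_km, used)
          lat[i] <- p[["lat"]]; lon[i] <- p[["lon"]]
          used <- c(used, round_key(lat[i], lon[i]))
        } else if (tk %in% names(pools)) {
          j <- pool_next[[tk]]
          pool_next[[tk]] <- j + 1L
          lat[i] <- pools[[tk]]$lat[j]; lon[i] <- pools[[tk]]$lon[j]
          used <- c(used, round_key(lat[i], lon[i]))
        } else if (tk == "urban") {
          p <- sample_urban_point(gaz, used)
          lat[i] <- p[["lat"]]; lon[i] <- p[["lon"]]
          used <- c(used, round_key(lat[i], lon[i]))
        } else if (tk == "duplicate") {
          originals <- which(is.na(issue))
          if (!length(originals)) {
            # no clean original to copy: the slot reverts to clean
            issue[i] <- NA_character_
            cpx <- sample_clean_points(1L, rect, realm, gaz,
                                       spec$margin_km, used)
            lat[i] <- cpx$lat; lon[i] <- cpx$lon; used <- cpx$used
          } else {
            dup_of[i] <- originals[sample.int(length(originals), 1L)]
          }
        }
      }
      # meta-data plants
      for (i in which(!is.na(issue) & issue %in% meta_issues)) {
        tk <- issue[i]
        if (tk == "year") md$year[i] <- sample(1600:1944, 1L)
        else if (tk == "basis")
          md$basis_of_record[i] <- sample(c("fossil_specimen", "unknown"), 1L)
        else if (tk == "count")
          md$individual_count[i] <- sample(c(0L, 150L), 1L)
        else if (tk == "id_level")
          md$taxon_rank[i] <- sample(c("genus", "unranked"), 1L)
        else if (tk == "precision")
          md$coordinate_uncertainty_m[i] <- stats::runif(1, 150000, 500000)
      }
      # duplicate plants last: ids of copies must sort after the original's
      is_dup <- !is.na(dup_of)
      ord <- c(which(!is_dup), which(is_dup))
      ids <- character(n_i)
      ids[ord] <- new_ids(n_i)
      for (i in which(is_dup)) {
        j <- dup_of[i]
        lat[i] <- lat[j]; lon[i] <- lon[j]
        md[i, ] <- md[j, ]
      }
      # slot that lost its issue to a missing original stays clean
      rec_rows[[length(rec_rows) + 1L]] <- data.frame(
        record_id = ids, species = sp, group_id = grp,
        latitude = lat, longitude = lon,
        coordinate_uncertainty_m = md$coordinate_uncertainty_m,
        basis_of_record = md$basis_of_record, year = md$year,
        individual_count = md$individual_count,
        taxon_rank = md$taxon_rank, stringsAsFactors = FALSE)
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        record_id = ids, issue = issue, stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, rec_rows)
  truth <- do.call(rbind, truth_rows)
  ranges <- do.call(rbind, range_rows)
  ord <- order(records$record_id)
  records <- records[ord, , drop = FALSE]
  truth <- truth[order(truth$record_id), , drop = FALSE]
  rownames(records) <- rownames(truth) <- rownames(ranges) <- NULL
  list(records = records, truth = truth, ranges = ranges)
}

#' Score a flag report against planted ground truth
#'
#' Per test: sensitivity = flagged-and-planted / planted, specificity =
#' unflagged-and-unplanted / unplanted. A test with no planted records has
#' undefined sensitivity (`NA`).
#'
#' @param report a [run_filters()] report.
#' @param truth the `truth` data frame from [simulate_occurrences()].
#' @return data frame: `test`, `n_planted`, `n_flagged`, `sensitivity`,
#'   `specificity`.
#' @export
score_against_truth <- function(report, truth) {
  stopifnot(identical(sort(report$record_id), sort(truth$record_id)))
  truth <- truth[match(report$record_id, truth$record_id), , drop = FALSE]
  out <- do.call(rbind, lapply(filter_test_tokens, function(tk) {
    planted <- !is.na(truth$issue) & truth$issue == tk
    flagged <- report[[tk]]
    data.frame(
      test = tk, n_planted = sum(planted), n_flagged = sum(flagged),
      sensitivity = if (sum(planted) == 0L) NA_real_ else
        sum(flagged & planted) / sum(planted),
      specificity = if (sum(!planted) == 0L) NA_real_ else
        sum(!flagged & !planted) / sum(!planted),
      stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Synthetic reference assessments from ground truth
#'
#' Applies the Criterion B assessment to each species' truth-clean records
#' (the records with no planted issue) and returns the resulting categories
#' as a stand-in reference table. This is a synthetic substitute for an
#' external red list, generated from the simulation itself.
#'
#' @param records,truth output of [simulate_occurrences()].
#' @param thresholds a [criterion_b_thresholds()].
#' @return data frame `species`, `category`.
#' @export
make_reference_assessments <- function(records, truth,
                                       thresholds =
                                         criterion_b_thresholds()) {
  truth <- truth[match(records$record_id, truth$record_id), , drop = FALSE]
  clean <- records[is.na(truth$issue), , drop = FALSE]
  auto <- assess_all(clean, thresholds)
  data.frame(species = auto$species, category = auto$category,
             stringsAsFactors = FALSE)
}
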