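# Reference geometries (gazetteer layers) and the spatial predicates used by
# the geographic quality tests. All coordinates are WGS84 decimal degrees;
# distances are great-circle kilometres on a sphere of authalic radius.

#' Authalic earth radius in kilometres
#'
#' Radius of the sphere with the same surface area as the WGS84 ellipsoid.
#' Used for every distance, projection and area computation in the package so
#' that all spatial results share one datum model.
#' @export
EARTH_RADIUS_KM <- 6371.0088

#' Construct a polygon gazetteer layer
#'
#' @param name layer name token (e.g. `"land"`, `"urban"`).
#' @param polygons list of polygons; each polygon is a list of rings, each
#'   ring a numeric matrix with columns `lon`, `lat`. The first ring is the
#'   outer boundary, any further rings are holes. Rings must be closed
#'   (first vertex equal to last). A single matrix is accepted as shorthand
#'   for a one-ring polygon.
#' @param feature_names optional character vector of feature names.
#' @return a `gaz_layer` object of kind `"polygon"`.
#' @export
gaz_polygon_layer <- function(name, polygons = list(), feature_names = NULL) {
  features <- vector("list", length(polygons))
  for (i in seq_along(polygons)) {
    poly <- polygons[[i]]
    if (is.matrix(poly)) poly <- list(poly)
    rings <- lapply(seq_along(poly), function(j) {
      ring <- poly[[j]]
      ring <- as.matrix(ring)
      storage.mode(ring) <- "double"
      if (ncol(ring) != 2L || nrow(ring) < 4L)
        stop("layer '", name, "', feature ", i, ", ring ", j,
             ": a polygon ring needs >= 4 lon/lat positions", call. = FALSE)
      if (ring[1L, 1L] != ring[nrow(ring), 1L] ||
          ring[1L, 2L] != ring[nrow(ring), 2L])
        stop("layer '", name, "', feature ", i, ", ring ", j,
             ": ring is not closed (first vertex != last)", call. = FALSE)
      if (diff(range(ring[, 1L])) > 180)
        stop("layer '", name, "', feature ", i,
             ": features spanning more than 180 degrees of longitude ",
             "(antimeridian crossing) are unsupported", call. = FALSE)
      colnames(ring) <- c("lon", "lat")
      ring
    })
    outer <- rings[[1L]]
    features[[i]] <- list(
      name = if (!is.null(feature_names)) feature_names[[i]] else NA_character_,
      rings = rings,
      bbox = c(lon_min = min(outer[, 1L]), lon_max = max(outer[, 1L]),
               lat_min = min(outer[, 2L]), lat_max = max(outer[, 2L]))
    )
  }
  structure(list(name = name, kind = "polygon", features = features),
            class = "gaz_layer")
}

#' Construct a point gazetteer layer
#'
#' @param name layer name token (e.g. `"capitals"`).
#' @param points data frame or matrix with columns `lon`, `lat` (and
#'   optionally `name`); may have zero rows.
#' @return a `gaz_layer` object of kind `"point"`.
#' @export
gaz_point_layer <- function(name, points = NULL) {
  if (is.null(points) || NROW(points) == 0L) {
    pts <- data.frame(name = character(), lon = numeric(), lat = numeric())
  } else {
    points <- as.data.frame(points)
    if (!all(c("lon", "lat") %in% names(points)))
      stop("point layer '", name, "' needs 'lon' and 'lat' columns",
           call. = FALSE)
    pts <- data.frame(
      name = if ("name" %in% names(points)) as.character(points$name)
             else rep(NA_character_, nrow(points)),
      lon = as.numeric(points$lon), lat = as.numeric(points$lat)
    )
  }
  structure(list(name = name, kind = "point", features = pts),
            class = "gaz_layer")
}

#' Number of features in a gazetteer layer
#' @param layer a `gaz_layer`.
#' @return integer feature count.
#' @export
gaz_n_features <- function(layer) {
  if (layer$kind == "point") nrow(layer$features) else length(layer$features)
}

gaz_layer_names <- c("land", "country_centroids", "province_centroids",
                     "capitals", "urban", "institutions")
gaz_layer_kinds <- c(land = "polygon", country_centroids = "point",
                     province_centroids = "point", capitals = "point",
                     urban = "polygon", institutions = "point")

#' Assemble a gazetteer from layers
#'
#' A gazetteer bundles the six reference layers the geographic tests use:
#' land polygons, country/province centroid points, capital points, urban
#' polygons and biodiversity-institution points. Any layer may be omitted;
#' the corresponding test then flags nothing (with a warning at test time).
#'
#' @param land,urban polygon `gaz_layer`s (or `NULL` for empty).
#' @param country_centroids,province_centroids,capitals,institutions point
#'   `gaz_layer`s (or `NULL` for empty).
#' @return a `gazetteer` object (named list of six `gaz_layer`s).
#' @export
gazetteer <- function(land = NULL, country_centroids = NULL,
                      province_centroids = NULL, capitals = NULL,
                      urban = NULL, institutions = NULL) {
  supplied <- list(land = land, country_centroids = country_centroids,
                   province_centroids = province_centroids,
                   capitals = capitals, urban = urban,
                   institutions = institutions)
  layers <- lapply(gaz_layer_names, function(nm) {
    lyr <- supplied[[nm]]
    if (is.null(lyr)) {
      if (gaz_layer_kinds[[nm]] == "polygon") gaz_polygon_layer(nm)
      else gaz_point_layer(nm)
    } else {
      stopifnot(inherits(lyr, "gaz_layer"))
      if (lyr$kind != gaz_layer_kinds[[nm]])
        stop("layer '", nm, "' must be of kind '", gaz_layer_kinds[[nm]], "'",
             call. = FALSE)
      lyr$name <- nm
      lyr
    }
  })
  names(layers) <- gaz_layer_names
  structure(layers, class = "gazetteer")
}

#' @export
print.gazetteer <- function(x, ...) {
  cat("<gazetteer>\n")
  for (nm in names(x))
    cat(sprintf("  %-18s %-7s %d feature(s)\n", nm, x[[nm]]$kind,
                gaz_n_features(x[[nm]])))
  invisible(x)
}

# ---- GeoJSON I/O -----------------------------------------------------------

geojson_coords_matrix <- function(coords) {
  m <- do.call(rbind, lapply(coords, function(p) c(p[[1L]], p[[2L]])))
  storage.mode(m) <- "double"
  colnames(m) <- c("lon", "lat")
  m
}

#' Read one gazetteer layer from a GeoJSON file
#'
#' Supports `FeatureCollection`s of `Point`/`MultiPoint` (for point layers)
#' and `Polygon`/`MultiPolygon` (for polygon layers). A feature's `name`
#' property is kept when present.
#'
#' @param path path to a GeoJSON (RFC 7946) file.
#' @param name layer name token.
#' @param kind `"polygon"` or `"point"`.
#' @return a `gaz_layer`.
#' @export
read_geojson_layer <- function(path, name, kind = c("polygon", "point")) {
  kind <- match.arg(kind)
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$type) || gj$type != "FeatureCollection")
    stop("'", path, "': expected a GeoJSON FeatureCollection", call. = FALSE)
  polys <- list(); poly_names <- character()
  pts <- list()
  for (k in seq_along(gj$features)) {
    feat <- gj$features[[k]]
    geom <- feat$geometry
    fname <- feat$properties$name
    fname <- if (is.null(fname)) NA_character_ else as.character(fname)
    gtype <- geom$type
    if (kind == "point") {
      if (gtype == "Point") {
        pts[[length(pts) + 1L]] <- data.frame(
          name = fname, lon = geom$coordinates[[1L]],
          lat = geom$coordinates[[2L]])
      } else if (gtype == "MultiPoint") {
        m <- geojson_coords_matrix(geom$coordinates)
        pts[[length(pts) + 1L]] <- data.frame(
          name = fname, lon = m[, 1L], lat = m[, 2L])
      } else {
        stop("'", path, "', feature ", k, ": geometry type '", gtype,
             "' not allowed in point layer '", name, "'", call. = FALSE)
      }
    } else {
      if (gtype == "Polygon") {
        polys[[length(polys) + 1L]] <-
          lapply(geom$coordinates, geojson_coords_matrix)
        poly_names <- c(poly_names, fname)
      } else if (gtype == "MultiPolygon") {
        for (pg in geom$coordinates) {
          polys[[length(polys) + 1L]] <- lapply(pg, geojson_coords_matrix)
          poly_names <- c(poly_names, fname)
        }
      } else {
        stop("'", path, "', feature ", k, ": geometry type '", gtype,
             "' not allowed in polygon layer '", name, "'", call. = FALSE)
      }
    }
  }
  if (kind == "point")
    gaz_point_layer(name, if (length(pts)) do.call(rbind, pts) else NULL)
  else
    tryCatch(gaz_polygon_layer(name, polys, poly_names),
             error = function(e) stop("'", path, "': ", conditionMessage(e),
                                      call. = FALSE))
}

#' Load a gazetteer from GeoJSON files
#'
#' @param land,country_centroids,province_centroids,capitals,urban,institutions
#'   paths to GeoJSON files, or `NULL` / missing file for an empty layer
#'   (a warning is emitted per missing layer).
#' @param quiet suppress missing-layer warnings.
#' @return a `gazetteer`.
#' @export
load_gazetteer <- function(land = NULL, country_centroids = NULL,
                           province_centroids = NULL, capitals = NULL,
                           urban = NULL, institutions = NULL, quiet = FALSE) {
  paths <- list(land = land, country_centroids = country_centroids,
                province_centroids = province_centroids, capitals = capitals,
                urban = urban, institutions = institutions)
  layers <- list()
  for (nm in gaz_layer_names) {
    p <- paths[[nm]]
    if (is.null(p) || !file.exists(p)) {
      if (!quiet)
        warning("gazetteer layer '", nm, "' not supplied; its test will ",
                "flag nothing", call. = FALSE)
      layers[[nm]] <- NULL
    } else {
      layers[[nm]] <- read_geojson_layer(p, nm, gaz_layer_kinds[[nm]])
    }
  }
  do.call(gazetteer, layers)
}

#' Write a gazetteer to GeoJSON files
#'
#' Writes one `<layer>.geojson` per non-empty layer. Output is deterministic
#' for identical input (fixed number formatting, no timestamps).
#'
#' @param gaz a `gazetteer`.
#' @param dir output directory (created if needed).
#' @return invisibly, named character vector of written paths.
#' @export
write_gazetteer <- function(gaz, dir) {
  stopifnot(inherits(gaz, "gazetteer"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  for (nm in names(gaz)) {
    lyr <- gaz[[nm]]
    if (gaz_n_features(lyr) == 0L) next
    if (lyr$kind == "point") {
      feats <- lapply(seq_len(nrow(lyr$features)), function(i) {
        list(type = "Feature",
             properties = list(name = lyr$features$name[i]),
             geometry = list(type = "Point",
                             coordinates = c(lyr$features$lon[i],
                                             lyr$features$lat[i])))
      })
    } else {
      feats <- lapply(lyr$features, function(f) {
        list(type = "Feature",
             properties = list(name = f$name),
             geometry = list(
               type = "Polygon",
               coordinates = lapply(f$rings, function(r)
                 lapply(seq_len(nrow(r)), function(i) c(r[i, 1L], r[i, 2L])))))
      })
    }
    fc <- list(type = "FeatureCollection", features = feats)
    path <- file.path(dir, paste0(nm, ".geojson"))
    jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA,
                         pretty = FALSE, na = "null")
    written[nm] <- path
  }
  invisible(written)
}

# ---- spatial predicates ----------------------------------------------------

# Even-odd ray casting for one closed ring, vectorized over points.
# Boundary points (on an edge or vertex) are handled by the caller.
point_in_ring <- function(lon, lat, ring) {
  inside <- rep(FALSE, length(lon))
  n <- nrow(ring)
  x <- ring[, 1L]; y <- ring[, 2L]
  for (j in seq_len(n - 1L)) {
    x1 <- x[j]; y1 <- y[j]; x2 <- x[j + 1L]; y2 <- y[j + 1L]
    crosses <- ((y1 > lat) != (y2 > lat))
    if (any(crosses)) {
      xi <- x1 + (lat[crosses] - y1) / (y2 - y1) * (x2 - x1)
      hit <- lon[crosses] < xi
      idx <- which(crosses)[hit]
      inside[idx] <- !inside[idx]
    }
  }
  inside
}

# TRUE where (lon, lat) lies on a segment of the ring (within eps degrees,
# used only to honour the boundary-counts-as-inside convention).
point_on_ring <- function(lon, lat, ring, eps = 1e-12) {
  on <- rep(FALSE, length(lon))
  n <- nrow(ring)
  x <- ring[, 1L]; y <- ring[, 2L]
  for (j in seq_len(n - 1L)) {
    x1 <- x[j]; y1 <- y[j]; x2 <- x[j + 1L]; y2 <- y[j + 1L]
    dx <- x2 - x1; dy <- y2 - y1
    cross <- (lon - x1) * dy - (lat - y1) * dx
    len2 <- dx * dx + dy * dy
    if (len2 == 0) {
      cand <- abs(lon - x1) <= eps & abs(lat - y1) <= eps
    } else {
      t <- ((lon - x1) * dx + (lat - y1) * dy) / len2
      cand <- abs(cross) <= eps * sqrt(len2) & t >= -eps & t <= 1 + eps
    }
    on <- on | cand
  }
  on
}

#' Test whether points fall inside a polygon layer
#'
#' Even-odd ray casting with a bounding-box prefilter per feature. A point on
#' a feature boundary counts as inside (coastal records are legitimate). Holes
#' are honoured: a point inside a hole ring is outside the feature.
#'
#' @param lat,lon numeric vectors of equal length, decimal degrees.
#' @param layer a polygon `gaz_layer`.
#' @param use_index use the bounding-box prefilter (result is identical with
#'   and without it; `FALSE` exists for verification).
#' @return logical vector, `TRUE` where the point is inside or on the
#'   boundary of any feature.
#' @export
point_in_layer <- function(lat, lon, layer, use_index = TRUE) {
  stopifnot(inherits(layer, "gaz_layer"), layer$kind == "polygon",
            length(lat) == length(lon))
  inside <- rep(FALSE, length(lat))
  for (f in layer$features) {
    todo <- which(!inside)
    if (!length(todo)) break
    if (use_index) {
      bb <- f$bbox
      todo <- todo[lon[todo] >= bb[["lon_min"]] & lon[todo] <= bb[["lon_max"]] &
                   lat[todo] >= bb[["lat_min"]] & lat[todo] <= bb[["lat_max"]]]
      if (!length(todo)) next
    }
    lo <- lon[todo]; la <- lat[todo]
    crossings <- rep(0L, length(todo))
    on_boundary <- rep(FALSE, length(todo))
    for (ring in f$rings) {
      crossings <- crossings + point_in_ring(lo, la, ring)
      on_boundary <- on_boundary | point_on_ring(lo, la, ring)
    }
    inside[todo] <- inside[todo] | (crossings %% 2L == 1L) | on_boundary
  }
  inside
}

#' Great-circle distance in kilometres
#'
#' Haversine distance on the authalic sphere (radius 6371.0088 km).
#' Vectorized; arguments are recycled.
#'
#' @param lat1,lon1,lat2,lon2 decimal degrees.
#' @return distance(s) in kilometres.
#' @export
geodesic_distance <- function(lat1, lon1, lat2, lon2) {
  rad <- pi / 180
  phi1 <- lat1 * rad; phi2 <- lat2 * rad
  dphi <- (lat2 - lat1) * rad
  dlam <- (lon2 - lon1) * rad
  a <- sin(dphi / 2)^2 + cos(phi1) * cos(phi2) * sin(dlam / 2)^2
  a <- pmin(pmax(a, 0), 1)
  2 * EARTH_RADIUS_KM * asin(sqrt(a))
}

#' Test whether points lie within a radius of any layer point
#'
#' @param lat,lon numeric vectors, decimal degrees.
#' @param layer a point `gaz_layer`.
#' @param radius_km buffer radius in kilometres (> 0); a distance exactly
#'   equal to the radius counts as near.
#' @return logical vector; all `FALSE` when the layer is empty.
#' @export
near_any_point <- function(lat, lon, layer, radius_km) {
  stopifnot(inherits(layer, "gaz_layer"), layer$kind == "point",
            radius_km > 0, length(lat) == length(lon))
  out <- rep(FALSE, length(lat))
  if (nrow(layer$features) == 0L) return(out)
  # coarse degree-box prefilter, then exact haversine
  deg <- radius_km / 111.0 * 1.5
  for (i in seq_len(nrow(layer$features))) {
    plon <- layer$features$lon[i]; plat <- layer$features$lat[i]
    todo <- which(!out & abs(lat - plat) <= deg &
                    (abs(lon - plon) <= deg / max(cos(plat * pi / 180), 1e-6)))
    if (!length(todo)) next
    d <- geodesic_distance(lat[todo], lon[todo], plat, plon)
    out[todo[d <= radius_km]] <- TRUE
  }
  out
}
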