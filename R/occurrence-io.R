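# Occurrence-record data model and delimited-text I/O.
#
# Records are kept in a plain data frame with one row per record and the
# canonical columns below. Numeric meta-data that is absent is NA, never a
# sentinel value; coordinates are stored at full input precision (rounding
# happens only inside the duplicate test).

occ_columns <- c("record_id", "species", "group_id", "latitude", "longitude",
                 "coordinate_uncertainty_m", "basis_of_record", "year",
                 "individual_count", "taxon_rank")

basis_levels <- c("preserved_specimen", "human_observation", "fossil_specimen",
                  "material_sample", "living_specimen", "machine_observation",
                  "unknown")

rank_levels <- c("species", "infraspecific", "genus", "family", "unranked")

#' Column mapping and delimiter for occurrence files
#'
#' Defaults follow Darwin-Core-style GBIF download headers.
#'
#' @param delim field delimiter (`","` or `"\t"`).
#' @param record_id,species,group_id,latitude,longitude,coordinate_uncertainty_m,basis_of_record,year,individual_count,taxon_rank
#'   column names in the file for each canonical field.
#' @return a named list used by [read_occurrences()] / [write_occurrences()].
#' @export
occ_dialect <- function(delim = ",",
                        record_id = "recordID",
                        species = "species",
                        group_id = "groupID",
                        latitude = "decimalLatitude",
                        longitude = "decimalLongitude",
                        coordinate_uncertainty_m = "coordinateUncertaintyInMeters",
                        basis_of_record = "basisOfRecord",
                        year = "year",
                        individual_count = "individualCount",
                        taxon_rank = "taxonRank") {
  list(delim = delim,
       columns = c(record_id = record_id, species = species,
                   group_id = group_id, latitude = latitude,
                   longitude = longitude,
                   coordinate_uncertainty_m = coordinate_uncertainty_m,
                   basis_of_record = basis_of_record, year = year,
                   individual_count = individual_count,
                   taxon_rank = taxon_rank))
}

#' Normalize basis-of-record tokens
#'
#' Maps GBIF-style uppercase tokens and free text onto the package
#' enumeration; unmappable or missing values become `"unknown"`.
#'
#' @param x character vector.
#' @return character vector of enumeration tokens.
#' @export
normalize_basis <- function(x) {
  key <- gsub("[^a-z]", "", tolower(trimws(as.character(x))))
  map <- c(preservedspecimen = "preserved_specimen",
           humanobservation = "human_observation",
           observation = "human_observation",
           fossilspecimen = "fossil_specimen",
           fossil = "fossil_specimen",
           materialsample = "material_sample",
           materialcitation = "material_sample",
           livingspecimen = "living_specimen",
           machineobservation = "machine_observation",
           unknown = "unknown")
  out <- unname(map[key])
  out[is.na(out)] <- "unknown"
  out[is.na(x) | key == ""] <- "unknown"
  out
}

#' Normalize taxon-rank tokens
#'
#' `species` and infraspecific ranks (subspecies, variety, form) pass the
#' identification-level test; genus, family and coarser ranks, and missing
#' values, do not.
#'
#' @param x character vector.
#' @return character vector of enumeration tokens.
#' @export
normalize_rank <- function(x) {
  key <- gsub("[^a-z]", "", tolower(trimws(as.character(x))))
  map <- c(species = "species",
           subspecies = "infraspecific", variety = "infraspecific",
           form = "infraspecific", infraspecificname = "infraspecific",
           infraspecies = "infraspecific",
           genus = "genus",
           family = "family", order = "family", class = "family",
           phylum = "family", kingdom = "family",
           unranked = "unranked")
  out <- unname(map[key])
  out[is.na(out)] <- "unranked"
  out[is.na(x) | key == ""] <- "unranked"
  out
}

parse_num <- function(x) suppressWarnings(as.numeric(x))
parse_int <- function(x) {
  v <- suppressWarnings(as.numeric(x))
  ifelse(is.finite(v), as.integer(round(v)), NA_integer_)
}

#' Read occurrence records from delimited text
#'
#' Rows whose coordinates cannot be parsed or fall outside latitude
#' \[-90, 90\] / longitude \[-180, 180\] are dropped and counted in the
#' ingestion log; all other fields are absent-tolerant. Coordinates are kept
#' at full input precision.
#'
#' @param path path to a delimited text file with a header row.
#' @param dialect column mapping from [occ_dialect()].
#' @return data frame of records with canonical columns; the ingestion log
#'   (`n_read`, `n_dropped`, `dropped_ids`) is attached as attribute
#'   `"ingestion"` and readable with [ingestion_log()].
#' @export
read_occurrences <- function(path, dialect = occ_dialect()) {
  stopifnot(file.exists(path))
  raw <- utils::read.table(path, header = TRUE, sep = dialect$delim,
                           colClasses = "character", quote = "\"",
                           na.strings = c("", "NA"), check.names = FALSE,
                           stringsAsFactors = FALSE)
  required <- c("species", "latitude", "longitude")
  for (fld in required) {
    col <- dialect$columns[[fld]]
    if (!col %in% names(raw))
      stop("required column '", col, "' (", fld, ") missing in ", path,
           call. = FALSE)
  }
  get_col <- function(fld) {
    col <- dialect$columns[[fld]]
    if (col %in% names(raw)) raw[[col]] else rep(NA_character_, nrow(raw))
  }
  lat <- parse_num(get_col("latitude"))
  lon <- parse_num(get_col("longitude"))
  ok <- is.finite(lat) & is.finite(lon) & lat >= -90 & lat <= 90 &
    lon >= -180 & lon <= 180
  ids <- get_col("record_id")
  if (all(is.na(ids)))
    ids <- sprintf("rec%06d", seq_len(nrow(raw)))
  rec <- data.frame(
    record_id = as.character(ids),
    species = as.character(get_col("species")),
    group_id = as.character(get_col("group_id")),
    latitude = lat, longitude = lon,
    coordinate_uncertainty_m = parse_num(get_col("coordinate_uncertainty_m")),
    basis_of_record = as.character(get_col("basis_of_record")),
    year = parse_int(get_col("year")),
    individual_count = parse_int(get_col("individual_count")),
    taxon_rank = as.character(get_col("taxon_rank")),
    stringsAsFactors = FALSE
  )
  dropped_ids <- rec$record_id[!ok]
  rec <- rec[ok, , drop = FALSE]
  rownames(rec) <- NULL
  if (anyDuplicated(rec$record_id))
    stop("duplicate record_id values in ", path, call. = FALSE)
  if (any(is.na(rec$species) | rec$species == ""))
    stop("empty species name in ", path, call. = FALSE)
  attr(rec, "ingestion") <- list(n_read = length(ok),
                                 n_dropped = sum(!ok),
                                 dropped_ids = dropped_ids)
  rec
}

#' Ingestion log of a read data set
#' @param records data frame returned by [read_occurrences()].
#' @return list with `n_read`, `n_dropped`, `dropped_ids` (or `NULL`).
#' @export
ingestion_log <- function(records) attr(records, "ingestion")

#' Write occurrence records to delimited text
#'
#' Inverse of [read_occurrences()]: re-reading a written file reproduces
#' every field, including absent values (written as empty cells).
#'
#' @param records data frame with canonical columns.
#' @param path output path.
#' @param dialect column mapping from [occ_dialect()].
#' @return invisibly, `path`.
#' @export
write_occurrences <- function(records, path, dialect = occ_dialect()) {
  stopifnot(is.data.frame(records))
  out <- data.frame(
    a = records$record_id, b = records$species, c = records$group_id,
    d = format_coord(records$latitude), e = format_coord(records$longitude),
    f = format_num(records$coordinate_uncertainty_m),
    g = records$basis_of_record, h = records$year, i = records$individual_count,
    j = records$taxon_rank, stringsAsFactors = FALSE, check.names = FALSE)
  names(out) <- unname(dialect$columns[occ_columns])
  utils::write.table(out, path, sep = dialect$delim, na = "", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# full-precision, locale-independent numeric formatting
format_coord <- function(x) {
  out <- vapply(x, function(v)
    if (is.na(v)) NA_character_ else format(v, digits = 15, scientific = FALSE),
    character(1))
  out
}
format_num <- format_coord

#' Rectangular study window
#'
#' @param min_lat,max_lat,min_lon,max_lon decimal degrees, `min < max`.
#' @return a `study_window` object.
#' @export
study_window <- function(min_lat, max_lat, min_lon, max_lon) {
  stopifnot(min_lat < max_lat, min_lon < max_lon,
            min_lat >= -90, max_lat <= 90, min_lon >= -180, max_lon <= 180)
  structure(list(min_lat = min_lat, max_lat = max_lat,
                 min_lon = min_lon, max_lon = max_lon),
            class = "study_window")
}

#' Split records by a study window
#'
#' Membership uses closed intervals on both axes (boundary points are kept
#' inside), so `inside` and `outside` always partition the input.
#'
#' @param records data frame of occurrence records.
#' @param window a [study_window()].
#' @return list with elements `inside` and `outside`.
#' @export
apply_study_window <- function(records, window) {
  stopifnot(inherits(window, "study_window"))
  keep <- records$latitude >= window$min_lat &
    records$latitude <= window$max_lat &
    records$longitude >= window$min_lon &
    records$longitude <= window$max_lon
  list(inside = records[keep, , drop = FALSE],
       outside = records[!keep, , drop = FALSE])
}

iucn_categories <- c("CR", "EN", "VU", "NT", "LC", "DD", "NE")

#' Normalize IUCN category tokens
#'
#' Accepts two-letter codes in any case and full category names
#' (e.g. `"endangered"`); unknown tokens map to `"NE"` with a warning.
#'
#' @param x character vector.
#' @return character vector of category codes.
#' @export
normalize_category <- function(x) {
  key <- gsub("[^a-z]", "", tolower(trimws(as.character(x))))
  map <- c(cr = "CR", criticallyendangered = "CR",
           en = "EN", endangered = "EN",
           vu = "VU", vulnerable = "VU",
           nt = "NT", nearthreatened = "NT", lrnt = "NT",
           lc = "LC", leastconcern = "LC", lrlc = "LC",
           dd = "DD", datadeficient = "DD",
           ne = "NE", notevaluated = "NE")
  out <- unname(map[key])
  bad <- is.na(out)
  if (any(bad)) {
    warning("unknown category token(s) mapped to NE: ",
            paste(unique(x[bad]), collapse = ", "), call. = FALSE)
    out[bad] <- "NE"
  }
  out
}

#' Read reference conservation assessments
#'
#' Two-column delimited text: species and IUCN category. Category tokens are
#' normalized with [normalize_category()].
#'
#' @param path file path.
#' @param species_col,category_col column names.
#' @param delim field delimiter.
#' @return data frame with columns `species`, `category`, one row per
#'   species; conflicting duplicate species are an error.
#' @export
read_reference_assessments <- function(path, species_col = "species",
                                       category_col = "category",
                                       delim = ",") {
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           colClasses = "character", quote = "\"",
                           na.strings = c("", "NA"), check.names = FALSE,
                           stringsAsFactors = FALSE)
  for (col in c(species_col, category_col))
    if (!col %in% names(raw))
      stop("required column '", col, "' missing in ", path, call. = FALSE)
  ref <- data.frame(species = raw[[species_col]],
                    category = normalize_category(raw[[category_col]]),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(ref$species)) {
    n_cat <- tapply(ref$category, ref$species, function(z) length(unique(z)))
    if (any(n_cat > 1))
      stop("conflicting categories for species: ",
           paste(names(n_cat)[n_cat > 1], collapse = ", "), call. = FALSE)
    ref <- ref[!duplicated(ref$species), , drop = FALSE]
  }
  rownames(ref) <- NULL
  ref
}
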