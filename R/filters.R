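# The quality tests applied to occurrence records, their erroneous/unfit
# classification, and Table-style per-group summaries.
#
# Meta-data tests: basis, year, precision, count, id_level.
# Coordinate/gazetteer tests: duplicate, zeros, equal_latlon, realm_mismatch,
#   country_centroid, province_centroid, capital, urban, institution.
# All tests are evaluated on every record (the summary denominators are group
# totals); the removal set is the union of all flags, so apart from the fixed
# duplicate-keeper rule the outcome is order-independent.

filter_test_tokens <- c("basis", "year", "precision", "count", "id_level",
                        "duplicate", "zeros", "equal_latlon", "realm_mismatch",
                        "country_centroid", "province_centroid", "capital",
                        "urban", "institution")

# Classification of each test: a record hit by an "error" test has likely
# wrong coordinates; one hit only by "unfit" tests is too imprecise or
# unsuitable for most downstream analyses.
default_test_classes <- c(
  basis = "unfit", year = "unfit", precision = "unfit", count = "unfit",
  id_level = "unfit", duplicate = "unfit", zeros = "error",
  equal_latlon = "error", realm_mismatch = "error",
  country_centroid = "unfit", province_centroid = "unfit",
  capital = "unfit", urban = "unfit", institution = "error")

#' Configuration of the record quality tests
#'
#' Defaults: records collected before 1945 are flagged (old coordinates are
#' typically derived from imprecise locality descriptions); coordinate
#' uncertainty strictly greater than 100 km is flagged (the grain of many
#' macro-ecological analyses); individual counts outside \[1, 99\] are
#' flagged; fossil and unknown-source records are flagged; duplicates are
#' detected per species after rounding coordinates to 4 decimal places;
#' country and province centroids use a conservative 1 km radius, capitals
#' 10 km, biodiversity institutions 100 m; plain-zero coordinates use a 0.5
#' degree box.
#'
#' @param min_year flag records with `year <` this (default 1945).
#' @param max_uncertainty_km flag records with coordinate uncertainty
#'   strictly greater than this, in km (default 100).
#' @param min_count,max_count inclusive individual-count bounds kept
#'   (default 1, 99).
#' @param allowed_bases basis-of-record tokens kept (default: all except
#'   `fossil_specimen` and `unknown`).
#' @param dup_decimals decimal places coordinates are rounded to before
#'   duplicate detection (default 4).
#' @param centroid_radius_km buffer around country and province centroids
#'   (default 1).
#' @param capital_radius_km buffer around capitals (default 10).
#' @param institution_radius_km buffer around biodiversity institutions
#'   (default 0.1).
#' @param zero_tolerance_deg half-width in degrees of the box around (0, 0)
#'   caught by the zeros test (default 0.5).
#' @param equal_tolerance_deg tolerance for the equal-latitude/longitude
#'   test (default 1e-9).
#' @param flag_equal_sign_flip also flag `lat == -lon` (default `TRUE`; the
#'   sign-flipped variant is the same data-entry slip with a sign error).
#' @param realms named character vector mapping each `group_id` to
#'   `"terrestrial"` or `"marine"`; required when the realm test is enabled.
#' @param enabled_tests subset of test tokens to run (default all).
#' @param test_classes named character vector mapping each test token to
#'   `"error"` or `"unfit"`; classification is configuration, not code.
#' @return a `filter_config` object.
#' @export
filter_config <- function(min_year = 1945L,
                          max_uncertainty_km = 100,
                          min_count = 1L, max_count = 99L,
                          allowed_bases = setdiff(basis_levels,
                                                  c("fossil_specimen",
                                                    "unknown")),
                          dup_decimals = 4L,
                          centroid_radius_km = 1,
                          capital_radius_km = 10,
                          institution_radius_km = 0.1,
                          zero_tolerance_deg = 0.5,
                          equal_tolerance_deg = 1e-9,
                          flag_equal_sign_flip = TRUE,
                          realms = character(),
                          enabled_tests = filter_test_tokens,
                          test_classes = default_test_classes) {
  stopifnot(min_count <= max_count, dup_decimals >= 0,
            centroid_radius_km > 0, capital_radius_km > 0,
            institution_radius_km > 0,
            all(enabled_tests %in% filter_test_tokens),
            all(filter_test_tokens %in% names(test_classes)),
            all(test_classes %in% c("error", "unfit")))
  structure(list(min_year = as.integer(min_year),
                 max_uncertainty_km = max_uncertainty_km,
                 min_count = as.integer(min_count),
                 max_count = as.integer(max_count),
                 allowed_bases = allowed_bases,
                 dup_decimals = as.integer(dup_decimals),
                 centroid_radius_km = centroid_radius_km,
                 capital_radius_km = capital_radius_km,
                 institution_radius_km = institution_radius_km,
                 zero_tolerance_deg = zero_tolerance_deg,
                 equal_tolerance_deg = equal_tolerance_deg,
                 flag_equal_sign_flip = isTRUE(flag_equal_sign_flip),
                 realms = realms,
                 enabled_tests = enabled_tests,
                 test_classes = test_classes),
            class = "filter_config")
}

# ---- meta-data tests -------------------------------------------------------

#' @rdname record_tests
#' @export
flag_basis_of_record <- function(records, config = filter_config()) {
  basis <- normalize_basis(records$basis_of_record)
  !(basis %in% config$allowed_bases)
}

#' @rdname record_tests
#' @export
flag_collection_year <- function(records, config = filter_config()) {
  yr <- records$year
  !is.na(yr) & yr < config$min_year
}

#' @rdname record_tests
#' @export
flag_coordinate_precision <- function(records, config = filter_config()) {
  unc_km <- records$coordinate_uncertainty_m / 1000
  !is.na(unc_km) & unc_km > config$max_uncertainty_km
}

#' @rdname record_tests
#' @export
flag_individual_count <- function(records, config = filter_config()) {
  n <- records$individual_count
  !is.na(n) & (n < config$min_count | n > config$max_count)
}

#' @rdname record_tests
#' @export
flag_identification_level <- function(records, config = filter_config()) {
  rank <- normalize_rank(records$taxon_rank)
  !(rank %in% c("species", "infraspecific"))
}

# ---- coordinate tests ------------------------------------------------------

#' Record quality tests
#'
#' Each `flag_*` function evaluates one quality test for every record and
#' returns a logical vector (`TRUE` = flagged). Absent meta-data never flags
#' a record, with one exception: a missing basis of record counts as unknown
#' source and is flagged. See [filter_config()] for thresholds and
#' [run_filters()] to evaluate all tests at once.
#'
#' @param records data frame of occurrence records (see
#'   [read_occurrences()]).
#' @param config a [filter_config()].
#' @param gazetteer a [gazetteer()] (gazetteer-based tests only).
#' @param layer a point `gaz_layer` ([flag_near_points()] only).
#' @param radius_km buffer radius in km ([flag_near_points()] only).
#' @return logical vector, one element per record.
#' @name record_tests
NULL

#' @rdname record_tests
#' @export
flag_duplicates <- function(records, config = filter_config()) {
  # round first and fold -0 to +0 so "-0.0000" and "0.0000" share a key
  rlat <- round(records$latitude, config$dup_decimals) + 0
  rlon <- round(records$longitude, config$dup_decimals) + 0
  key <- paste(records$species,
               sprintf("%.*f", config$dup_decimals, rlat),
               sprintf("%.*f", config$dup_decimals, rlon),
               sep = "\r")
  # keeper = smallest record_id (lexicographic) within each key group
  ord <- order(key, records$record_id, method = "radix")
  flagged_sorted <- duplicated(key[ord])
  flagged <- logical(nrow(records))
  flagged[ord] <- flagged_sorted
  flagged
}

#' @rdname record_tests
#' @export
flag_zeros <- function(records, config = filter_config()) {
  abs(records$latitude) <= config$zero_tolerance_deg &
    abs(records$longitude) <= config$zero_tolerance_deg
}

#' @rdname record_tests
#' @export
flag_equal_latlon <- function(records, config = filter_config()) {
  tol <- config$equal_tolerance_deg
  eq <- abs(records$latitude - records$longitude) <= tol
  if (config$flag_equal_sign_flip)
    eq <- eq | abs(records$latitude + records$longitude) <= tol
  eq & !(records$latitude == 0 & records$longitude == 0)
}

#' @rdname record_tests
#' @export
flag_realm_mismatch <- function(records, config, gazetteer) {
  realm <- unname(config$realms[records$group_id])
  if (any(is.na(realm)))
    stop("no realm configured for group(s): ",
         paste(unique(records$group_id[is.na(realm)]), collapse = ", "),
         call. = FALSE)
  stopifnot(all(realm %in% c("terrestrial", "marine")))
  on_land <- point_in_layer(records$latitude, records$longitude,
                            gazetteer$land)
  ifelse(realm == "terrestrial", !on_land, on_land)
}

#' @rdname record_tests
#' @export
flag_near_points <- function(records, layer, radius_km) {
  near_any_point(records$latitude, records$longitude, layer, radius_km)
}

#' @rdname record_tests
#' @export
flag_urban <- function(records, gazetteer) {
  point_in_layer(records$latitude, records$longitude, gazetteer$urban)
}

# ---- orchestration ---------------------------------------------------------

#' Run all enabled quality tests
#'
#' Evaluates every enabled test on every record and derives the
#' classification: `erroneous` (hit by at least one error-class test),
#' `unfit` (hit by at least one unfit-class test), `clean` (no flags).
#' A record can be both erroneous and unfit. Gazetteer tests whose layer is
#' empty flag nothing and warn.
#'
#' @param records data frame of occurrence records.
#' @param config a [filter_config()]; `config$realms` must cover every
#'   `group_id` when the realm test is enabled.
#' @param gazetteer a [gazetteer()].
#' @return a `flag_report` data frame: `record_id`, one logical column per
#'   test token, and logical `erroneous`, `unfit`, `clean`.
#' @export
run_filters <- function(records, config = filter_config(),
                        gazetteer = NULL) {
  stopifnot(inherits(config, "filter_config"))
  n <- nrow(records)
  enabled <- config$enabled_tests
  gaz_needed <- c("realm_mismatch", "country_centroid", "province_centroid",
                  "capital", "urban", "institution")
  if (is.null(gazetteer) && any(gaz_needed %in% enabled))
    stop("gazetteer required for enabled gazetteer-based tests", call. = FALSE)

  off <- function() rep(FALSE, n)
  layer_or_warn <- function(lyr_name, test) {
    lyr <- gazetteer[[lyr_name]]
    if (gaz_n_features(lyr) == 0L) {
      warning("gazetteer layer '", lyr_name, "' is empty; test '", test,
              "' flags nothing", call. = FALSE)
      NULL
    } else lyr
  }
  flags <- data.frame(record_id = records$record_id,
                      stringsAsFactors = FALSE)
  flags$basis <- if ("basis" %in% enabled)
    flag_basis_of_record(records, config) else off()
  flags$year <- if ("year" %in% enabled)
    flag_collection_year(records, config) else off()
  flags$precision <- if ("precision" %in% enabled)
    flag_coordinate_precision(records, config) else off()
  flags$count <- if ("count" %in% enabled)
    flag_individual_count(records, config) else off()
  flags$id_level <- if ("id_level" %in% enabled)
    flag_identification_level(records, config) else off()
  flags$duplicate <- if ("duplicate" %in% enabled)
    flag_duplicates(records, config) else off()
  flags$zeros <- if ("zeros" %in% enabled)
    flag_zeros(records, config) else off()
  flags$equal_latlon <- if ("equal_latlon" %in% enabled)
    flag_equal_latlon(records, config) else off()
  flags$realm_mismatch <- if ("realm_mismatch" %in% enabled && n > 0) {
    if (is.null(layer_or_warn("land", "realm_mismatch"))) off()
    else flag_realm_mismatch(records, config, gazetteer)
  } else off()
  near_or_off <- function(lyr_name, test, radius) {
    if (!(test %in% enabled) || n == 0L) return(off())
    lyr <- layer_or_warn(lyr_name, test)
    if (is.null(lyr)) off() else flag_near_points(records, lyr, radius)
  }
  flags$country_centroid <- near_or_off("country_centroids",
                                        "country_centroid",
                                        config$centroid_radius_km)
  flags$province_centroid <- near_or_off("province_centroids",
                                         "province_centroid",
                                         config$centroid_radius_km)
  flags$capital <- near_or_off("capitals", "capital",
                               config$capital_radius_km)
  flags$institution <- near_or_off("institutions", "institution",
                                   config$institution_radius_km)
  flags$urban <- if ("urban" %in% enabled && n > 0) {
    if (is.null(layer_or_warn("urban", "urban"))) off()
    else flag_urban(records, gazetteer)
  } else off()

  flags <- flags[, c("record_id", filter_test_tokens)]
  flag_mat <- as.matrix(flags[, filter_test_tokens, drop = FALSE])
  err_tests <- names(config$test_classes)[config$test_classes == "error"]
  unfit_tests <- names(config$test_classes)[config$test_classes == "unfit"]
  flags$erroneous <- rowSums(flag_mat[, err_tests, drop = FALSE]) > 0
  flags$unfit <- rowSums(flag_mat[, unfit_tests, drop = FALSE]) > 0
  flags$clean <- rowSums(flag_mat) == 0
  class(flags) <- c("flag_report", "data.frame")
  flags
}

#' Extract the clean (filtered) data set
#'
#' Returns exactly the records with no flags, with original full-precision
#' coordinates (the duplicate test's rounding never touches the data).
#'
#' @param records data frame of occurrence records.
#' @param report the matching [run_filters()] report.
#' @return data frame of clean records.
#' @export
filtered_dataset <- function(records, report) {
  stopifnot(identical(records$record_id, report$record_id))
  out <- records[report$clean, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-group flag summary
#'
#' One row per group plus a `Total` row: record count, percentage flagged by
#' any test, percentage erroneous / unfit, and percentage flagged per test.
#' Because records can be flagged by several tests, per-test percentages can
#' sum to more than the overall flagged percentage.
#'
#' @param report a [run_filters()] report.
#' @param records the matching records.
#' @param by records column to group by (default `"group_id"`).
#' @return data frame, percentages in \[0, 100\].
#' @export
summarize_flags <- function(report, records, by = "group_id") {
  stopifnot(identical(records$record_id, report$record_id))
  grp <- as.character(records[[by]])
  one <- function(idx, label) {
    n <- length(idx)
    pct <- function(v) if (n == 0L) 0 else 100 * sum(v[idx]) / n
    row <- data.frame(group = label, n_records = n,
                      pct_flagged = pct(!report$clean),
                      pct_erroneous = pct(report$erroneous),
                      pct_unfit = pct(report$unfit),
                      stringsAsFactors = FALSE)
    for (tk in filter_test_tokens)
      row[[paste0("pct_", tk)]] <- pct(report[[tk]])
    row
  }
  groups <- sort(unique(grp))
  out <- do.call(rbind, lapply(groups, function(g) one(which(grp == g), g)))
  out <- rbind(out, one(seq_len(nrow(report)), "Total"))
  rownames(out) <- NULL
  out
}
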