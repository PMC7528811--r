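cfg <- filter_config(realms = c(g1 = "terrestrial"))

test_that("meta-data tests honour thresholds and absent values", {
  rec <- mk_records(lat = 1:8 + 0.1, lon = rep(2.2, 8))

  rec$year <- c(1944L, 1945L, 1700L, NA, 2000L, 1944L, NA, 1990L)
  expect_identical(flag_collection_year(rec, cfg),
                   c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE))

  rec$coordinate_uncertainty_m <- c(150000, 100000, NA, 99999, 500000,
                                    NA, 1, 100001)
  expect_identical(flag_coordinate_precision(rec, cfg),
                   c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, TRUE))

  rec$individual_count <- c(0L, 99L, 100L, 1L, NA, -5L, 50L, 1000L)
  expect_identical(flag_individual_count(rec, cfg),
                   c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE, TRUE))

  rec$basis_of_record <- c("fossil_specimen", "preserved_specimen", NA,
                           "human_observation", "FOSSIL_SPECIMEN",
                           "machine_observation", "unknown", "gibberish")
  expect_identical(flag_basis_of_record(rec, cfg),
                   c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, TRUE))

  rec$taxon_rank <- c("unranked", "species", "subspecies", "genus", "family",
                      NA, "SPECIES", "variety")
  expect_identical(flag_identification_level(rec, cfg),
                   c(TRUE, FALSE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE))
})

test_that("duplicate detection rounds to 4 decimals per species and keeps the smallest id", {
  rec <- mk_records(lat = c(10.00001, 10.00003, 10, 10.00001),
                    lon = c(20.00004, 20.00001, 30, 20.00004),
                    species = c("a", "a", "a", "b"),
                    id = c("r2", "r1", "r3", "r4"))
  fl <- flag_duplicates(rec, cfg)
  # r1 and r2 share the rounded location; keeper is r1 (smallest id)
  expect_identical(fl, c(TRUE, FALSE, FALSE, FALSE))

  # same coordinates, different species: no duplicates
  rec2 <- mk_records(lat = c(1.5, 1.5), lon = c(2.5, 2.5),
                     species = c("a", "b"))
  expect_identical(flag_duplicates(rec2, cfg), c(FALSE, FALSE))

  # three identical records: one keeper, two flagged
  rec3 <- mk_records(lat = rep(1.5, 3), lon = rep(2.5, 3))
  expect_identical(sum(flag_duplicates(rec3, cfg)), 2L)
})

test_that("zeros and equal-lat/lon tests catch data-entry artefacts", {
  rec <- mk_records(lat = c(0, 0, 0.4, -23.5, 23.5, 10, 0.6),
                    lon = c(0, 30, -0.4, -23.5, -23.5, 20, 0))
  expect_identical(flag_zeros(rec, cfg),
                   c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE))
  # (0.4, -0.4) is both in the zeros box and an exact sign-flipped pair
  expect_identical(flag_equal_latlon(rec, cfg),
                   c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE))
  # sign-flip variant is configurable
  cfg_noflip <- filter_config(flag_equal_sign_flip = FALSE)
  expect_identical(flag_equal_latlon(rec, cfg_noflip),
                   c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE))
})

test_that("realm test flags the wrong side of the coast, boundary is land", {
  gaz <- mk_mini_gazetteer()
  rec <- mk_records(lat = c(5, 25, 0, 5), lon = c(5, 25, 0, 25),
                    group = c("t", "t", "t", "m"))
  cfg2 <- filter_config(realms = c(t = "terrestrial", m = "marine"))
  fl <- flag_realm_mismatch(rec, cfg2, gaz)
  # (5,5) on land ok; (25,25) at sea flagged; (0,0) boundary vertex is land
  expect_identical(fl, c(FALSE, TRUE, FALSE, FALSE))
  # marine record on land is flagged
  rec2 <- mk_records(lat = 5, lon = 5, group = "m")
  expect_true(flag_realm_mismatch(rec2, cfg2, gaz))
  # group without a realm errors
  rec3 <- mk_records(lat = 5, lon = 5, group = "unconfigured")
  expect_error(flag_realm_mismatch(rec3, cfg2, gaz), "unconfigured")
})

test_that("proximity tests use their per-layer radii", {
  gaz <- mk_mini_gazetteer()
  # centroid at (3,3): 0.5 km away flagged at 1 km, 2 km away is not
  near <- 3 + 0.5 / 111.195
  far <- 3 + 2 / 111.195
  rec <- mk_records(lat = c(near, far), lon = c(3, 3))
  expect_identical(flag_near_points(rec, gaz$country_centroids, 1),
                   c(TRUE, FALSE))
  # capital at (5,15), radius 10 km: 5 km away flagged
  rec2 <- mk_records(lat = 15 + 5 / 111.195, lon = 5)
  expect_true(flag_near_points(rec2, gaz$capitals, 10))
  # institution radius 0.1 km: 5 km away is not flagged
  rec3 <- mk_records(lat = 17 + 5 / 111.195, lon = 3)
  expect_false(flag_near_points(rec3, gaz$institutions, 0.1))
})

test_that("urban test flags polygon membership only", {
  gaz <- mk_mini_gazetteer()
  rec <- mk_records(lat = c(10.5, 5), lon = c(10.5, 5))
  expect_identical(flag_urban(rec, gaz), c(TRUE, FALSE))
})

test_that("run_filters derives erroneous/unfit/clean per the class table", {
  gaz <- mk_mini_gazetteer()
  cfg2 <- filter_config(realms = c(g1 = "terrestrial"))
  rec <- mk_records(lat = c(5, 5.0000001, 25, 6, 10.5),
                    lon = c(5, 5.0000001, 25, 6, 10.5),
                    id = sprintf("r%d", 1:5))
  rec$latitude[c(1, 2)] <- c(5, 5)          # exact duplicates
  rec$longitude[c(1, 2)] <- c(7, 7)
  rec$latitude[4] <- 6; rec$longitude[4] <- 8.5
  rep <- run_filters(rec, cfg2, gaz)
  # r2: duplicate only -> unfit, not erroneous
  expect_true(rep$duplicate[2] && rep$unfit[2] && !rep$erroneous[2])
  # r3: at sea (and on the lat==lon diagonal) -> erroneous
  expect_true(rep$realm_mismatch[3] && rep$erroneous[3])
  # r4: clean
  expect_true(rep$clean[4] && !rep$erroneous[4] && !rep$unfit[4])
  # r5: urban -> unfit
  expect_true(rep$urban[5] && rep$unfit[5])
  # partition: clean + flagged = all; flagged = erroneous union unfit
  expect_identical(rep$clean, !(rep$erroneous | rep$unfit))

  # class membership is configuration: reclassify urban as error
  classes <- occfiltr:::default_test_classes
  classes["urban"] <- "error"
  cfg3 <- filter_config(realms = c(g1 = "terrestrial"),
                        test_classes = classes)
  rep3 <- run_filters(rec, cfg3, gaz)
  expect_true(rep3$erroneous[5])
})

test_that("empty gazetteer layers warn and flag nothing", {
  gaz <- gazetteer(land = mk_mini_gazetteer()$land)
  cfg2 <- filter_config(realms = c(g1 = "terrestrial"))
  rec <- mk_records(lat = c(5, 6), lon = c(5, 8))
  w <- capture_warnings(rep <- run_filters(rec, cfg2, gaz))
  expect_true(any(grepl("urban", w)))
  expect_true(any(grepl("capitals", w)))
  expect_false(any(rep$urban))
  expect_false(any(rep$capital))
})

test_that("disabling tests removes their flags", {
  gaz <- mk_mini_gazetteer()
  cfg2 <- filter_config(realms = c(g1 = "terrestrial"),
                        enabled_tests = c("year", "zeros"))
  rec <- mk_records(lat = 25, lon = 25)  # at sea, on diagonal
  rec$year <- 1900L
  rep <- run_filters(rec, cfg2, gaz)
  expect_true(rep$year[1])
  expect_false(rep$realm_mismatch[1])
  expect_false(rep$equal_latlon[1])
})

test_that("filtered_dataset returns exactly the clean records, untouched", {
  gaz <- mk_mini_gazetteer()
  cfg2 <- filter_config(realms = c(g1 = "terrestrial"))
  rec <- mk_records(lat = c(5.123456789, 25), lon = c(7.987654321, 25))
  rep <- run_filters(rec, cfg2, gaz)
  clean <- filtered_dataset(rec, rep)
  expect_identical(clean$record_id, "r0001")
  expect_identical(clean$latitude, 5.123456789)  # full precision preserved
  # all flagged -> empty; all clean -> identity
  rec2 <- mk_records(lat = c(5, 6), lon = c(7, 8))
  rep2 <- run_filters(rec2, cfg2, gaz)
  expect_identical(filtered_dataset(rec2, rep2), rec2)
})

test_that("flag report is deterministic for identical inputs", {
  gaz <- mk_mini_gazetteer()
  cfg2 <- filter_config(realms = c(g1 = "terrestrial"))
  set.seed(31)
  rec <- mk_records(lat = runif(200, 0, 20), lon = runif(200, 0, 20))
  expect_identical(run_filters(rec, cfg2, gaz), run_filters(rec, cfg2, gaz))
})

test_that("summaries report per-test percentages with multi-flag semantics", {
  gaz <- mk_mini_gazetteer(capital_in_urban = TRUE)
  cfg2 <- filter_config(realms = c(g1 = "terrestrial"))
  # 10 records: 1 in urban AND near the capital, 9 clean
  rec <- mk_records(lat = c(10.5, 5 + 0.1 * (1:9)), lon = c(10.5, rep(5, 9)))
  rep <- run_filters(rec, cfg2, gaz)
  s <- summarize_flags(rep, rec)
  tot <- s[s$group == "Total", ]
  expect_equal(tot$pct_urban, 10)
  expect_equal(tot$pct_capital, 10)
  expect_equal(tot$pct_flagged, 10)  # overall < sum of per-test
  expect_lt(tot$pct_flagged, tot$pct_urban + tot$pct_capital)
  # empty input: all-zero totals, no division error
  rec0 <- mk_records(numeric(0), numeric(0))
  rep0 <- run_filters(rec0, cfg2, gaz)
  s0 <- summarize_flags(rep0, rec0)
  expect_equal(s0$pct_flagged, 0)
})

test_that("enlarging a buffer radius only grows the flag set", {
  gaz <- make_toy_gazetteer()
  set.seed(41)
  rec <- mk_records(lat = runif(300, -21, 21), lon = runif(300, -29, 29))
  prev <- rep(FALSE, 300)
  for (r in c(0.5, 5, 50, 500)) {
    cur <- flag_near_points(rec, gaz$capitals, r)
    expect_true(all(cur | !prev))
    prev <- cur
  }
})
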