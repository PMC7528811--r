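test_that("toy gazetteer is deterministic and internally consistent", {
  gaz1 <- make_toy_gazetteer()
  gaz2 <- make_toy_gazetteer(seed = 99)
  expect_identical(gaz1, gaz2)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_gazetteer(gaz1, d1); write_gazetteer(gaz2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
  # every reference point lies on land; urban polygons sit inside land
  pts <- rbind(gaz1$country_centroids$features,
               gaz1$province_centroids$features,
               gaz1$capitals$features, gaz1$institutions$features)
  expect_true(all(point_in_layer(pts$lat, pts$lon, gaz1$land)))
  for (f in gaz1$urban$features) {
    ring <- f$rings[[1]]
    expect_true(all(point_in_layer(ring[, "lat"], ring[, "lon"], gaz1$land)))
  }
  # no point feature is inside an urban polygon or near another point
  expect_false(any(point_in_layer(pts$lat, pts$lon, gaz1$urban)))
  d <- outer(seq_len(nrow(pts)), seq_len(nrow(pts)), function(i, j)
    geodesic_distance(pts$lat[i], pts$lon[i], pts$lat[j], pts$lon[j]))
  diag(d) <- Inf
  expect_gt(min(d), 100)  # far beyond any test buffer
})

test_that("simulation is deterministic under a fixed seed", {
  spec <- simulation_spec(seed = 7, n_groups = 2, n_species = 5)
  sim1 <- simulate_occurrences(spec)
  sim2 <- simulate_occurrences(spec)
  expect_identical(sim1, sim2)
  sim3 <- simulate_occurrences(spec, seed = 8)
  expect_false(identical(sim1$records, sim3$records))
})

test_that("zero contamination yields a fully clean data set", {
  spec <- simulation_spec(
    seed = 3, n_groups = 2, realms = c("terrestrial", "marine"),
    n_species = 6,
    contamination = stats::setNames(numeric(14),
                                    occfiltr:::plantable_issues))
  sim <- simulate_occurrences(spec)
  expect_true(all(is.na(sim$truth$issue)))
  gaz <- make_toy_gazetteer()
  cfg <- filter_config(realms = c(group01 = "terrestrial",
                                  group02 = "marine"))
  rep <- run_filters(sim$records, cfg, gaz)
  expect_true(all(rep$clean))
})

test_that("a pure zeros transform sends every record to the origin", {
  rates <- stats::setNames(numeric(14), occfiltr:::plantable_issues)
  rates["zeros"] <- 1
  # one record per species so the one-zeros-plant-per-species guard is idle
  spec <- simulation_spec(
    seed = 5, n_groups = 1, realms = "terrestrial", n_species = 10,
    records_per_species = list(meanlog = log(1), sdlog = 0, max = 1L),
    contamination = rates)
  sim <- simulate_occurrences(spec)
  expect_identical(nrow(sim$records), 10L)
  expect_true(all(sim$records$latitude == 0 & sim$records$longitude == 0))
  expect_true(all(sim$truth$issue == "zeros"))
})

test_that("planted fractions track configured rates (binomial 99% CI)", {
  rate <- 0.04
  rates <- stats::setNames(rep(rate, 14), occfiltr:::plantable_issues)
  # modest per-species counts so per-species planting guards do not bind
  spec <- simulation_spec(
    seed = 13, n_groups = 2, realms = c("terrestrial", "terrestrial"),
    n_species = 60,
    records_per_species = list(meanlog = log(12), sdlog = 0.4, max = 40L),
    contamination = rates)
  sim <- simulate_occurrences(spec)
  n <- nrow(sim$records)
  expect_gt(n, 1000)
  for (tk in setdiff(occfiltr:::plantable_issues, "zeros")) {
    k <- sum(sim$truth$issue == tk, na.rm = TRUE)
    ci <- stats::qbinom(c(0.005, 0.995), n, rate)
    expect_gte(k, ci[1])
    expect_lte(k, ci[2])
  }
})

test_that("clean records satisfy the separation margins of the truth contract", {
  spec <- simulation_spec(seed = 17, n_groups = 2,
                          realms = c("terrestrial", "marine"), n_species = 8)
  sim <- simulate_occurrences(spec)
  gaz <- make_toy_gazetteer()
  clean <- sim$records[is.na(sim$truth$issue), ]
  realms <- c(group01 = "terrestrial", group02 = "marine")
  pts <- rbind(gaz$country_centroids$features,
               gaz$province_centroids$features,
               gaz$capitals$features, gaz$institutions$features)
  on_land <- point_in_layer(clean$latitude, clean$longitude, gaz$land)
  expect_identical(on_land,
                   unname(realms[clean$group_id]) == "terrestrial")
  expect_false(any(point_in_layer(clean$latitude, clean$longitude,
                                  gaz$urban)))
  expect_false(any(near_any_point(clean$latitude, clean$longitude,
                                  gaz_point_layer("all", pts),
                                  spec$margin_km)))
  expect_true(all(clean$year >= 1945))
  expect_true(all(clean$individual_count >= 1 & clean$individual_count <= 99))
  expect_true(all(clean$taxon_rank == "species"))
  # pairwise rounded-coordinate distinct within species
  key <- paste(clean$species, round(clean$latitude, 4),
               round(clean$longitude, 4))
  expect_false(anyDuplicated(key) > 0)
  # records within each species stay inside the true range rectangle
  for (sp in unique(clean$species)[1:4]) {
    r <- sim$ranges[sim$ranges$species == sp, ]
    cs <- clean[clean$species == sp, ]
    expect_true(all(cs$latitude >= r$min_lat & cs$latitude <= r$max_lat &
                      cs$longitude >= r$min_lon & cs$longitude <= r$max_lon))
  }
})

test_that("filter output reproduces the planted truth exactly", {
  spec <- simulation_spec(seed = 23, n_groups = 3,
                          realms = c("terrestrial", "terrestrial", "marine"),
                          n_species = 10)
  sim <- simulate_occurrences(spec)
  gaz <- make_toy_gazetteer()
  cfg <- filter_config(realms = stats::setNames(spec$realms,
                                                sprintf("group%02d", 1:3)))
  rep <- run_filters(sim$records, cfg, gaz)
  sc <- score_against_truth(rep, sim$truth)
  planted <- sc[sc$n_planted > 0, ]
  expect_gt(nrow(planted), 5)
  expect_true(all(planted$sensitivity == 1))
  expect_true(all(sc$specificity == 1))
  # flagged records are exactly the contaminated ones
  truth <- sim$truth[match(rep$record_id, sim$truth$record_id), ]
  expect_identical(!rep$clean, !is.na(truth$issue))
})

test_that("scoring handles degenerate filters and absent plants", {
  spec <- simulation_spec(seed = 29, n_groups = 1, realms = "terrestrial",
                          n_species = 5)
  sim <- simulate_occurrences(spec)
  rep <- run_filters(sim$records, filter_config(
    realms = c(group01 = "terrestrial"),
    enabled_tests = c("year", "zeros")), gazetteer = NULL)
  # all-flagging "filter": force every flag on
  rep$year <- TRUE
  sc <- score_against_truth(rep, sim$truth)
  yr <- sc[sc$test == "year", ]
  if (yr$n_planted < nrow(sim$records)) expect_equal(yr$specificity, 0)
  # a test with nothing planted has undefined sensitivity
  no_plant <- sc[sc$n_planted == 0, ]
  expect_true(all(is.na(no_plant$sensitivity)))
})

test_that("true range area matches the EOO of a dense uniform sample", {
  spec <- simulation_spec(seed = 31, n_groups = 1, realms = "terrestrial",
                          n_species = 2)
  sim <- simulate_occurrences(spec)
  r <- sim$ranges[1, ]
  set.seed(99)
  lat <- runif(2000, r$min_lat, r$max_lat)
  lon <- runif(2000, r$min_lon, r$max_lon)
  eoo <- compute_eoo(lat, lon)
  expect_gte(eoo, 0.90 * r$area_km2)
  expect_lte(eoo, r$area_km2 * (1 + 1e-6))
})
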