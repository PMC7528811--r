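th <- criterion_b_thresholds()

test_that("EOO handles degenerate point sets and matches the closed form", {
  expect_true(is.na(compute_eoo(c(1, 2), c(1, 2))))          # 2 points
  expect_true(is.na(compute_eoo(c(1, 1, 1), c(1, 2, 3))))    # collinear
  expect_true(is.na(compute_eoo(rep(1, 5), rep(2, 5))))      # 1 unique point
  # 1x1 degree equatorial square: R^2 * dLambda * (sin(1 deg) - sin 0)
  R <- 6371.0088
  closed <- R^2 * (pi / 180) * sin(pi / 180)
  eoo <- compute_eoo(c(0, 0, 1, 1), c(0, 1, 0, 1))
  expect_equal(eoo, closed, tolerance = 0.01)
  # interior points never change the hull
  eoo2 <- compute_eoo(c(0, 0, 1, 1, 0.5, 0.3), c(0, 1, 0, 1, 0.5, 0.7))
  expect_equal(eoo2, eoo, tolerance = 1e-12)
})

test_that("EOO agrees with an independent spherical area implementation", {
  skip_if_not_installed("geosphere")
  set.seed(8)
  for (i in 1:5) {
    lat <- runif(40, -20, 10); lon <- runif(40, -60, -40)
    p <- behrmann_project(lat, lon)
    hull <- grDevices::chull(p$x, p$y)
    ref <- geosphere::areaPolygon(cbind(lon[hull], lat[hull]),
                                  a = 6371008.8, f = 0) / 1e6
    expect_equal(compute_eoo(lat, lon), ref, tolerance = 0.005)
  }
})

test_that("hull monotonicity: adding points never shrinks the EOO", {
  set.seed(14)
  for (i in 1:20) {
    lat <- runif(30, -20, 20); lon <- runif(30, -30, 30)
    base <- compute_eoo(lat[1:15], lon[1:15])
    grown <- compute_eoo(lat, lon)
    if (!is.na(base)) expect_gte(grown + 1e-9, base)
  }
})

test_that("AOO is occupied 2-km cells times 4, locations use 10-km cells", {
  # 3 points far apart -> 3 cells -> 12 km^2
  expect_equal(compute_aoo(c(0, 1, 2), c(0, 1, 2), th), 12)
  # 2 points in one cell -> 4 km^2 (cell at origin covers [0,2)x[0,2) km)
  near <- behrmann_unproject(c(0.4, 0.9), c(0.4, 0.9))
  expect_equal(compute_aoo(near$lat, near$lon, th), 4)
  expect_identical(count_locations(near$lat, near$lon, th), 1L)
  expect_identical(count_locations(5, 5, th), 1L)
  # pigeonhole: n points occupy at most n cells
  set.seed(15)
  lat <- runif(200, -10, 10); lon <- runif(200, -10, 10)
  expect_lte(compute_aoo(lat, lon, th), 4 * 200)
  expect_true(compute_aoo(lat, lon, th) %% 4 == 0)
  # coarser grid: locations <= occupied AOO cells
  expect_lte(count_locations(lat, lon, th), compute_aoo(lat, lon, th) / 4)
})

test_that("Criterion B matches the direct-comparison oracle on the full lattice", {
  eoos <- c(50, 99, 100, 4999, 5000, 19999, 20000, 1e6)
  aoos <- c(4, 8, 10, 499, 500, 1999, 2000, 1e4)
  locs <- c(1, 2, 5, 6, 10, 11)
  n_checked <- 0L
  for (e in eoos) for (a in aoos) for (l in locs) {
    expect_identical(assess_criterion_b(e, a, l, th),
                     oracle_criterion_b(e, a, l, th),
                     info = sprintf("eoo=%g aoo=%g loc=%d", e, a, l))
    n_checked <- n_checked + 1L
  }
  expect_identical(n_checked, 384L)
  # undefined EOO falls back to B2 only
  expect_identical(assess_criterion_b(NA, 8, 1, th), "CR")
  expect_identical(assess_criterion_b(NA, 8, 1, th),
                   oracle_criterion_b(NA, 8, 1, th))
  expect_identical(assess_criterion_b(50, 5000, 30, th), "NT_proxy")
})

test_that("severity is monotone in EOO", {
  sev <- c(NT_proxy = 0, VU = 1, EN = 2, CR = 3)
  for (l in c(1, 5, 10, 30)) {
    prev <- -1
    for (e in rev(c(50, 99, 100, 4999, 5000, 19999, 20000, 1e6))) {
      cur <- sev[[assess_criterion_b(e, 1e4, l, th)]]
      expect_gte(cur, prev)  # decreasing EOO never less severe
      prev <- cur
    }
  }
})

test_that("assess_all composes the metrics per species deterministically", {
  rec <- mk_records(lat = c(5.5, 5.5), lon = c(6.5, 8.5),
                    species = c("one rec", "one rec"))
  rec <- rbind(rec, mk_records(lat = 3.3, lon = 3.3, species = "single",
                               id = "r9999"))
  res <- assess_all(rec, th)
  expect_identical(res$species, c("one rec", "single"))
  single <- res[res$species == "single", ]
  expect_true(is.na(single$eoo_km2))
  expect_equal(single$aoo_km2, 4)
  expect_identical(single$n_locations, 1L)
  expect_identical(single$category, "CR")
  # splitting input and concatenating gives the same result
  res2 <- assess_all(rec[c(3, 1, 2), ], th)
  expect_equal(res, res2)
  expect_identical(nrow(assess_all(mk_records(numeric(0), numeric(0)))), 0L)
})

test_that("binary threatened classification and reference comparison", {
  expect_identical(binarize_threatened(c("CR", "EN", "VU", "NT_proxy", "LC",
                                         "NT", "DD", "NE")),
                   c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, NA, NA))
  auto <- data.frame(species = c("a", "b", "c", "d"),
                     n_records = 1L, eoo_km2 = NA, aoo_km2 = 4,
                     n_locations = 1L,
                     category = c("CR", "NT_proxy", "VU", "EN"))
  ref <- data.frame(species = c("a", "b", "c", "e"),
                    category = c("EN", "VU", "DD", "LC"))
  cmp <- compare_with_reference(auto, ref)
  expect_identical(cmp$n_overlap, 3L)
  expect_identical(cmp$n_compared, 2L)   # c has DD reference -> excluded
  expect_identical(cmp$n_match, 1L)      # a: CR vs EN both threatened
  expect_equal(cmp$match_pct, 50)        # b: NT_proxy vs VU mismatch
  # no overlap -> undefined match
  cmp0 <- compare_with_reference(auto,
                                 data.frame(species = "zz", category = "LC"))
  expect_true(is.na(cmp0$match_pct))
})

test_that("range change reports per-group medians of percentage change", {
  base <- data.frame(species = c("a", "b", "c"), n_records = 5L,
                     eoo_km2 = c(100, 200, NA), aoo_km2 = c(40, 100, 8),
                     n_locations = 2L, category = "VU")
  filt <- base
  filt$eoo_km2 <- c(80, 200, NA)
  filt$aoo_km2 <- c(40, 50, 8)
  groups <- c(a = "g1", b = "g1", c = "g2")
  chg <- range_change(base, filt, groups)
  g1 <- chg[chg$group == "g1", ]
  expect_equal(g1$median_eoo_change_pct, median(c(-20, 0)))
  expect_equal(g1$median_aoo_change_pct, median(c(0, -50)))
  # species with undefined EOO excluded from the EOO median, kept for AOO
  g2 <- chg[chg$group == "g2", ]
  expect_true(is.na(g2$median_eoo_change_pct))
  expect_equal(g2$median_aoo_change_pct, 0)
  # identical assessments -> zero change
  expect_equal(range_change(base, base)$median_aoo_change_pct, 0)
})
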