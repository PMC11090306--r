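# Synthetic scenario generator: determinism, planted truth, IO round-trips.

small_config <- function(seed = 101, ...) {
  scenario_config(seed = seed, n_species = 2L, n_inside = 60L,
                  n_marginal = 8L, n_extralimital = 10L, ...)
}

test_that("the same seed reproduces the scenario bit for bit", {
  s1 <- generate_scenario(small_config(7))
  s2 <- generate_scenario(small_config(7))
  expect_identical(s1$occurrences, s2$occurrences)
  expect_identical(s1$truth, s2$truth)
  s3 <- generate_scenario(small_config(8))
  expect_false(identical(s1$occurrences, s3$occurrences))
})

test_that("record counts follow the configuration", {
  cfg <- small_config(5)
  s <- generate_scenario(cfg)
  per <- cfg$n_inside + cfg$n_marginal + cfg$n_extralimital
  expect_equal(nrow(s$occurrences), 2 * per)
  expect_equal(length(unique(s$occurrences$species)), 2)
  # corrupted records are excluded from truth statuses
  expect_equal(sum(s$truth$excluded), 2 * round(cfg$dubious_rate * per))
  tr <- s$truth[!s$truth$excluded, ]
  expect_true(all(tr$status %in% c("inside", "marginal_buffer", "extralimital")))
  # each planted class loses at most the corrupted records
  expect_lte(abs(sum(tr$status == "extralimital") - 2 * cfg$n_extralimital),
             sum(s$truth$excluded))
})

test_that("n_extralimital = 0 produces no extralimital truth", {
  s <- generate_scenario(scenario_config(seed = 11, n_species = 1L,
                                         n_inside = 40L, n_marginal = 5L,
                                         n_extralimital = 0L,
                                         dubious_rate = 0))
  expect_equal(sum(s$truth$status == "extralimital"), 0)
  expect_equal(sum(s$truth$excluded), 0)
})

test_that("planted truth distances agree with independent recomputation", {
  s <- generate_scenario(small_config(23))
  tr <- s$truth[!s$truth$excluded, ]
  occ <- s$occurrences[match(tr$record_id, s$occurrences$record_id), ]
  for (sp in unique(tr$species)) {
    rows <- tr$species == sp
    xy <- project_points(cbind(occ$longitude[rows], occ$latitude[rows]), s$spec)
    disp <- boundary_displacement(xy, s$core_polys[[sp]])
    expect_equal(disp$inside, tr$status[rows] == "inside")
    expect_lt(max(abs(disp$distance_km - tr$distance_km[rows])), 0.01)  # < 10 m
  }
})

test_that("extralimital truth respects the distance floor and bearing model", {
  cfg <- scenario_config(seed = 31, n_species = 3L, n_inside = 50L,
                         n_marginal = 5L, n_extralimital = 60L,
                         dubious_rate = 0)
  s <- generate_scenario(cfg)
  ex <- s$truth[s$truth$status == "extralimital", ]
  expect_true(all(ex$distance_km > 5))
  cs <- circular_summary(ex$bearing_deg %% 360)
  expect_lt(abs(cs$mean_bearing_deg - cfg$bearing$mu_deg), 15)
  marg <- s$truth[s$truth$status == "marginal_buffer", ]
  expect_true(all(marg$distance_km > 0 & marg$distance_km < 5))
})

test_that("the study region contains all uncorrupted records", {
  s <- generate_scenario(small_config(41))
  tr_ok <- !s$truth$excluded
  region <- project_poly(s$study_region, s$spec)
  xy <- project_points(cbind(s$occurrences$longitude[tr_ok],
                             s$occurrences$latitude[tr_ok]), s$spec)
  expect_true(all(pp_contains(region, xy[, 1], xy[, 2])))
})

test_that("truth HU codes match polygon point-in-cell tests", {
  s <- generate_scenario(small_config(53))
  tr <- s$truth[!s$truth$excluded, ]
  occ <- s$occurrences[match(tr$record_id, s$occurrences$record_id), ]
  xy <- project_points(cbind(occ$longitude, occ$latitude), s$spec)
  idx <- match(tr$hu_code, s$hu$codes)
  expect_false(anyNA(idx))
  hits <- vapply(seq_len(nrow(tr)), function(i) {
    pp_contains(s$hu$geometries[[idx[i]]], xy[i, 1], xy[i, 2])
  }, logical(1))
  expect_true(all(hits))
})

test_that("scenario write/read round-trips through disk", {
  s <- generate_scenario(small_config(67))
  d <- withr::local_tempdir()
  write_scenario(s, d)
  expect_true(all(file.exists(file.path(d, c(
    "occurrences.csv", "marginal_records.csv", "truth.csv",
    "hu_layer.geojson", "management_units.geojson",
    "study_region.geojson", "grouping.csv", "config.txt")))))
  back <- read_scenario(d)
  expect_equal(back$occurrences$record_id, s$occurrences$record_id)
  expect_equal(back$occurrences$longitude, s$occurrences$longitude,
               tolerance = 1e-9)
  expect_equal(back$truth$status, s$truth$status)
  expect_equal(back$truth$distance_km, s$truth$distance_km, tolerance = 1e-6)
  expect_equal(back$config$seed, s$config$seed)
  expect_equal(back$config$distance$meanlog, s$config$distance$meanlog)
  expect_equal(sort(back$hu$codes), sort(s$hu$codes))
  # geometries survive the lon/lat round-trip to sub-meter precision
  g0 <- s$units$geometries[[1]]
  g1 <- back$units$geometries[[match(s$units$units$abbreviation[1],
                                     back$units$units$abbreviation)]]
  expect_equal(pp_area(g1), pp_area(g0), tolerance = 1e-6)
})

test_that("config round-trips through its text format", {
  cfg <- small_config(99)
  f <- withr::local_tempfile(fileext = ".txt")
  write_config(cfg, f)
  back <- read_scenario_config(f)
  expect_equal(back$seed, cfg$seed)
  expect_equal(back$n_extralimital, cfg$n_extralimital)
  expect_equal(back$distance$sdlog, cfg$distance$sdlog)
  expect_equal(back$bearing$kappa, cfg$bearing$kappa)
  expect_equal(back$year_weights, cfg$year_weights)
})

test_that("invalid configurations are rejected", {
  expect_error(scenario_config(seed = 1,
                               distance = list(kind = "fixed", km = 3)),
               "5")
  expect_error(scenario_config())
})

test_that("GeoJSON range round-trip preserves geometry and properties", {
  spec <- local_azimuthal(-150, 64)
  pts <- unproject_points(rbind(c(0, 0), c(40000, 0), c(40000, 30000),
                                c(0, 30000), c(15000, 12000)), spec)
  r <- build_mcp(pts, spec, species = "T t")
  f <- withr::local_tempfile(fileext = ".geojson")
  write_ranges_geojson(r, f)
  back <- read_ranges_geojson(f, spec)[[1]]
  expect_equal(back$species, "T t")
  expect_equal(back$provenance, "MCP_2009")
  expect_equal(back$area_km2, r$area_km2, tolerance = 1e-6)
})
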