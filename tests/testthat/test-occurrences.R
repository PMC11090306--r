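# Darwin Core ingest, precision filtering, dubiousness flagging, taxonomy.

write_dwc <- function(lines, ext = "csv") {
  f <- withr::local_tempfile(fileext = paste0(".", ext),
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("a small Darwin Core csv is parsed field-by-field", {
  f <- write_dwc(c(
    "occurrenceID,scientificName,decimalLatitude,decimalLongitude,coordinateUncertaintyInMeters,year,basisOfRecord,institutionCode",
    "r1,Sorex cinereus,64.84,-147.7,100,2015,PreservedSpecimen,UAM",
    "r2,Sorex cinereus,64.90,-147.8,,1988,HumanObservation,GBIF",
    "r3,Alces alces,61.2,-149.9,250,2010,MaterialSample,UAM"))
  occ <- read_occurrences(f, split = FALSE)
  expect_equal(nrow(occ), 3)
  expect_equal(occ$record_id, c("r1", "r2", "r3"))
  expect_equal(occ$species, c("Sorex cinereus", "Sorex cinereus", "Alces alces"))
  expect_equal(occ$latitude, c(64.84, 64.90, 61.2))
  expect_equal(occ$longitude, c(-147.7, -147.8, -149.9))
  expect_equal(occ$uncertainty_m, c(100, NA, 250))
  expect_equal(occ$year, c(2015L, 1988L, 2010L))
  expect_equal(occ$basis, c("specimen", "human_observation", "tissue"))
  expect_equal(occ$flags, c("", "", ""))
})

test_that("tab-delimited input is auto-detected and split by species", {
  f <- write_dwc(c(
    paste("scientificName", "decimalLatitude", "decimalLongitude", sep = "\t"),
    paste("Sorex cinereus", "64.8", "-147.7", sep = "\t"),
    paste("Alces alces", "61.2", "-149.9", sep = "\t"),
    paste("Sorex cinereus", "64.9", "-147.8", sep = "\t")), ext = "txt")
  sets <- read_occurrences(f)
  expect_named(sets, c("Sorex cinereus", "Alces alces"))
  expect_equal(nrow(sets[["Sorex cinereus"]]), 2)
  expect_equal(nrow(sets[["Alces alces"]]), 1)
})

test_that("impossible coordinates are flagged at ingest", {
  f <- write_dwc(c(
    "scientificName,decimalLatitude,decimalLongitude",
    "Sorex cinereus,91.2,-147.7",
    "Sorex cinereus,64.8,-147.7"))
  occ <- read_occurrences(f, split = FALSE)
  expect_true(has_flag(occ, "dubious_coordinates")[1])
  expect_false(has_flag(occ, "dubious_coordinates")[2])
})

test_that("a missing mandatory column is named in the error", {
  f <- write_dwc(c("scientificName,decimalLatitude", "Sorex cinereus,64.8"))
  expect_error(read_occurrences(f), "decimalLongitude")
})

test_that("an empty file yields an empty result, not an error", {
  f <- write_dwc("scientificName,decimalLatitude,decimalLongitude")
  expect_identical(read_occurrences(f), list())
  expect_equal(nrow(read_occurrences(f, split = FALSE)), 0)
})

test_that("splitting ten hand-built records gives the hand counts", {
  occ <- make_occ(lon = seq(-150, -149.1, by = 0.1), lat = rep(64, 10),
                  species = rep(c("A a", "B b"), c(6, 4)))
  sets <- split_occurrences(occ)
  expect_equal(vapply(sets, nrow, integer(1)), c("A a" = 6L, "B b" = 4L))
  expect_equal(dplyr::bind_rows(sets)$record_id, occ$record_id)
})

test_that("precision filter is strict at the threshold and conserves rows", {
  occ <- make_occ(lon = rep(-150, 4), lat = rep(64, 4))
  occ$uncertainty_m <- c(4999, 5000, 5001, NA)
  parts <- filter_by_precision(occ, max_uncertainty_m = 5000)
  expect_equal(parts$kept$record_id, c("t001", "t004"))
  expect_equal(parts$dropped$record_id, c("t002", "t003"))
  expect_true(has_flag(parts$kept, "missing_uncertainty")[2])
  expect_false(has_flag(parts$kept, "missing_uncertainty")[1])
  expect_equal(nrow(parts$kept) + nrow(parts$dropped), nrow(occ))
})

test_that("precision filter agrees with brute force on 100 random records", {
  set.seed(42)
  occ <- make_occ(lon = runif(100, -160, -140), lat = runif(100, 58, 68))
  occ$uncertainty_m <- ifelse(runif(100) < 0.2, NA, runif(100, 0, 10000))
  parts <- filter_by_precision(occ, 5000)
  manual_keep <- is.na(occ$uncertainty_m) | occ$uncertainty_m < 5000
  expect_setequal(parts$kept$record_id, occ$record_id[manual_keep])
  expect_setequal(parts$dropped$record_id, occ$record_id[!manual_keep])
})

test_that("null island and implausible years are flagged, and flagging is idempotent", {
  occ <- make_occ(lon = c(0, -150, -150, -150), lat = c(0, 64, 64, 64),
                  year = c(2000L, 2099L, 1650L, 2000L))
  out <- flag_dubious(occ)
  expect_true(has_flag(out, "dubious_coordinates")[1])
  expect_equal(has_flag(out, "dubious_year"), c(FALSE, TRUE, TRUE, FALSE))
  expect_false(any(is_dubious(out)[4]))
  expect_identical(flag_dubious(out), out)
  expect_equal(nrow(out), 4)   # flagging never drops rows
})

test_that("records far outside the study region are flagged, nearby ones kept", {
  spec <- local_azimuthal(-150, 64)
  # study region: ~100 km box in degrees around (-150, 64)
  region <- planar_poly(list(x = c(-151, -149, -149, -151),
                             y = c(63.5, 63.5, 64.5, 64.5)))
  # 5 planted far-out records (longitude sign flipped) among in-region ones
  occ <- make_occ(lon = c(rep(-150, 5), rep(150, 5)),
                  lat = rep(64, 10))
  out <- flag_dubious(occ, study_region = region, spec = spec)
  expect_equal(sum(has_flag(out, "dubious_coordinates")), 5)
  expect_equal(which(has_flag(out, "dubious_coordinates")), 6:10)
  # a point ~2 km outside the boundary is within the 5 km tolerance
  near <- make_occ(lon = -151.04, lat = 64)
  expect_false(has_flag(flag_dubious(near, region, spec), "dubious_coordinates"))
})

test_that("taxonomy harmonization maps synonyms and conserves records", {
  occ <- make_occ(lon = rep(-150, 5), lat = rep(64, 5))
  occ$raw_name <- occ$species <- c("Sorex cinereus", "Sorex cinereus arcticus",
                                   "Alces americanus", "Alces alces",
                                   "Mystery beast")
  tab <- c("Sorex cinereus arcticus" = "Sorex cinereus",
           "Alces americanus" = "Alces alces",
           "Sorex cinereus" = "Sorex cinereus",
           "Alces alces" = "Alces alces")
  out <- apply_taxonomy(occ, tab)
  expect_equal(out$species, c("Sorex cinereus", "Sorex cinereus",
                              "Alces alces", "Alces alces", "Mystery beast"))
  expect_equal(out$raw_name, occ$raw_name)         # provenance kept
  expect_equal(has_flag(out, "taxonomy_unresolved"),
               c(FALSE, FALSE, FALSE, FALSE, TRUE))
  sets <- split_occurrences(out)
  expect_equal(sum(vapply(sets, nrow, integer(1))), 5)  # record conservation
})

test_that("write/read round-trip preserves the table", {
  occ <- make_occ(lon = c(-150.123, -149.5), lat = c(64.25, 63.75),
                  unc = c(120, NA), year = c(2001L, NA))
  f <- withr::local_tempfile(fileext = ".csv")
  write_occurrences(occ, f)
  back <- read_occurrences(f, split = FALSE)
  expect_equal(back$longitude, occ$longitude)
  expect_equal(back$latitude, occ$latitude)
  expect_equal(back$uncertainty_m, occ$uncertainty_m)
  expect_equal(back$year, occ$year)
  expect_equal(back$record_id, occ$record_id)
})

test_that("ingest is deterministic", {
  f <- write_dwc(c(
    "scientificName,decimalLatitude,decimalLongitude",
    "Sorex cinereus,64.8,-147.7",
    "Alces alces,61.2,-149.9"))
  expect_identical(read_occurrences(f), read_occurrences(f))
})
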