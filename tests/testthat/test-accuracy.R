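# Sensitivity, hydrologic-unit occupancy, and the scoreboard.

ASPEC <- local_azimuthal(-150, 64)

aocc_at <- function(dx, dy, ...) {
  ll <- unproject_points(cbind(dx, dy), ASPEC)
  make_occ(lon = ll[, 1], lat = ll[, 2], ...)
}

asquare <- function(half = 20000) {
  pts <- unproject_points(rbind(c(-half, -half), c(half, -half),
                                c(half, half), c(-half, half)), ASPEC)
  build_mcp(pts, ASPEC, species = "T t")
}

test_that("sensitivity is 100% when every record is inside", {
  base <- asquare()
  set.seed(2)
  occ <- aocc_at(runif(50, -19000, 19000), runif(50, -19000, 19000))
  s <- sensitivity(occ, base)
  expect_equal(s$sensitivity_pct, 100)
  expect_equal(s$n_in, 50)
  expect_equal(s$n_total, 50)
})

test_that("9 within-tolerance records of 10 give 90%", {
  base <- asquare()
  occ <- aocc_at(c(rep(0, 8), 24000, 40000), c(seq(0, 7000, 1000), 0, 0))
  s <- sensitivity(occ, base)
  expect_equal(s$sensitivity_pct, 90)
  expect_equal(s$n_in, 9)   # 8 inside + 1 marginal (4 km out)
})

test_that("sensitivity matches a planted 37-of-40 truth", {
  base <- asquare()
  set.seed(77)
  inside <- cbind(runif(37, -19000, 19000), runif(37, -19000, 19000))
  outside <- cbind(20000 + runif(3, 6000, 30000), runif(3, -10000, 10000))
  occ <- aocc_at(c(inside[, 1], outside[, 1]), c(inside[, 2], outside[, 2]))
  s <- sensitivity(occ, base)
  expect_equal(s$sensitivity_pct, 100 * 37 / 40)
})

test_that("flagged records are excluded from the denominator unless requested", {
  base <- asquare()
  occ <- aocc_at(c(0, 0, 40000, 40000), c(0, 5000, 0, 5000))
  occ$flags[c(2, 3)] <- "dubious_coordinates"
  s <- sensitivity(occ, base)
  expect_equal(s$n_total, 2)
  expect_equal(s$sensitivity_pct, 50)
  s2 <- sensitivity(occ, base, include_flagged = TRUE)
  expect_equal(s2$n_total, 4)
})

test_that("HU occupancy counts only units intersecting the range", {
  base <- asquare(25000)    # 50 km square
  # 2x2 grid of 30 km cells covering the range, plus 2 far-away cells
  cell <- function(x0, y0) pp_rect(x0, x0 + 30000, y0, y0 + 30000)
  hus <- hu_layer(c("A1", "A2", "B1", "B2", "Z1", "Z2"),
                  list(cell(-30000, -30000), cell(0, -30000),
                       cell(-30000, 0), cell(0, 0),
                       cell(500000, 0), cell(500000, 500000)))
  # records in two of the four intersecting cells
  occ <- aocc_at(c(-15000, 15000), c(-15000, -15000))
  h <- hu_occupancy(occ, base, hus)
  expect_equal(h$hu_total, 4)
  expect_equal(h$hu_occupied, 2)
  expect_equal(h$hu_occupancy_pct, 50)
})

test_that("a range touching no unit warns and returns NA occupancy", {
  base <- asquare()
  hus <- hu_layer("far", list(pp_rect(900000, 930000, 900000, 930000)))
  expect_warning(h <- hu_occupancy(aocc_at(0, 0), base, hus), "no hydrologic unit")
  expect_true(is.na(h$hu_occupancy_pct))
  expect_equal(h$hu_total, 0L)
})

test_that("a record within tolerance of a unit counts it as occupied", {
  base <- asquare(25000)
  hus <- hu_layer("only", list(pp_rect(-30000, 30000, -30000, 30000)))
  # record 4 km outside the unit's edge
  occ <- aocc_at(34000, 0)
  expect_equal(hu_occupancy(occ, base, hus)$hu_occupied, 1)
  # and 6 km outside does not count
  occ2 <- aocc_at(36000, 0)
  expect_equal(hu_occupancy(occ2, base, hus)$hu_occupied, 0)
})

test_that("scoreboard tallies a hand-built metrics table with strict comparisons", {
  m <- tibble::tibble(
    species = paste("Sp", 1:6),
    sensitivity_pct = c(95, 90, 85, 100, NA, 20),
    hu_occupancy_pct = c(60, 50, 40, NA, 30, 80),
    n_total = c(10, 10, 10, 10, 10, 10),
    extralimital_total = c(0, 2, NA, 5, 0, 1))
  sb <- scoreboard(m)
  expect_equal(sb$n_species, 6)
  expect_equal(sb$n_species_with_sensitivity, 5)
  expect_equal(sb$n_exceeding_sensitivity, 2)   # 95, 100 (strictly > 90)
  expect_equal(sb$n_reaching_sensitivity, 3)    # 95, 90, 100 (>= 90)
  expect_equal(sb$mean_sensitivity_pct, mean(c(95, 90, 85, 100, 20)))
  expect_equal(sb$n_species_with_occupancy, 5)
  expect_equal(sb$mean_hu_occupancy_pct, mean(c(60, 50, 40, 30, 80)))
  expect_equal(sb$n_above_occupancy_threshold, 2)  # 60, 80 strictly above 50
  expect_equal(sb$n_below_occupancy_threshold, 2)  # 40, 30 strictly below
  expect_equal(sb$n_with_extralimitals, 3)         # 2, 5, 1
  expect_equal(sb$weighted_mean_sensitivity_pct, mean(c(95, 90, 85, 100, 20)))
})

test_that("the packaged evaluation fixture reproduces the published tallies", {
  tab <- load_table1_fixture()
  expect_equal(nrow(tab), 61)
  sb_akgap <- scoreboard(dplyr::rename(tab, sensitivity_pct = akgap_sensitivity,
                                       hu_occupancy_pct = akgap_hu_occupancy))
  expect_equal(sb_akgap$n_species_with_sensitivity, 37)
  expect_equal(sb_akgap$n_exceeding_sensitivity, 31)   # sensitivity > 90%
  expect_equal(sb_akgap$mean_hu_occupancy_pct, 57.3, tolerance = 0.001)
  expect_equal(sb_akgap$n_below_occupancy_threshold, 13)
  sb_iucn <- scoreboard(dplyr::rename(tab, sensitivity_pct = iucn_sensitivity))
  expect_equal(sb_iucn$n_species_with_sensitivity, 39)
  expect_equal(sb_iucn$n_reaching_sensitivity, 17)     # sensitivity >= 90%
  sb <- scoreboard(tab)
  expect_equal(sb$n_with_extralimitals, 39)
  expect_equal(round(100 * sb$n_with_extralimitals / sb$n_species, 1), 63.9)
})
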