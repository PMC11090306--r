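# MCP and concave-hull range construction.

# a local planar frame so degrees map to meters predictably
SPEC <- local_azimuthal(-150, 64)

# place projected-meter offsets around the frame origin as lon/lat
ll_at <- function(dx, dy) {
  unproject_points(cbind(dx, dy), SPEC)
}

test_that("MCP of a triangle is that triangle", {
  ll <- ll_at(c(0, 10000, 0), c(0, 0, 10000))
  mcp <- build_mcp(ll, SPEC, species = "T t")
  expect_s3_class(mcp, "range_polygon")
  expect_equal(mcp$provenance, "MCP_2009")
  expect_equal(mcp$area_km2, 50, tolerance = 1e-6)
})

test_that("interior points do not change the MCP", {
  sq <- ll_at(c(0, 20000, 20000, 0), c(0, 0, 20000, 20000))
  withcenter <- rbind(sq, ll_at(10000, 10000))
  a1 <- build_mcp(sq, SPEC)$area_km2
  a2 <- build_mcp(withcenter, SPEC)$area_km2
  expect_equal(a1, a2, tolerance = 1e-9)
  expect_equal(a1, 400, tolerance = 1e-6)
})

test_that("MCP area matches the gift-wrapping oracle on 200 random points", {
  set.seed(31)
  dx <- runif(200, -40000, 40000); dy <- runif(200, -40000, 40000)
  mcp <- build_mcp(ll_at(dx, dy), SPEC)
  hull <- giftwrap_hull(cbind(dx, dy))
  oracle_km2 <- abs(ring_signed_area(list(x = hull[, 1], y = hull[, 2]))) / 1e6
  expect_equal(mcp$area_km2, oracle_km2, tolerance = 1e-6)
})

test_that("degenerate MCP inputs are promoted to thin valid polygons", {
  one <- build_mcp(ll_at(0, 0), SPEC)
  expect_gt(one$area_km2, 0)
  expect_lt(one$area_km2, pi * 1.1^2 / 1e6)   # ~1 m disk
  two <- build_mcp(ll_at(c(0, 10000), c(0, 0)), SPEC)
  # 10 km x 2 m sliver plus end caps
  expect_equal(two$area_km2 * 1e6, 10000 * 2 + pi, tolerance = 0.02)
  collinear <- build_mcp(ll_at(c(0, 5000, 10000), c(0, 0, 0)), SPEC)
  expect_equal(collinear$area_km2, two$area_km2, tolerance = 1e-3)
})

test_that("aggregation distance follows its formula", {
  p <- concave_hull_params()
  # two points 30 km apart: median NN = 30 km > 1 km floor
  expect_equal(aggregation_distance(cbind(c(0, 30000), c(0, 0)), p), 12 * 30000)
  # tight cluster: floor engages
  xy <- cbind(c(0, 10, 20, 30), c(0, 0, 0, 0))
  expect_equal(aggregation_distance(xy, p), 12 * 1000)
  # against the all-pairs oracle on random points
  set.seed(8)
  xy <- cbind(runif(60, 0, 50000), runif(60, 0, 50000))
  expect_equal(aggregation_distance(xy, p),
               12 * max(1000, median(allpairs_nn(xy))))
})

test_that("a single point yields a buffer_m disk", {
  r <- build_concave_range(ll_at(0, 0), SPEC)
  expect_equal(r$provenance, "CONCAVE_CURRENT")
  expect_equal(r$area_km2, pi * 5^2, tolerance = 0.01)
})

test_that("two distant clusters yield a disjoint two-part range", {
  set.seed(4)
  a <- cbind(runif(30, 0, 20000), runif(30, 0, 20000))
  b <- cbind(runif(30, 500000, 520000), runif(30, 0, 20000))
  xy <- rbind(a, b)
  r <- build_concave_range(ll_at(xy[, 1], xy[, 2]), SPEC)
  expect_equal(pp_n_parts(r$geometry), 2)
})

test_that("a huge factor reduces the concave hull to the buffered convex hull", {
  set.seed(12)
  xy <- cbind(runif(80, 0, 60000), runif(80, 0, 60000))
  ll <- ll_at(xy[, 1], xy[, 2])
  loose <- concave_hull_params(multiplicative_factor = 1e6)
  r <- build_concave_range(ll, SPEC, loose)
  hull_buf <- pp_buffer(build_mcp(ll, SPEC)$geometry, 5000)
  expect_equal(r$area_km2, pp_area(hull_buf) / 1e6, tolerance = 1e-3)
})

test_that("the concave range contains every contributing point", {
  set.seed(21)
  xy <- cbind(runif(120, 0, 80000), runif(120, 0, 80000))
  # add an isolated outlier that no triangle will keep
  xy <- rbind(xy, c(400000, 400000))
  r <- build_concave_range(ll_at(xy[, 1], xy[, 2]), SPEC)
  expect_true(all(pp_contains(r$geometry, xy[, 1], xy[, 2])))
})

test_that("tightening the factor never grows the range", {
  set.seed(33)
  xy <- cbind(runif(70, 0, 70000), runif(70, 0, 70000))
  ll <- ll_at(xy[, 1], xy[, 2])
  areas <- vapply(c(2, 5, 12, 50), function(f) {
    build_concave_range(ll, SPEC, concave_hull_params(multiplicative_factor = f))$area_km2
  }, numeric(1))
  expect_true(all(diff(areas) >= -1e-9))
})

test_that("per-species factor overrides are applied", {
  p <- concave_hull_params()
  expect_equal(apply_factor_overrides(p, "Microtus abbreviatus")$multiplicative_factor, 8)
  expect_equal(apply_factor_overrides(p, "Microtus longicaudus")$multiplicative_factor, 15)
  expect_equal(apply_factor_overrides(p, "Sorex cinereus")$multiplicative_factor, 12)
})

test_that("dubious records are excluded from the concave range", {
  set.seed(44)
  xy <- cbind(runif(40, 0, 30000), runif(40, 0, 30000))
  ll <- ll_at(xy[, 1], xy[, 2])
  occ <- make_occ(lon = c(ll[, 1], 0), lat = c(ll[, 2], 0))
  occ <- flag_dubious(occ)    # the appended (0,0) gets flagged
  r_with_flagged_row <- build_concave_range(occ, SPEC)
  r_clean <- build_concave_range(ll, SPEC)
  expect_equal(r_with_flagged_row$area_km2, r_clean$area_km2, tolerance = 1e-9)
})
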