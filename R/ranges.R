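# Range construction: baseline minimum convex polygons (MCPs) from digitized
# marginal records, and current concave-hull ranges from full occurrence sets
# via Delaunay edge-pruning.

RANGE_PROVENANCE <- c("MCP_2009", "IUCN", "AKGAP", "CONCAVE_CURRENT")

#' Construct a range polygon object
#'
#' @param species Species binomial.
#' @param provenance One of `"MCP_2009"`, `"IUCN"`, `"AKGAP"`,
#'   `"CONCAVE_CURRENT"`.
#' @param geometry A [planar_poly()] in projected meters.
#' @param spec The [projection_spec()] of the planar frame.
#' @return An object of class `range_polygon` with the recorded `area_km2`.
#' @export
range_polygon <- function(species, provenance, geometry, spec) {
  provenance <- match.arg(provenance, RANGE_PROVENANCE)
  geometry <- pp_normalize(geometry)
  if (length(geometry) == 0L)
    stop("range_polygon: empty geometry for ", species, call. = FALSE)
  structure(list(species = species, provenance = provenance,
                 geometry = geometry, spec = spec,
                 area_km2 = polygon_area_km2(geometry)),
            class = "range_polygon")
}

#' @export
print.range_polygon <- function(x, ...) {
  cat(sprintf("<range_polygon: %s [%s], %.1f km^2, %d part(s)>\n",
              x$species, x$provenance, x$area_km2, pp_n_parts(x$geometry)))
  invisible(x)
}

#' Planar polygon area in square kilometers
#' @param polygon A `planar_poly` (meters) or a `range_polygon`.
#' @return Area in km^2 (holes subtracted).
#' @export
polygon_area_km2 <- function(polygon) {
  if (inherits(polygon, "range_polygon")) polygon <- polygon$geometry
  pp_area(polygon) / 1e6
}

# ---- minimum convex polygon -------------------------------------------------

#' Build a baseline minimum convex polygon range
#'
#' The convex hull of the projected marginal-record coordinates. Degenerate
#' inputs (one or two points, or all collinear) are promoted to valid polygons
#' by a 1 m buffer so downstream intersection code needs no special cases.
#'
#' @param points A two-column matrix/data.frame of lon/lat marginal records,
#'   or a tibble with `longitude`/`latitude` columns.
#' @param spec A [projection_spec()].
#' @param species Species name recorded on the output.
#' @return A `range_polygon` with provenance `"MCP_2009"`.
#' @export
build_mcp <- function(points, spec, species = "unknown") {
  xy <- .points_to_xy(points, spec)
  if (nrow(xy) < 1L) stop("build_mcp: needs at least 1 point", call. = FALSE)
  xy <- unique(xy)
  h <- grDevices::chull(xy[, 1], xy[, 2])
  hull <- xy[h, , drop = FALSE]
  geom <- NULL
  if (nrow(hull) >= 3L && abs(ring_signed_area(list(x = hull[, 1], y = hull[, 2]))) > 1e-6) {
    # chull returns clockwise order; reverse to counter-clockwise
    cand <- planar_poly(list(x = rev(hull[, 1]), y = rev(hull[, 2])))
    # near-collinear slivers can vanish under clipping; fall through if so
    if (length(pp_normalize(cand)) > 0L) geom <- cand
  }
  if (is.null(geom)) {
    geom <- if (nrow(xy) == 1L) {
      pp_circle(xy[1, 1], xy[1, 2], 1, n = 32L)
    } else {
      # segment (2 points or collinear set): buffer the polyline by 1 m
      ord <- order(xy[, 1], xy[, 2])
      line <- list(list(x = xy[ord, 1], y = xy[ord, 2]))
      out <- polyclip::polylineoffset(line, 1, jointype = "round", endtype = "openround")
      planar_poly(out)
    }
  }
  range_polygon(species, "MCP_2009", geom, spec)
}

.points_to_xy <- function(points, spec) {
  if (is.data.frame(points) && all(c("longitude", "latitude") %in% names(points))) {
    ll <- cbind(points$longitude, points$latitude)
  } else {
    ll <- as.matrix(points)
  }
  ll <- ll[stats::complete.cases(ll), , drop = FALSE]
  project_points(ll, spec)
}

# ---- concave hull -----------------------------------------------------------

#' Concave-hull parameters
#'
#' Controls the concave range rule: Delaunay triangles whose longest edge
#' exceeds `multiplicative_factor * max(min_search_distance_m, median
#' nearest-neighbour distance)` are pruned, and the surviving geometry is
#' dilated by `buffer_m`. Per-species factor overrides accommodate disjunct
#' distributions (defaults follow the study conventions: factor 12 for all
#' species except Microtus abbreviatus, 8, and Microtus longicaudus, 15).
#'
#' @param min_search_distance_m Floor on the nearest-neighbour scale (m).
#' @param buffer_m Final dilation distance (m).
#' @param multiplicative_factor Unitless scale factor for the aggregation
#'   distance.
#' @param overrides Named numeric vector of per-species factors.
#' @return A list of class `concave_hull_params`.
#' @export
concave_hull_params <- function(min_search_distance_m = 1000,
                                buffer_m = 5000,
                                multiplicative_factor = 12,
                                overrides = c("Microtus abbreviatus" = 8,
                                              "Microtus longicaudus" = 15)) {
  stopifnot(min_search_distance_m > 0, buffer_m > 0, multiplicative_factor > 0)
  if (length(overrides) && any(overrides <= 0))
    stop("concave_hull_params: overrides must be positive", call. = FALSE)
  structure(list(min_search_distance_m = min_search_distance_m,
                 buffer_m = buffer_m,
                 multiplicative_factor = multiplicative_factor,
                 overrides = overrides),
            class = "concave_hull_params")
}

#' Resolve the multiplicative factor for one species
#' @param params A [concave_hull_params()].
#' @param species Species name.
#' @return `params` with `multiplicative_factor` replaced by the species
#'   override when one exists.
#' @export
apply_factor_overrides <- function(params, species) {
  if (species %in% names(params$overrides))
    params$multiplicative_factor <- unname(params$overrides[[species]])
  params
}

#' Aggregation distance for the concave-hull edge-pruning rule
#'
#' `multiplicative_factor * max(min_search_distance_m, median nearest-
#' neighbour distance)` over the projected points. Exposed separately so the
#' rule is unit-testable.
#'
#' @param xy Two-column matrix of projected point coordinates (m).
#' @param params A [concave_hull_params()].
#' @return Aggregation distance in meters.
#' @export
aggregation_distance <- function(xy, params) {
  xy <- unique(as.matrix(xy))
  if (nrow(xy) < 2L)
    stop("aggregation_distance: undefined for fewer than 2 distinct points", call. = FALSE)
  nn <- spatstat.geom::nndist(xy[, 1], xy[, 2])
  params$multiplicative_factor * max(params$min_search_distance_m, stats::median(nn))
}

#' Build a current concave-hull range from an occurrence set
#'
#' Delaunay-triangulates the projected points, discards triangles with any
#' edge longer than the [aggregation_distance()], unions the survivors
#' together with the points left uncovered by any surviving triangle, and
#' dilates the union by `buffer_m`. A single point (or fully coincident set)
#' yields a disk of radius `buffer_m`.
#'
#' @param points Occurrence tibble (with `longitude`/`latitude`) or lon/lat
#'   matrix. Records flagged dubious or without coordinates are excluded.
#' @param spec A [projection_spec()].
#' @param params A [concave_hull_params()]; per-species overrides are applied.
#' @param species Species name recorded on the output.
#' @return A `range_polygon` with provenance `"CONCAVE_CURRENT"`.
#' @export
build_concave_range <- function(points, spec, params = concave_hull_params(),
                                species = "unknown") {
  if (is.data.frame(points) && "flags" %in% names(points))
    points <- points[occ_analyzable(points), , drop = FALSE]
  params <- apply_factor_overrides(params, species)
  xy <- unique(.points_to_xy(points, spec))
  if (nrow(xy) == 0L) stop("build_concave_range: no usable coordinates", call. = FALSE)
  if (nrow(xy) == 1L) {
    geom <- pp_circle(xy[1, 1], xy[1, 2], params$buffer_m)
    return(range_polygon(species, "CONCAVE_CURRENT", geom, spec))
  }
  agg <- aggregation_distance(xy, params)
  tris <- .pruned_triangles(xy, agg)
  pieces <- tris$polys
  # points not covered by a surviving triangle contribute a small seed disk;
  # the shared buffer_m dilation below turns each into a buffer_m disk
  uncovered <- setdiff(seq_len(nrow(xy)), tris$covered)
  for (i in uncovered)
    pieces[[length(pieces) + 1L]] <- unclass(pp_circle(xy[i, 1], xy[i, 2], 1, n = 24L))[[1]]
  u <- structure(polyclip::polyclip(pieces, pieces, op = "union",
                                    fillA = "nonzero", fillB = "nonzero"),
                 class = "planar_poly")
  geom <- pp_buffer(u, params$buffer_m)
  range_polygon(species, "CONCAVE_CURRENT", geom, spec)
}

# Delaunay triangles with all edges <= agg, as polyclip-ready rings, plus the
# indices of points touched by at least one surviving triangle.
.pruned_triangles <- function(xy, agg) {
  dd <- deldir::deldir(xy[, 1], xy[, 2], suppressMsge = TRUE)
  tl <- deldir::triang.list(dd)
  polys <- list(); covered <- integer()
  for (tr in tl) {
    ex <- tr$x; ey <- tr$y
    e <- sqrt((ex - c(ex[-1], ex[1]))^2 + (ey - c(ey[-1], ey[1]))^2)
    if (all(e <= agg)) {
      if (ring_signed_area(list(x = ex, y = ey)) < 0) { ex <- rev(ex); ey <- rev(ey) }
      polys[[length(polys) + 1L]] <- list(x = ex, y = ey)
      covered <- c(covered, tr$ptNum)
    }
  }
  list(polys = polys, covered = unique(covered))
}

# ---- displacement primitive -------------------------------------------------

#' Distance and bearing from a range boundary to points
#'
#' For each projected point, reports whether it lies inside (or on the
#' boundary of) the polygon; for outside points, the minimum planar distance
#' to the boundary and the geographic bearing (degrees clockwise from north)
#' *from* the nearest boundary point *to* the occurrence point.
#'
#' @param xy Two-column matrix of projected point coordinates (m).
#' @param polygon A `planar_poly` or `range_polygon`.
#' @return A tibble with columns `inside`, `distance_km`, `bearing_deg`,
#'   `anchor_x`, `anchor_y` (`distance_km` 0 and `bearing_deg` `NA` for
#'   inside points).
#' @export
boundary_displacement <- function(xy, polygon) {
  if (inherits(polygon, "range_polygon")) polygon <- polygon$geometry
  polygon <- as_planar_poly(polygon)
  if (length(polygon) == 0L) stop("boundary_displacement: empty polygon", call. = FALSE)
  xy <- as.matrix(xy)
  if (ncol(xy) != 2L) xy <- matrix(xy, ncol = 2L)
  inside <- pp_contains(polygon, xy[, 1], xy[, 2])
  out <- tibble::tibble(inside = inside,
                        distance_km = 0,
                        bearing_deg = NA_real_,
                        anchor_x = NA_real_, anchor_y = NA_real_)
  if (any(!inside)) {
    nb <- pp_nearest_boundary(polygon, xy[!inside, 1], xy[!inside, 2])
    out$distance_km[!inside] <- nb$dist / 1000
    out$bearing_deg[!inside] <- planar_bearing_deg(nb$bx, nb$by,
                                                   xy[!inside, 1], xy[!inside, 2])
    out$anchor_x[!inside] <- nb$bx
    out$anchor_y[!inside] <- nb$by
  }
  out
}
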