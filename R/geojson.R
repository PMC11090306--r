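# GeoJSON interchange for polygon layers. Geometries are stored on disk as
# WGS84 FeatureCollections (RFC 7946 ring orientation: exterior CCW, holes
# CW — the same convention the planar representation uses) and projected
# into the planar frame on read.

# Group normalized rings into MultiPolygon nesting: each outer ring with the
# holes it contains.
.rings_to_multipoly <- function(poly) {
  poly <- pp_normalize(poly)
  outers <- Filter(function(r) ring_signed_area(r) > 0, poly)
  holes <- Filter(function(r) ring_signed_area(r) < 0, poly)
  lapply(outers, function(o) {
    mine <- Filter(function(h) all(pp_contains(planar_poly(list(o)), h$x, h$y)), holes)
    c(list(o), mine)
  })
}

.ring_to_coords <- function(r) {
  # close the ring per GeoJSON
  m <- cbind(c(r$x, r$x[1]), c(r$y, r$y[1]))
  lapply(seq_len(nrow(m)), function(i) c(m[i, 1], m[i, 2]))
}

.poly_to_geojson_geom <- function(poly_lonlat) {
  parts <- .rings_to_multipoly(poly_lonlat)
  coords <- lapply(parts, function(rings) lapply(rings, .ring_to_coords))
  if (length(coords) == 1L) {
    list(type = "Polygon", coordinates = coords[[1]])
  } else {
    list(type = "MultiPolygon", coordinates = coords)
  }
}

.geojson_geom_to_poly <- function(geom) {
  coords <- geom$coordinates
  if (identical(geom$type, "Polygon")) coords <- list(coords)
  else if (!identical(geom$type, "MultiPolygon"))
    stop("GeoJSON geometry type not supported: ", geom$type, call. = FALSE)
  rings <- list()
  for (part in coords) {
    for (ring in part) {
      m <- do.call(rbind, lapply(ring, function(p) as.numeric(p[1:2])))
      # drop the closing vertex
      if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
      rings[[length(rings) + 1L]] <- list(x = m[, 1], y = m[, 2])
    }
  }
  planar_poly(rings)
}

#' Write polygon features to GeoJSON
#'
#' Geometries (planar meters) are re-projected to WGS84 lon/lat on write.
#'
#' @param geometries List of `planar_poly` objects.
#' @param properties A data.frame of feature properties, one row per
#'   geometry.
#' @param path Output path.
#' @param spec The [projection_spec()] of the planar frame.
#' @export
write_geojson <- function(geometries, properties, path, spec) {
  stopifnot(length(geometries) == nrow(properties))
  features <- lapply(seq_along(geometries), function(i) {
    ll <- unproject_poly(geometries[[i]], spec)
    props <- as.list(properties[i, , drop = FALSE])
    props <- lapply(props, function(v) if (is.factor(v)) as.character(v) else v)
    list(type = "Feature", properties = props,
         geometry = .poly_to_geojson_geom(ll))
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = 10, pretty = FALSE)
  invisible(path)
}

#' Read polygon features from GeoJSON
#'
#' @param path Path to a GeoJSON FeatureCollection of (Multi)Polygons in
#'   WGS84 lon/lat.
#' @param spec The [projection_spec()] to project geometries into.
#' @return A list with `properties` (tibble) and `geometries` (list of
#'   `planar_poly` in projected meters).
#' @export
read_geojson <- function(path, spec) {
  fc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(fc$type, "FeatureCollection"))
    stop("read_geojson: not a FeatureCollection: ", path, call. = FALSE)
  geoms <- list(); props <- list()
  for (f in fc$features) {
    ll <- .geojson_geom_to_poly(f$geometry)
    geoms[[length(geoms) + 1L]] <- project_poly(ll, spec)
    props[[length(props) + 1L]] <-
      tibble::as_tibble(lapply(f$properties, function(v) if (is.null(v)) NA else v))
  }
  list(properties = dplyr::bind_rows(props), geometries = geoms)
}

#' Write range polygons to GeoJSON
#'
#' Features carry `species`, `provenance`, and `area_km2` properties.
#' @param ranges A list of `range_polygon` objects (sharing one projection).
#' @param path Output path.
#' @export
write_ranges_geojson <- function(ranges, path) {
  if (inherits(ranges, "range_polygon")) ranges <- list(ranges)
  props <- tibble::tibble(
    species = vapply(ranges, `[[`, character(1), "species"),
    provenance = vapply(ranges, `[[`, character(1), "provenance"),
    area_km2 = vapply(ranges, `[[`, numeric(1), "area_km2"))
  write_geojson(lapply(ranges, `[[`, "geometry"), props, path,
                ranges[[1]]$spec)
}

#' Read range polygons from GeoJSON
#' @param path Path written by [write_ranges_geojson()].
#' @param spec The [projection_spec()] to project into.
#' @return A list of `range_polygon` objects.
#' @export
read_ranges_geojson <- function(path, spec) {
  gj <- read_geojson(path, spec)
  lapply(seq_along(gj$geometries), function(i) {
    range_polygon(gj$properties$species[i], gj$properties$provenance[i],
                  gj$geometries[[i]], spec)
  })
}
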