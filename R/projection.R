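# Map projections. The pipeline's contract is "planar meters after
# projection": every distance, bearing, and area is computed in one projected
# frame per study region. Two projections are provided, implemented from the
# standard conic/azimuthal equal-area formulas (Snyder 1987):
#
#   * albers_equal_area — ellipsoidal Albers equal-area conic on GRS80, the
#     projection family used for Alaska statewide mapping (NAD83 Alaska
#     Albers, EPSG:3338, is the default parameterization).
#   * local_azimuthal  — spherical Lambert azimuthal equal-area on the
#     authalic sphere, centered on a study region; used by the synthetic
#     scenario generator.

GRS80_A  <- 6378137
GRS80_F  <- 1 / 298.257222101
R_AUTH   <- 6371007.1809  # authalic radius of GRS80

#' Projection specification
#'
#' @param kind `"albers_equal_area"` or `"local_azimuthal"`.
#' @param lon0,lat0 Longitude/latitude of the projection origin (decimal
#'   degrees).
#' @param lat1,lat2 Standard parallels (Albers only).
#' @param x0,y0 False easting/northing in meters.
#' @return An object of class `projection_spec`.
#' @seealso [alaska_albers()], [local_azimuthal()]
#' @export
projection_spec <- function(kind = c("albers_equal_area", "local_azimuthal"),
                            lon0, lat0, lat1 = NULL, lat2 = NULL,
                            x0 = 0, y0 = 0) {
  kind <- match.arg(kind)
  if (kind == "albers_equal_area" && (is.null(lat1) || is.null(lat2)))
    stop("albers_equal_area needs standard parallels lat1 and lat2", call. = FALSE)
  structure(list(kind = kind, lon0 = lon0, lat0 = lat0,
                 lat1 = lat1, lat2 = lat2, x0 = x0, y0 = y0),
            class = "projection_spec")
}

#' NAD83 Alaska Albers projection (EPSG:3338 parameterization)
#' @return A `projection_spec`.
#' @export
alaska_albers <- function() {
  projection_spec("albers_equal_area", lon0 = -154, lat0 = 50,
                  lat1 = 55, lat2 = 65)
}

#' Local azimuthal equal-area projection centered on a study region
#' @param lon0,lat0 Projection center in decimal degrees.
#' @return A `projection_spec`.
#' @export
local_azimuthal <- function(lon0, lat0) {
  projection_spec("local_azimuthal", lon0 = lon0, lat0 = lat0)
}

#' @export
print.projection_spec <- function(x, ...) {
  cat(sprintf("<projection_spec: %s, origin (%.4f, %.4f)>\n",
              x$kind, x$lon0, x$lat0))
  invisible(x)
}

# ---- Albers (ellipsoidal) ---------------------------------------------------

.albers_consts <- function(spec) {
  e2 <- GRS80_F * (2 - GRS80_F)
  e <- sqrt(e2)
  mfun <- function(phi) cos(phi) / sqrt(1 - e2 * sin(phi)^2)
  qfun <- function(phi) {
    s <- sin(phi)
    (1 - e2) * (s / (1 - e2 * s^2) - (1 / (2 * e)) * log((1 - e * s) / (1 + e * s)))
  }
  p1 <- spec$lat1 * pi / 180; p2 <- spec$lat2 * pi / 180
  p0 <- spec$lat0 * pi / 180
  m1 <- mfun(p1); m2 <- mfun(p2)
  q1 <- qfun(p1); q2 <- qfun(p2); q0 <- qfun(p0)
  n <- (m1^2 - m2^2) / (q2 - q1)
  C <- m1^2 + n * q1
  rho0 <- GRS80_A * sqrt(C - n * q0) / n
  list(e = e, e2 = e2, n = n, C = C, rho0 = rho0, qfun = qfun)
}

.albers_fwd <- function(lon, lat, spec) {
  k <- .albers_consts(spec)
  lam <- (lon - spec$lon0) * pi / 180
  phi <- lat * pi / 180
  q <- k$qfun(phi)
  rho <- GRS80_A * sqrt(k$C - k$n * q) / k$n
  th <- k$n * lam
  cbind(x = rho * sin(th) + spec$x0,
        y = k$rho0 - rho * cos(th) + spec$y0)
}

.albers_inv <- function(x, y, spec) {
  k <- .albers_consts(spec)
  x <- x - spec$x0; y <- y - spec$y0
  rho <- sqrt(x^2 + (k$rho0 - y)^2)
  th <- atan2(sign(k$n) * x, sign(k$n) * (k$rho0 - y))
  q <- (k$C - rho^2 * k$n^2 / GRS80_A^2) / k$n
  # iterate for phi (Snyder 3-16)
  phi <- asin(pmin(1, pmax(-1, q / 2)))
  e <- k$e; e2 <- k$e2
  for (i in 1:8) {
    s <- sin(phi)
    phi <- phi + (1 - e2 * s^2)^2 / (2 * cos(phi)) *
      (q / (1 - e2) - s / (1 - e2 * s^2) +
         (1 / (2 * e)) * log((1 - e * s) / (1 + e * s)))
  }
  cbind(lon = spec$lon0 + th / k$n * 180 / pi,
        lat = phi * 180 / pi)
}

# ---- local azimuthal equal-area (spherical, authalic radius) ----------------

.laea_fwd <- function(lon, lat, spec) {
  lam <- (lon - spec$lon0) * pi / 180
  phi <- lat * pi / 180
  phi1 <- spec$lat0 * pi / 180
  denom <- 1 + sin(phi1) * sin(phi) + cos(phi1) * cos(phi) * cos(lam)
  if (any(denom <= 1e-12))
    stop("local_azimuthal: point antipodal to projection origin", call. = FALSE)
  kp <- sqrt(2 / denom)
  cbind(x = R_AUTH * kp * cos(phi) * sin(lam) + spec$x0,
        y = R_AUTH * kp * (cos(phi1) * sin(phi) - sin(phi1) * cos(phi) * cos(lam)) + spec$y0)
}

.laea_inv <- function(x, y, spec) {
  x <- x - spec$x0; y <- y - spec$y0
  phi1 <- spec$lat0 * pi / 180
  rho <- sqrt(x^2 + y^2)
  lon <- numeric(length(x)); lat <- numeric(length(x))
  zero <- rho < 1e-9
  cc <- 2 * asin(pmin(1, rho / (2 * R_AUTH)))
  lat <- ifelse(zero, spec$lat0,
                asin(cos(cc) * sin(phi1) + y * sin(cc) * cos(phi1) / ifelse(zero, 1, rho)) * 180 / pi)
  lon <- ifelse(zero, spec$lon0,
                spec$lon0 + atan2(x * sin(cc),
                                  rho * cos(phi1) * cos(cc) - y * sin(phi1) * sin(cc)) * 180 / pi)
  cbind(lon = lon, lat = lat)
}

# ---- public API -------------------------------------------------------------

#' Project longitude/latitude to planar meters
#'
#' @param lonlat A two-column matrix or data.frame of WGS84/NAD83 longitudes
#'   and latitudes in decimal degrees.
#' @param spec A [projection_spec()].
#' @return A two-column matrix with columns `x`, `y` (meters).
#' @export
project_points <- function(lonlat, spec) {
  lonlat <- as.matrix(lonlat)
  lon <- as.numeric(lonlat[, 1]); lat <- as.numeric(lonlat[, 2])
  bad <- !is.finite(lon) | !is.finite(lat) | abs(lat) > 89.9 | abs(lon) > 360
  if (any(bad))
    stop(sprintf("project_points: coordinate outside projection domain at row %d (%.4f, %.4f)",
                 which(bad)[1], lon[which(bad)[1]], lat[which(bad)[1]]), call. = FALSE)
  switch(spec$kind,
         albers_equal_area = .albers_fwd(lon, lat, spec),
         local_azimuthal   = .laea_fwd(lon, lat, spec))
}

#' Inverse projection from planar meters to longitude/latitude
#'
#' @param xy A two-column matrix or data.frame of planar coordinates (m).
#' @param spec A [projection_spec()].
#' @return A two-column matrix with columns `lon`, `lat` (decimal degrees).
#' @export
unproject_points <- function(xy, spec) {
  xy <- as.matrix(xy)
  x <- as.numeric(xy[, 1]); y <- as.numeric(xy[, 2])
  switch(spec$kind,
         albers_equal_area = .albers_inv(x, y, spec),
         local_azimuthal   = .laea_inv(x, y, spec))
}

# Project a lon/lat ring list to a planar_poly and back.
project_poly <- function(poly_lonlat, spec) {
  rings <- lapply(unclass(as_planar_poly(poly_lonlat)), function(r) {
    m <- project_points(cbind(r$x, r$y), spec)
    list(x = m[, 1], y = m[, 2])
  })
  planar_poly(rings)
}

unproject_poly <- function(poly_planar, spec) {
  rings <- lapply(unclass(as_planar_poly(poly_planar)), function(r) {
    m <- unproject_points(cbind(r$x, r$y), spec)
    list(x = m[, 1], y = m[, 2])
  })
  planar_poly(rings)
}
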