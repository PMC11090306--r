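#' @title Planar polygon primitives
#'
#' @description
#' All metric computation in extralimitr happens in a single projected planar
#' frame (meters). Polygons are represented as plain lists of rings, each ring
#' a `list(x =, y =)` of vertex coordinates (not closed; the last vertex is
#' implicitly joined to the first). Outer rings are counter-clockwise
#' (positive signed area), holes clockwise (negative), the same convention
#' polyclip and GeoJSON use.
#'
#' @name planar-geometry
#' @keywords internal
NULL

# ---- construction -----------------------------------------------------------

#' Construct a planar multipolygon
#'
#' @param rings A single ring (`list(x=, y=)`) or a list of rings. Rings with
#'   positive signed area are outer boundaries, negative ones holes.
#' @return An object of class `planar_poly` (a normalized list of rings).
#' @export
planar_poly <- function(rings) {
  if (is.list(rings) && !is.null(rings$x)) rings <- list(rings)
  if (length(rings) == 0L) stop("planar_poly: empty geometry", call. = FALSE)
  for (r in rings) {
    if (is.null(r$x) || is.null(r$y) || length(r$x) != length(r$y))
      stop("planar_poly: each ring needs equal-length x and y", call. = FALSE)
    if (length(r$x) < 3L)
      stop("planar_poly: rings need at least 3 vertices", call. = FALSE)
    if (!all(is.finite(r$x)) || !all(is.finite(r$y)))
      stop("planar_poly: non-finite coordinates", call. = FALSE)
  }
  structure(lapply(rings, function(r) list(x = as.numeric(r$x), y = as.numeric(r$y))),
            class = "planar_poly")
}

as_planar_poly <- function(p) {
  if (inherits(p, "planar_poly")) p else planar_poly(p)
}

#' @export
print.planar_poly <- function(x, ...) {
  a <- pp_area(x)
  cat(sprintf("<planar_poly: %d ring(s), area %.6g km^2>\n",
              length(x), a / 1e6))
  invisible(x)
}

#' Axis-aligned rectangle polygon
#' @param xmin,xmax,ymin,ymax Rectangle bounds in planar meters.
#' @return A `planar_poly`.
#' @export
pp_rect <- function(xmin, xmax, ymin, ymax) {
  planar_poly(list(x = c(xmin, xmax, xmax, xmin), y = c(ymin, ymin, ymax, ymax)))
}

#' Regular-polygon approximation of a circle
#' @param cx,cy Center in planar meters.
#' @param r Radius (m).
#' @param n Number of vertices.
#' @return A `planar_poly`.
#' @export
pp_circle <- function(cx, cy, r, n = 180L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  planar_poly(list(x = cx + r * cos(th), y = cy + r * sin(th)))
}

#' Ellipse polygon
#' @param cx,cy Center (m); `a`,`b` semi-axes (m); `rot` rotation (radians);
#'   `n` vertices.
#' @return A `planar_poly`.
#' @export
pp_ellipse <- function(cx, cy, a, b, rot = 0, n = 180L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  ex <- a * cos(th); ey <- b * sin(th)
  planar_poly(list(x = cx + ex * cos(rot) - ey * sin(rot),
                   y = cy + ex * sin(rot) + ey * cos(rot)))
}

# ---- area -------------------------------------------------------------------

ring_signed_area <- function(r) {
  x <- r$x; y <- r$y
  sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
}

# Normalize arbitrary (possibly mis-oriented / self-overlapping) rings to a
# clean even-odd-free representation via a nonzero-fill self-union.
pp_normalize <- function(poly) {
  poly <- as_planar_poly(poly)
  out <- polyclip::polyclip(unclass(poly), unclass(poly), op = "union",
                            fillA = "nonzero", fillB = "nonzero")
  if (length(out) == 0L) return(structure(list(), class = "planar_poly"))
  structure(out, class = "planar_poly")
}

#' Planar area of a multipolygon in square meters
#'
#' Holes are subtracted. Mis-oriented rings are repaired first (absolute-area
#' convention via a nonzero-fill self-union).
#' @param poly A `planar_poly`.
#' @return Area in m^2.
#' @export
pp_area <- function(poly) {
  poly <- pp_normalize(poly)
  if (length(poly) == 0L) return(0)
  sum(vapply(poly, ring_signed_area, numeric(1)))
}

# ---- boolean operations -----------------------------------------------------

#' Union of planar polygons
#' @param polys A list of `planar_poly` objects (or a single one).
#' @return A `planar_poly` multipolygon.
#' @export
pp_union <- function(polys) {
  if (inherits(polys, "planar_poly")) polys <- list(polys)
  rings <- unlist(lapply(polys, unclass), recursive = FALSE)
  out <- polyclip::polyclip(rings, rings, op = "union",
                            fillA = "nonzero", fillB = "nonzero")
  structure(out, class = "planar_poly")
}

pp_intersection <- function(a, b) {
  out <- polyclip::polyclip(unclass(as_planar_poly(a)), unclass(as_planar_poly(b)),
                            op = "intersection",
                            fillA = "nonzero", fillB = "nonzero")
  structure(out, class = "planar_poly")
}

pp_difference <- function(a, b) {
  out <- polyclip::polyclip(unclass(as_planar_poly(a)), unclass(as_planar_poly(b)),
                            op = "minus", fillA = "nonzero", fillB = "nonzero")
  structure(out, class = "planar_poly")
}

#' Buffer (dilate) a polygon by a distance
#' @param poly A `planar_poly`.
#' @param dist Buffer distance in meters (positive = outward).
#' @return A `planar_poly`.
#' @export
pp_buffer <- function(poly, dist) {
  poly <- pp_normalize(poly)
  out <- polyclip::polyoffset(unclass(poly), dist, jointype = "round",
                              arctol = max(abs(dist) / 5000, 1e-4))
  structure(out, class = "planar_poly")
}

# Number of disjoint parts: outer rings after normalization.
pp_n_parts <- function(poly) {
  poly <- pp_normalize(poly)
  sum(vapply(poly, function(r) ring_signed_area(r) > 0, logical(1)))
}

pp_bbox <- function(poly) {
  poly <- as_planar_poly(poly)
  xs <- unlist(lapply(poly, `[[`, "x")); ys <- unlist(lapply(poly, `[[`, "y"))
  c(xmin = min(xs), xmax = max(xs), ymin = min(ys), ymax = max(ys))
}

# ---- point-in-polygon -------------------------------------------------------

#' Test points against a multipolygon (boundary counts as inside)
#'
#' Nonzero winding rule over all rings, so holes are honoured.
#' @param poly A `planar_poly`.
#' @param x,y Point coordinates (m), vectorized.
#' @return Logical vector.
#' @export
pp_contains <- function(poly, x, y) {
  poly <- as_planar_poly(poly)
  n <- length(x)
  wind <- integer(n)
  on_bound <- logical(n)
  pts <- list(x = as.numeric(x), y = as.numeric(y))
  for (r in poly) {
    res <- polyclip::pointinpolygon(pts, r)
    on_bound <- on_bound | (res == -1L)
    sgn <- if (ring_signed_area(r) >= 0) 1L else -1L
    wind <- wind + ifelse(res == 1L, sgn, 0L)
  }
  wind > 0L | on_bound
}

# ---- distance to boundary ---------------------------------------------------

# Decompose rings into segments (x0,y0)-(x1,y1).
pp_segments <- function(poly) {
  poly <- as_planar_poly(poly)
  segs <- lapply(poly, function(r) {
    nx <- c(r$x[-1], r$x[1]); ny <- c(r$y[-1], r$y[1])
    cbind(x0 = r$x, y0 = r$y, x1 = nx, y1 = ny)
  })
  do.call(rbind, segs)
}

#' Nearest point on a polygon boundary
#'
#' For each query point, returns the minimum distance to the boundary of the
#' multipolygon and the coordinates of the nearest boundary point.
#' @param poly A `planar_poly`.
#' @param x,y Query point coordinates (m), vectorized.
#' @return A data.frame with columns `dist` (m), `bx`, `by` (nearest boundary
#'   point).
#' @export
pp_nearest_boundary <- function(poly, x, y) {
  segs <- pp_segments(poly)
  dx <- segs[, "x1"] - segs[, "x0"]
  dy <- segs[, "y1"] - segs[, "y0"]
  len2 <- dx * dx + dy * dy
  len2[len2 == 0] <- 1e-300
  n <- length(x)
  dist <- numeric(n); bx <- numeric(n); by <- numeric(n)
  for (i in seq_len(n)) {
    t <- ((x[i] - segs[, "x0"]) * dx + (y[i] - segs[, "y0"]) * dy) / len2
    t <- pmin(1, pmax(0, t))
    px <- segs[, "x0"] + t * dx
    py <- segs[, "y0"] + t * dy
    d2 <- (x[i] - px)^2 + (y[i] - py)^2
    j <- which.min(d2)
    dist[i] <- sqrt(d2[j]); bx[i] <- px[j]; by[i] <- py[j]
  }
  data.frame(dist = dist, bx = bx, by = by)
}

# Geographic bearing (degrees clockwise from north) of the vector from
# (x0,y0) to (x1,y1) in a planar frame with x east, y north.
planar_bearing_deg <- function(x0, y0, x1, y1) {
  b <- atan2(x1 - x0, y1 - y0) * 180 / pi
  (b + 360) %% 360
}
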