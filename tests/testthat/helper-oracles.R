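# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own geometry code paths.

# O(n^2) gift-wrapping (Jarvis march) convex hull; returns vertex rows in
# counter-clockwise order.
giftwrap_hull <- function(xy) {
  xy <- unique(xy)
  n <- nrow(xy)
  start <- which.min(xy[, 2] + 1e-9 * xy[, 1])   # lowest point, ties by x
  hull <- integer(0)
  cur <- start
  repeat {
    hull <- c(hull, cur)
    cand <- 1L
    for (j in seq_len(n)) {
      if (j == cur) next
      if (cand == cur) { cand <- j; next }
      cross <- (xy[cand, 1] - xy[cur, 1]) * (xy[j, 2] - xy[cur, 2]) -
        (xy[cand, 2] - xy[cur, 2]) * (xy[j, 1] - xy[cur, 1])
      d_cand <- sum((xy[cand, ] - xy[cur, ])^2)
      d_j <- sum((xy[j, ] - xy[cur, ])^2)
      if (cross < 0 || (abs(cross) < 1e-9 && d_j > d_cand)) cand <- j
    }
    cur <- cand
    if (cur == start) break
  }
  xy[hull, , drop = FALSE]
}

# minimum distance from a point to a polygon boundary by densifying every
# edge at `spacing` meters and scanning vertices
densified_boundary_dist <- function(poly, px, py, spacing = 1) {
  best <- Inf
  for (r in unclass(poly)) {
    nv <- length(r$x)
    for (i in seq_len(nv)) {
      j <- if (i == nv) 1L else i + 1L
      len <- sqrt((r$x[j] - r$x[i])^2 + (r$y[j] - r$y[i])^2)
      t <- seq(0, 1, length.out = max(2L, ceiling(len / spacing) + 1L))
      xs <- r$x[i] + t * (r$x[j] - r$x[i])
      ys <- r$y[i] + t * (r$y[j] - r$y[i])
      best <- min(best, sqrt(min((px - xs)^2 + (py - ys)^2)))
    }
  }
  best
}

# all-pairs nearest-neighbour distances
allpairs_nn <- function(xy) {
  d <- as.matrix(stats::dist(xy))
  diag(d) <- Inf
  apply(d, 1, min)
}

# Monte-Carlo area of a polygon by point-in-polygon sampling over its bbox
montecarlo_area <- function(poly, n = 1e6, seed = 1) {
  set.seed(seed)
  bb <- c(min(sapply(unclass(poly), function(r) min(r$x))),
          max(sapply(unclass(poly), function(r) max(r$x))),
          min(sapply(unclass(poly), function(r) min(r$y))),
          max(sapply(unclass(poly), function(r) max(r$y))))
  px <- runif(n, bb[1], bb[2]); py <- runif(n, bb[3], bb[4])
  frac <- mean(pp_contains(poly, px, py))
  frac * (bb[2] - bb[1]) * (bb[4] - bb[3])
}

# random simple (star-shaped) polygon around the origin
random_star_polygon <- function(n = 12, rmin = 2000, rmax = 10000, seed = 1) {
  set.seed(seed)
  th <- sort(runif(n, 0, 2 * pi))
  r <- runif(n, rmin, rmax)
  planar_poly(list(x = r * cos(th), y = r * sin(th)))
}

# small occurrence tibble builder
make_occ <- function(lon, lat, species = "Testus testus", unc = NA_real_,
                     year = NA_integer_, flags = "") {
  n <- length(lon)
  tibble::tibble(record_id = sprintf("t%03d", seq_len(n)),
                 species = species, raw_name = species,
                 longitude = lon, latitude = lat,
                 uncertainty_m = rep_len(unc, n),
                 year = rep_len(as.integer(year), n),
                 basis = "specimen", source = "test",
                 flags = rep_len(flags, n))
}
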