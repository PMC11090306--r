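# Synthetic scenario generator. Builds fully specified occurrence sets with
# known ground truth — core ranges, planted inside/marginal/extralimital
# points at controlled distances and bearings, deliberately corrupted
# "dubious" records, and companion hydrologic-unit and management-unit
# layers — so every pipeline stage is testable without external downloads.
#
# One global seed drives an integer-mixed substream per species, so adding a
# species to a config does not perturb the draws of the others.

#' Synthetic scenario configuration
#'
#' All distributions are fully parameterized and all randomness flows from
#' `seed`. Distances are planted relative to each species' core range
#' boundary: `n_inside` points uniform within the core ellipse, `n_marginal`
#' in the `marginal_band_km` just outside it, and `n_extralimital` at
#' distances drawn from `distance` (rejection-enforced above
#' `distance$min_km`) along bearings drawn from `bearing`.
#'
#' @param seed Integer seed (mandatory).
#' @param n_species Number of species.
#' @param n_inside,n_marginal,n_extralimital Planted counts per species.
#' @param core_semi_major_km,core_semi_minor_km Core range ellipse semi-axes.
#' @param species_spacing_km Distance between adjacent species' core centers.
#' @param lon0,lat0 Scenario center (decimal degrees); the planar frame is a
#'   local azimuthal equal-area projection centered here.
#' @param distance Extralimital distance distribution:
#'   `list(kind = "lognormal", meanlog =, sdlog =, min_km =)` or
#'   `list(kind = "fixed", km =)`.
#' @param bearing Bearing distribution: `list(kind = "vonmises", mu_deg =,
#'   kappa =)` or `list(kind = "uniform")`.
#' @param marginal_band_km Two-element range of planted marginal distances
#'   (km outside the boundary); keep inside (0, 4.5] so planted statuses are
#'   unambiguous against the 5 km tolerance.
#' @param year_weights Mixture weights `c(pre =, recent =, missing =)` for
#'   event years (pre-2009, 2009 or later, absent).
#' @param year_pre,year_recent Year ranges for the two mixture components.
#' @param dubious_rate Fraction of records per species corrupted into
#'   dubious records (kinds cycle: longitude sign flip, implausible year,
#'   (0,0) coordinates).
#' @param uncertainty `list(min_m =, max_m =, missing_frac =)` uniform
#'   coordinate-uncertainty distribution with a missing fraction.
#' @param hu_cell_km Hydrologic-unit grid cell size (km).
#' @param n_units Number of synthetic management-unit rectangles.
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(seed,
                            n_species = 5L,
                            n_inside = 200L,
                            n_marginal = 20L,
                            n_extralimital = 25L,
                            core_semi_major_km = 60,
                            core_semi_minor_km = 45,
                            species_spacing_km = 350,
                            lon0 = -150, lat0 = 63,
                            distance = list(kind = "lognormal",
                                            meanlog = log(50), sdlog = 0.3,
                                            min_km = 5.6),
                            bearing = list(kind = "vonmises",
                                           mu_deg = 200, kappa = 4),
                            marginal_band_km = c(0.5, 4.4),
                            year_weights = c(pre = 0.70, recent = 0.25,
                                             missing = 0.05),
                            year_pre = c(1900L, 2008L),
                            year_recent = c(2009L, 2020L),
                            dubious_rate = 0.045,
                            uncertainty = list(min_m = 10, max_m = 4500,
                                               missing_frac = 0.30),
                            hu_cell_km = 50,
                            n_units = 3L) {
  if (missing(seed)) stop("scenario_config: seed is mandatory", call. = FALSE)
  stopifnot(n_species >= 1, n_inside >= 0, n_marginal >= 0, n_extralimital >= 0,
            core_semi_major_km > 0, core_semi_minor_km > 0,
            length(marginal_band_km) == 2, marginal_band_km[1] > 0,
            marginal_band_km[2] <= 4.5, dubious_rate >= 0, dubious_rate < 1,
            hu_cell_km > 0)
  if (identical(distance$kind, "fixed")) {
    if (distance$km <= 5)
      stop("scenario_config: fixed extralimital distance must exceed 5 km", call. = FALSE)
  } else if (identical(distance$kind, "lognormal")) {
    if (is.null(distance$min_km)) distance$min_km <- 5.6
    if (stats::plnorm(distance$min_km, distance$meanlog, distance$sdlog) > 0.99)
      stop("scenario_config: extralimital distance distribution has almost no mass above min_km",
           call. = FALSE)
  } else stop("scenario_config: unknown distance kind", call. = FALSE)
  if (!identical(bearing$kind, "vonmises") && !identical(bearing$kind, "uniform"))
    stop("scenario_config: unknown bearing kind", call. = FALSE)
  w <- year_weights / sum(year_weights)
  structure(list(seed = as.integer(seed), n_species = as.integer(n_species),
                 n_inside = as.integer(n_inside),
                 n_marginal = as.integer(n_marginal),
                 n_extralimital = as.integer(n_extralimital),
                 core_semi_major_km = core_semi_major_km,
                 core_semi_minor_km = core_semi_minor_km,
                 species_spacing_km = species_spacing_km,
                 lon0 = lon0, lat0 = lat0,
                 distance = distance, bearing = bearing,
                 marginal_band_km = marginal_band_km,
                 year_weights = w, year_pre = as.integer(year_pre),
                 year_recent = as.integer(year_recent),
                 dubious_rate = dubious_rate, uncertainty = uncertainty,
                 hu_cell_km = hu_cell_km, n_units = as.integer(n_units)),
            class = "scenario_config")
}

# deterministic per-species substream seed, kept below 2^31
.substream_seed <- function(seed, index) {
  ((as.numeric(seed) %% 100000) * 10007 + index * 7919 + 1) %% 2147483647
}

.species_names <- function(n) sprintf("Simulatus species%02d", seq_len(n))

# planted point at displacement distance d (km) and bearing theta from the
# nearest boundary point of a convex core polygon; iterate a fixed point on
# the launch angle so the realized bearing matches theta.
.plant_outside <- function(core, cx, cy, d_km, theta_deg) {
  d <- d_km * 1000
  a_major <- NULL
  psi <- theta_deg
  p <- c(NA_real_, NA_real_)
  for (iter in 1:8) {
    u <- c(sin(psi * pi / 180), cos(psi * pi / 180))
    # radial launch from center: boundary hit along u, then push out by d
    nb0 <- pp_nearest_boundary(core, cx + u[1] * 1e7, cy + u[2] * 1e7)
    # cheap boundary point along direction: scale center->far point to hull
    p <- c(nb0$bx + u[1] * d, nb0$by + u[2] * d)
    # refine to exact distance from the true nearest boundary point
    for (k in 1:3) {
      nb <- pp_nearest_boundary(core, p[1], p[2])
      v <- c(p[1] - nb$bx, p[2] - nb$by)
      vn <- sqrt(sum(v^2))
      if (vn < 1e-9) v <- u else v <- v / vn
      p <- c(nb$bx + v[1] * d, nb$by + v[2] * d)
    }
    b <- planar_bearing_deg(nb$bx, nb$by, p[1], p[2])
    err <- ((theta_deg - b + 540) %% 360) - 180
    if (abs(err) < 0.01) break
    psi <- (psi + err) %% 360
  }
  p
}

#' Generate a synthetic scenario
#'
#' @param config A [scenario_config()].
#' @return A list of class `synthetic_scenario` with elements `config`,
#'   `spec` (projection), `occurrences` (one tibble, all species),
#'   `marginal` (named list of lon/lat marginal-record matrices — the core
#'   polygon vertices, so [build_mcp()] reconstructs the core),
#'   `core_polys` (named list of planar core polygons), `study_region`
#'   (lon/lat polygon), `hu` ([hu_layer()]), `units`
#'   ([management_layer()]), `grouping` (species -> group), and `truth`
#'   (per-record ground-truth classification).
#' @export
generate_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  spec <- local_azimuthal(config$lon0, config$lat0)
  nsp <- config$n_species
  sp_names <- .species_names(nsp)
  # species core centers on a centered row
  offs <- (seq_len(nsp) - (nsp + 1) / 2) * config$species_spacing_km * 1000
  a <- config$core_semi_major_km * 1000
  b <- config$core_semi_minor_km * 1000
  cores <- stats::setNames(lapply(offs, function(o) pp_ellipse(o, 0, a, b, n = 96L)),
                           sp_names)
  occ_list <- list(); truth_list <- list()
  for (i in seq_len(nsp)) {
    set.seed(.substream_seed(config$seed, i))
    sp <- sp_names[i]; core <- cores[[sp]]; cx <- offs[i]; cy <- 0
    n_in <- config$n_inside; n_mar <- config$n_marginal; n_ex <- config$n_extralimital
    # inside: uniform in the ellipse
    r <- sqrt(stats::runif(n_in)); th <- stats::runif(n_in, 0, 2 * pi)
    pts_in <- cbind(cx + a * r * cos(th), cy + b * r * sin(th))
    # marginal band
    d_mar <- stats::runif(n_mar, config$marginal_band_km[1], config$marginal_band_km[2])
    th_mar <- stats::runif(n_mar, 0, 360)
    pts_mar <- t(vapply(seq_len(n_mar), function(j)
      .plant_outside(core, cx, cy, d_mar[j], th_mar[j]), numeric(2)))
    # extralimital
    d_ex <- .draw_distances(config$distance, n_ex)
    th_ex <- .draw_bearings(config$bearing, n_ex)
    pts_ex <- t(vapply(seq_len(n_ex), function(j)
      .plant_outside(core, cx, cy, d_ex[j], th_ex[j]), numeric(2)))
    xy <- rbind(pts_in,
                if (n_mar) pts_mar else NULL,
                if (n_ex) pts_ex else NULL)
    n <- nrow(xy)
    # years
    comp <- sample(c("pre", "recent", "missing"), n, replace = TRUE,
                   prob = config$year_weights)
    year <- rep(NA_integer_, n)
    year[comp == "pre"] <- sample(seq(config$year_pre[1], config$year_pre[2]),
                                  sum(comp == "pre"), replace = TRUE)
    year[comp == "recent"] <- sample(seq(config$year_recent[1], config$year_recent[2]),
                                     sum(comp == "recent"), replace = TRUE)
    # uncertainty
    unc <- stats::runif(n, config$uncertainty$min_m, config$uncertainty$max_m)
    unc[stats::runif(n) < config$uncertainty$missing_frac] <- NA_real_
    # recompute exact truth displacement against the core polygon; the truth
    # status is derived from this geometry, not the sampling intent (a point
    # sampled uniformly in the exact ellipse can fall a few meters outside
    # the polygonal core, making "marginal_buffer" its true label)
    disp <- boundary_displacement(xy, core)
    status <- ifelse(disp$inside, "inside",
                     ifelse(disp$distance_km > 5, "extralimital",
                            "marginal_buffer"))
    ll <- unproject_points(xy, spec)
    occ <- tibble::tibble(
      record_id = sprintf("S%02d-%05d", i, seq_len(n)),
      species = sp, raw_name = sp,
      longitude = ll[, 1], latitude = ll[, 2],
      uncertainty_m = unc, year = year,
      basis = sample(c("specimen", "tissue", "machine_observation",
                       "human_observation"), n, replace = TRUE),
      source = "synthetic", flags = "")
    truth <- tibble::tibble(
      record_id = occ$record_id, species = sp, status = status,
      distance_km = disp$distance_km, bearing_deg = disp$bearing_deg,
      year = year, excluded = FALSE)
    # corrupt a deterministic subset into dubious records
    n_dub <- round(config$dubious_rate * n)
    if (n_dub > 0) {
      idx <- sort(sample(n, n_dub))
      kinds <- rep(c("lonflip", "year2099", "null_island"), length.out = n_dub)
      for (k in seq_along(idx)) {
        j <- idx[k]
        if (kinds[k] == "lonflip") {
          occ$longitude[j] <- -occ$longitude[j]
        } else if (kinds[k] == "year2099") {
          occ$year[j] <- 2099L
          truth$year[j] <- 2099L
        } else {
          occ$longitude[j] <- 0; occ$latitude[j] <- 0
        }
      }
      truth$excluded[idx] <- TRUE
      truth$status[idx] <- NA_character_
      truth$distance_km[idx] <- NA_real_
      truth$bearing_deg[idx] <- NA_real_
    }
    occ_list[[i]] <- occ; truth_list[[i]] <- truth
  }
  occurrences <- dplyr::bind_rows(occ_list)
  truth <- dplyr::bind_rows(truth_list)
  # layers from a dedicated substream
  set.seed(.substream_seed(config$seed, 0L))
  ext <- .scenario_extent(cores, config)
  study_region <- unproject_poly(pp_rect(ext[1], ext[2], ext[3], ext[4]), spec)
  hu <- .make_hu_grid(ext, config$hu_cell_km)
  units <- .make_units(ext, config$n_units)
  truth$hu_code <- .hu_code_for(ext, config$hu_cell_km,
                                occurrences, truth, spec)
  truth$unit_abbreviations <- .units_for(units, occurrences, truth, spec)
  marginal <- lapply(cores, function(core) {
    ring <- unclass(core)[[1]]
    unproject_points(cbind(ring$x, ring$y), spec)
  })
  grouping <- stats::setNames(rep(c("OrderA", "OrderB"), length.out = nsp), sp_names)
  structure(list(config = config, spec = spec, occurrences = occurrences,
                 marginal = marginal, core_polys = cores,
                 study_region = study_region, hu = hu, units = units,
                 grouping = grouping, truth = truth),
            class = "synthetic_scenario")
}

.draw_distances <- function(distance, n) {
  if (n == 0L) return(numeric(0))
  if (identical(distance$kind, "fixed")) return(rep(distance$km, n))
  out <- numeric(0)
  while (length(out) < n) {
    d <- stats::rlnorm(n, distance$meanlog, distance$sdlog)
    out <- c(out, d[d > distance$min_km])
  }
  out[seq_len(n)]
}

.draw_bearings <- function(bearing, n) {
  if (n == 0L) return(numeric(0))
  if (identical(bearing$kind, "uniform")) stats::runif(n, 0, 360)
  else rvonmises_deg(n, bearing$mu_deg, bearing$kappa)
}

.scenario_extent <- function(cores, config) {
  bb <- sapply(cores, pp_bbox)
  margin <- 250 * 1000   # covers the extralimital distance tail
  c(min(bb["xmin", ]) - margin, max(bb["xmax", ]) + margin,
    min(bb["ymin", ]) - margin, max(bb["ymax", ]) + margin)
}

.make_hu_grid <- function(ext, cell_km) {
  cell <- cell_km * 1000
  xs <- seq(ext[1], ext[2], by = cell)
  ys <- seq(ext[3], ext[4], by = cell)
  nx <- length(xs) - 1L; ny <- length(ys) - 1L
  codes <- character(0); geoms <- list()
  for (iy in seq_len(ny)) for (ix in seq_len(nx)) {
    codes <- c(codes, sprintf("HU%03d%03d", ix, iy))
    geoms[[length(geoms) + 1L]] <- pp_rect(xs[ix], xs[ix + 1], ys[iy], ys[iy + 1])
  }
  hu_layer(codes, geoms)
}

.make_units <- function(ext, n_units) {
  if (n_units == 0L) {
    return(management_layer(tibble::tibble(unit_name = character(),
                                           abbreviation = character(),
                                           agency = character(),
                                           status = character()), list()))
  }
  w <- (ext[2] - ext[1]) / (2 * n_units)
  h <- (ext[4] - ext[3]) / 3
  geoms <- lapply(seq_len(n_units), function(i) {
    x0 <- ext[1] + (2 * i - 1.5) * w
    pp_rect(x0, x0 + w, ext[3] + h, ext[3] + 2 * h)
  })
  units <- tibble::tibble(
    unit_name = sprintf("Synthetic Refuge %d", seq_len(n_units)),
    abbreviation = sprintf("SYN%d", seq_len(n_units)),
    agency = rep(c("FWS", "NPS"), length.out = n_units),
    status = rep(c("NWR", "NP"), length.out = n_units))
  management_layer(units, geoms)
}

# truth HU codes by grid arithmetic (independent of the polygon machinery)
.hu_code_for <- function(ext, cell_km, occurrences, truth, spec) {
  cell <- cell_km * 1000
  usable <- !truth$excluded
  out <- rep(NA_character_, nrow(truth))
  if (!any(usable)) return(out)
  xy <- project_points(cbind(occurrences$longitude[usable],
                             occurrences$latitude[usable]), spec)
  ix <- floor((xy[, 1] - ext[1]) / cell) + 1L
  iy <- floor((xy[, 2] - ext[3]) / cell) + 1L
  nx <- length(seq(ext[1], ext[2], by = cell)) - 1L
  ny <- length(seq(ext[3], ext[4], by = cell)) - 1L
  ok <- ix >= 1L & ix <= nx & iy >= 1L & iy <= ny
  out[usable][ok] <- sprintf("HU%03d%03d", ix[ok], iy[ok])
  out
}

# truth unit memberships by rectangle distance arithmetic (units are
# axis-aligned rectangles, so the 5 km tolerance test is closed-form)
.units_for <- function(units, occurrences, truth, spec, tolerance_km = 5) {
  out <- rep("", nrow(truth))
  usable <- !truth$excluded & truth$status %in% "extralimital"
  if (!any(usable) || nrow(units$units) == 0L) return(out)
  xy <- project_points(cbind(occurrences$longitude[usable],
                             occurrences$latitude[usable]), spec)
  tol <- tolerance_km * 1000
  memb <- rep("", sum(usable))
  for (i in seq_len(nrow(units$units))) {
    bb <- pp_bbox(units$geometries[[i]])
    dx <- pmax(0, pmax(bb["xmin"] - xy[, 1], xy[, 1] - bb["xmax"]))
    dy <- pmax(0, pmax(bb["ymin"] - xy[, 2], xy[, 2] - bb["ymax"]))
    hit <- sqrt(dx^2 + dy^2) <= tol
    memb[hit] <- ifelse(memb[hit] == "", units$units$abbreviation[i],
                        paste(memb[hit], units$units$abbreviation[i], sep = ";"))
  }
  out[usable] <- memb
  out
}

#' Ground-truth classification table of a scenario
#'
#' Returns the embedded truth table in the classifier's output schema for
#' direct comparison with [classify_occurrences()] results.
#' @param scenario A `synthetic_scenario`.
#' @return A tibble with `record_id`, `species`, `status`, `distance_km`,
#'   `bearing_deg`, `year`, `excluded`.
#' @export
scenario_truth <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  scenario$truth[, c("record_id", "species", "status", "distance_km",
                     "bearing_deg", "year", "excluded")]
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat(sprintf("<synthetic_scenario: %d species, %d records, seed %d>\n",
              x$config$n_species, nrow(x$occurrences), x$config$seed))
  invisible(x)
}
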