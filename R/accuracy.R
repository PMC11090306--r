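# Range-map accuracy scoring: sensitivity (fraction of occurrences inside a
# range, with tolerance) and hydrologic-unit (HU) occupancy (fraction of HUs
# intersecting a range that contain at least one record), plus the
# scoreboard summarising a per-species metrics table.

#' Construct a hydrologic-unit layer
#'
#' @param codes Character vector of unique unit codes (HUC8-style).
#' @param geometries List of `planar_poly` geometries (projected meters),
#'   one per code.
#' @return An object of class `hu_layer`.
#' @export
hu_layer <- function(codes, geometries) {
  if (anyDuplicated(codes)) stop("hu_layer: duplicate unit codes", call. = FALSE)
  if (length(codes) != length(geometries))
    stop("hu_layer: codes and geometries differ in length", call. = FALSE)
  structure(list(codes = as.character(codes),
                 geometries = lapply(geometries, as_planar_poly)),
            class = "hu_layer")
}

#' @export
print.hu_layer <- function(x, ...) {
  cat(sprintf("<hu_layer: %d units>\n", length(x$codes))); invisible(x)
}

#' Range-map sensitivity against an occurrence set
#'
#' Sensitivity = occurrences within the range (inside, or at most
#' `tolerance_km` outside its boundary) divided by all analyzable
#' occurrences, as a percentage.
#'
#' @param occ An occurrence tibble for one species.
#' @param range_poly A `range_polygon` to score.
#' @param tolerance_km Spatial tolerance in km (default 5).
#' @param include_flagged Include dubious-flagged records.
#' @return A one-row tibble: `species`, `range_provenance`,
#'   `sensitivity_pct`, `n_in`, `n_total`.
#' @export
sensitivity <- function(occ, range_poly, tolerance_km = 5,
                        include_flagged = FALSE) {
  cl <- classify_occurrences(occ, range_poly, tolerance_km = tolerance_km,
                             include_flagged = include_flagged)
  cl <- cl[!cl$excluded, , drop = FALSE]
  n_total <- nrow(cl)
  n_in <- sum(cl$status %in% c("inside", "marginal_buffer"))
  tibble::tibble(species = occ$species[1],
                 range_provenance = range_poly$provenance,
                 sensitivity_pct = if (n_total > 0) 100 * n_in / n_total else NA_real_,
                 n_in = n_in, n_total = n_total)
}

#' Hydrologic-unit occupancy of a range
#'
#' The denominator is the number of HUs whose geometry intersects the range
#' polygon; the numerator those among them containing at least one
#' occurrence record (a point inside the unit or within `tolerance_km` of
#' it).
#'
#' @param occ An occurrence tibble for one species.
#' @param range_poly A `range_polygon`.
#' @param hus A [hu_layer()] in the same planar frame.
#' @param tolerance_km Spatial tolerance in km (default 5).
#' @param include_flagged Include dubious-flagged records.
#' @return A one-row tibble: `species`, `range_provenance`, `hu_total`,
#'   `hu_occupied`, `hu_occupancy_pct` (`NA` with a warning when the range
#'   intersects no unit).
#' @export
hu_occupancy <- function(occ, range_poly, hus, tolerance_km = 5,
                         include_flagged = FALSE) {
  if (length(hus$codes) == 0L) stop("hu_occupancy: empty HU layer", call. = FALSE)
  in_range <- vapply(hus$geometries, function(g) {
    length(pp_intersection(g, range_poly$geometry)) > 0L
  }, logical(1))
  hu_total <- sum(in_range)
  if (hu_total == 0L) {
    warning("hu_occupancy: range intersects no hydrologic unit for ",
            occ$species[1], call. = FALSE)
    return(tibble::tibble(species = occ$species[1],
                          range_provenance = range_poly$provenance,
                          hu_total = 0L, hu_occupied = 0L,
                          hu_occupancy_pct = NA_real_))
  }
  use <- occ_analyzable(occ, include_flagged = include_flagged)
  xy <- if (any(use))
    project_points(cbind(occ$longitude[use], occ$latitude[use]), range_poly$spec)
  else matrix(numeric(0), ncol = 2)
  tol_m <- tolerance_km * 1000
  occupied <- vapply(which(in_range), function(i) {
    g <- hus$geometries[[i]]
    if (nrow(xy) == 0L) return(FALSE)
    ins <- pp_contains(g, xy[, 1], xy[, 2])
    if (any(ins)) return(TRUE)
    any(pp_nearest_boundary(g, xy[, 1], xy[, 2])$dist <= tol_m)
  }, logical(1))
  tibble::tibble(species = occ$species[1],
                 range_provenance = range_poly$provenance,
                 hu_total = hu_total, hu_occupied = sum(occupied),
                 hu_occupancy_pct = 100 * sum(occupied) / hu_total)
}

#' Scoreboard over a per-species metrics table
#'
#' Tallies a metrics table the way published range-map evaluations are
#' reported: species counts whose sensitivity strictly exceeds ("exceeded")
#' or reaches ("reached", >=) the sensitivity threshold, unweighted mean
#' sensitivity and HU occupancy across species with available values,
#' strict above/below counts for occupancy, and the count of species with at
#' least one extralimital record. Species with missing values are excluded
#' from the corresponding denominators.
#'
#' @param metrics A tibble with columns `species` and any of
#'   `sensitivity_pct`, `hu_occupancy_pct`, `n_total` (record counts, used
#'   for the record-weighted mean), `extralimital_total`.
#' @param sensitivity_threshold_pct Sensitivity threshold (default 90).
#' @param occupancy_threshold_pct Occupancy threshold (default 50).
#' @return A list of class `scoreboard_summary`.
#' @export
scoreboard <- function(metrics, sensitivity_threshold_pct = 90,
                       occupancy_threshold_pct = 50) {
  stopifnot(nrow(metrics) > 0)
  sens <- if ("sensitivity_pct" %in% names(metrics)) metrics$sensitivity_pct else rep(NA_real_, nrow(metrics))
  occ <- if ("hu_occupancy_pct" %in% names(metrics)) metrics$hu_occupancy_pct else rep(NA_real_, nrow(metrics))
  extra <- if ("extralimital_total" %in% names(metrics)) metrics$extralimital_total else rep(NA_real_, nrow(metrics))
  ntot <- if ("n_total" %in% names(metrics)) metrics$n_total else rep(NA_real_, nrow(metrics))
  s <- sens[!is.na(sens)]
  o <- occ[!is.na(occ)]
  w_ok <- !is.na(sens) & !is.na(ntot)
  structure(list(
    n_species = nrow(metrics),
    n_species_with_sensitivity = length(s),
    n_exceeding_sensitivity = sum(s > sensitivity_threshold_pct),
    n_reaching_sensitivity = sum(s >= sensitivity_threshold_pct),
    mean_sensitivity_pct = if (length(s)) mean(s) else NA_real_,
    weighted_mean_sensitivity_pct =
      if (any(w_ok)) sum(sens[w_ok] * ntot[w_ok]) / sum(ntot[w_ok]) else NA_real_,
    n_species_with_occupancy = length(o),
    mean_hu_occupancy_pct = if (length(o)) mean(o) else NA_real_,
    n_above_occupancy_threshold = sum(o > occupancy_threshold_pct),
    n_below_occupancy_threshold = sum(o < occupancy_threshold_pct),
    n_with_extralimitals = sum(!is.na(extra) & extra > 0),
    sensitivity_threshold_pct = sensitivity_threshold_pct,
    occupancy_threshold_pct = occupancy_threshold_pct),
    class = "scoreboard_summary")
}

#' @export
print.scoreboard_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "<scoreboard: %d species; sensitivity > %.1f%% for %d of %d ",
    "(mean %.1f%%); HU occupancy mean %.1f%%, < %.1f%% for %d; ",
    "%d species with extralimital records>\n"),
    x$n_species, x$sensitivity_threshold_pct, x$n_exceeding_sensitivity,
    x$n_species_with_sensitivity, x$mean_sensitivity_pct,
    x$mean_hu_occupancy_pct, x$occupancy_threshold_pct,
    x$n_below_occupancy_threshold, x$n_with_extralimitals))
  invisible(x)
}
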