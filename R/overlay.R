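# Managed-land overlay: attribute extralimital records to management units
# (parks, refuges) with the same spatial tolerance used by every other
# intersection in the pipeline, and emit the species x unit x year-range
# table.

#' Construct a management-unit layer
#'
#' @param units A data.frame with columns `unit_name`, `abbreviation`,
#'   `agency` (`"NPS"`, `"FWS"`, or `"other"`), `status` (e.g., NWR, NM, NP,
#'   NP&P, NHP).
#' @param geometries List of `planar_poly` geometries (projected meters), one
#'   per unit.
#' @return An object of class `management_layer`.
#' @export
management_layer <- function(units, geometries) {
  need <- c("unit_name", "abbreviation", "agency", "status")
  if (!all(need %in% names(units)))
    stop("management_layer: units needs columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (anyDuplicated(units$abbreviation))
    stop("management_layer: duplicate abbreviations", call. = FALSE)
  if (nrow(units) != length(geometries))
    stop("management_layer: units and geometries differ in length", call. = FALSE)
  structure(list(units = tibble::as_tibble(units),
                 geometries = lapply(geometries, as_planar_poly)),
            class = "management_layer")
}

#' @export
print.management_layer <- function(x, ...) {
  cat(sprintf("<management_layer: %d units>\n", nrow(x$units))); invisible(x)
}

#' Attribute extralimital records to management units
#'
#' A record is attributed to every unit whose polygon contains it or lies
#' within `tolerance_km` of it, so one record may hit several units. Year
#' ranges are the min/max event years of the attributed records.
#'
#' @param classified Classification tibble (from [classify_occurrences()],
#'   possibly several species bound together); only extralimital rows are
#'   attributed.
#' @param layer A [management_layer()] in the same planar frame.
#' @param tolerance_km Spatial tolerance in km (default 5; set 0 for strict
#'   containment).
#' @return A tibble with one row per (species, unit): `species`,
#'   `unit_abbreviation`, `first_year`, `last_year`, `year_range`
#'   (formatted `"Y1-Y2"`, or `"Y"` when equal), `n_records`.
#' @export
unit_overlay <- function(classified, layer, tolerance_km = 5) {
  ex <- classified[!classified$excluded &
                     classified$status == "extralimital", , drop = FALSE]
  tol_m <- tolerance_km * 1000
  rows <- list()
  for (i in seq_len(nrow(layer$units))) {
    g <- layer$geometries[[i]]
    if (nrow(ex) == 0L) next
    hit <- pp_contains(g, ex$x_m, ex$y_m)
    if (tol_m > 0 && any(!hit)) {
      d <- pp_nearest_boundary(g, ex$x_m[!hit], ex$y_m[!hit])$dist
      hit[!hit] <- d <= tol_m
    }
    if (!any(hit)) next
    sub <- ex[hit, , drop = FALSE]
    per_sp <- dplyr::group_by(sub, .data$species) |>
      dplyr::summarise(
        first_year = if (all(is.na(.data$year))) NA_integer_ else min(.data$year, na.rm = TRUE),
        last_year = if (all(is.na(.data$year))) NA_integer_ else max(.data$year, na.rm = TRUE),
        n_records = dplyr::n(), .groups = "drop")
    per_sp$unit_abbreviation <- layer$units$abbreviation[i]
    rows[[length(rows) + 1L]] <- per_sp
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(species = character(), unit_abbreviation = character(),
                          first_year = integer(), last_year = integer(),
                          year_range = character(), n_records = integer()))
  }
  out <- dplyr::bind_rows(rows)
  out$year_range <- ifelse(is.na(out$first_year), NA_character_,
                           ifelse(out$first_year == out$last_year,
                                  as.character(out$first_year),
                                  paste0(out$first_year, "-", out$last_year)))
  dplyr::arrange(
    dplyr::select(out, "species", "unit_abbreviation", "first_year",
                  "last_year", "year_range", "n_records"),
    .data$species, .data$unit_abbreviation)
}

#' Pivot a unit overlay into a species x unit matrix
#'
#' @param overlay Output of [unit_overlay()].
#' @return A tibble with one row per unit and one column per species holding
#'   the formatted year range.
#' @export
overlay_matrix <- function(overlay) {
  if (nrow(overlay) == 0L) return(tibble::tibble(unit_abbreviation = character()))
  tidyr::pivot_wider(overlay[, c("unit_abbreviation", "species", "year_range")],
                     names_from = "species", values_from = "year_range")
}
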