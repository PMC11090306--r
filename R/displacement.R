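# Displacement profiles: distances and bearings of extralimital records from
# their baseline range boundary, grouped (typically by taxonomic order) and
# summarised for wind-rose reporting.

#' Long table of extralimital displacements by group and subset
#'
#' One row per extralimital record per subset it belongs to: every record
#' enters the `"all"` subset; records with `year >= cutoff_year` also enter
#' `"recent"`.
#'
#' @param classified Classification tibble (possibly several species bound
#'   together) from [classify_occurrences()].
#' @param grouping Named character vector mapping species to a grouping
#'   variable (e.g., taxonomic order). Species missing from the mapping are
#'   assigned group `"unknown"` with a warning.
#' @param cutoff_year Inclusive cutoff for the recent subset (default 2009).
#' @return A tibble with columns `group`, `subset`, `species`, `record_id`,
#'   `distance_km`, `bearing_deg`, `year`.
#' @export
displacement_table <- function(classified, grouping, cutoff_year = 2009L) {
  ex <- classified[!classified$excluded &
                     classified$status == "extralimital", , drop = FALSE]
  grp <- unname(grouping[ex$species])
  if (any(is.na(grp))) {
    warning("displacement_table: species missing from grouping assigned 'unknown': ",
            paste(unique(ex$species[is.na(grp)]), collapse = ", "), call. = FALSE)
    grp[is.na(grp)] <- "unknown"
  }
  base <- tibble::tibble(group = grp, species = ex$species,
                         record_id = ex$record_id,
                         distance_km = ex$distance_km,
                         bearing_deg = ex$bearing_deg, year = ex$year)
  all_rows <- dplyr::mutate(base, subset = "all")
  recent <- base[!is.na(base$year) & base$year >= cutoff_year, , drop = FALSE]
  recent <- dplyr::mutate(recent, subset = "recent")
  out <- dplyr::bind_rows(all_rows, recent)
  dplyr::select(out, "group", "subset", "species", "record_id",
                "distance_km", "bearing_deg", "year")
}

#' Group displacement summaries
#'
#' Arithmetic mean and sample standard deviation (n-1 denominator) of
#' displacement distances, and a [circular_summary()] of bearings, per
#' (group, subset).
#'
#' @param table Output of [displacement_table()].
#' @param group Optional single group to summarise; default all groups.
#' @return A tibble with one row per (group, subset): `n`,
#'   `mean_distance_km`, `sd_distance_km`, `mean_bearing_deg`,
#'   `circ_sd_deg`, `resultant_length`.
#' @export
group_summary <- function(table, group = NULL) {
  if (!is.null(group)) table <- table[table$group %in% group, , drop = FALSE]
  if (nrow(table) == 0L) stop("group_summary: no rows for group", call. = FALSE)
  dplyr::group_by(table, .data$group, .data$subset) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_distance_km = mean(.data$distance_km),
      sd_distance_km = stats::sd(.data$distance_km),
      cs = list(circular_summary(.data$bearing_deg)),
      .groups = "drop") |>
    dplyr::mutate(
      mean_bearing_deg = vapply(.data$cs, `[[`, numeric(1), "mean_bearing_deg"),
      circ_sd_deg = vapply(.data$cs, `[[`, numeric(1), "circ_sd_deg"),
      resultant_length = vapply(.data$cs, `[[`, numeric(1), "resultant_length")) |>
    dplyr::select(-"cs")
}

#' Wind-rose binning of bearings
#'
#' Partitions `[0, 360)` into `n_sectors` equal sectors (sector `s` spans
#' `[s*360/n, (s+1)*360/n)`) and reports per-sector counts and mean
#' distances.
#'
#' @param table Output of [displacement_table()].
#' @param group Group to bin; `NULL` uses all rows.
#' @param subset `"all"` or `"recent"` (default `"all"`).
#' @param n_sectors Number of sectors (default 16).
#' @return A tibble with `sector`, `from_deg`, `to_deg`, `n`,
#'   `mean_distance_km`.
#' @export
windrose <- function(table, group = NULL, subset = "all", n_sectors = 16L) {
  rows <- table[table$subset == subset, , drop = FALSE]
  if (!is.null(group)) rows <- rows[rows$group %in% group, , drop = FALSE]
  if (nrow(rows) == 0L) stop("windrose: no rows to bin", call. = FALSE)
  width <- 360 / n_sectors
  sec <- floor(rows$bearing_deg / width)
  sec[sec >= n_sectors] <- n_sectors - 1L   # guard bearing == 360 - eps rounding
  out <- tibble::tibble(sector = 0:(n_sectors - 1L))
  out$from_deg <- out$sector * width
  out$to_deg <- out$from_deg + width
  counts <- tabulate(sec + 1L, nbins = n_sectors)
  out$n <- counts
  out$mean_distance_km <- vapply(0:(n_sectors - 1L), function(s) {
    d <- rows$distance_km[sec == s]
    if (length(d)) mean(d) else NA_real_
  }, numeric(1))
  out
}

#' Plot a wind rose of displacement bearings
#'
#' Polar bar chart of sector counts (requires ggplot2).
#' @param table Output of [displacement_table()].
#' @param group,subset,n_sectors Passed to [windrose()].
#' @return A ggplot object.
#' @export
plot_windrose <- function(table, group = NULL, subset = "all", n_sectors = 16L) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_windrose requires ggplot2", call. = FALSE)
  wr <- windrose(table, group = group, subset = subset, n_sectors = n_sectors)
  mid <- (wr$from_deg + wr$to_deg) / 2
  ggplot2::ggplot(wr, ggplot2::aes(x = mid, y = .data$n)) +
    ggplot2::geom_col(width = 360 / n_sectors, fill = "steelblue",
                      colour = "grey30") +
    ggplot2::coord_polar(start = 0, direction = 1) +
    ggplot2::scale_x_continuous(limits = c(0, 360),
                                breaks = c(0, 90, 180, 270),
                                labels = c("N", "E", "S", "W")) +
    ggplot2::labs(x = NULL, y = "records",
                  title = if (is.null(group)) "All groups" else group)
}
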