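# Scenario (de)serialization. A scenario directory holds the standard
# interchange files the pipeline consumes — occurrence CSV, marginal-record
# CSV, GeoJSON layers, truth CSV, and a flat key = value config echo — so
# synthetic data exercises the real readers and writers.

.flatten_config <- function(config) {
  out <- list()
  for (k in names(config)) {
    v <- config[[k]]
    if (is.list(v)) {
      for (k2 in names(v)) out[[paste(k, k2, sep = ".")]] <- v[[k2]]
    } else if (length(v) > 1L) {
      nm <- if (!is.null(names(v))) names(v) else seq_along(v)
      for (j in seq_along(v)) out[[paste(k, nm[j], sep = ".")]] <- v[j]
    } else out[[k]] <- v
  }
  out
}

#' Write a flat key = value config file
#' @param config A [scenario_config()] (or any flat-able named list).
#' @param path Output path.
#' @export
write_config <- function(config, path) {
  fl <- .flatten_config(unclass(config))
  lines <- vapply(names(fl), function(k) {
    v <- fl[[k]]
    sprintf("%s = %s", k, if (is.character(v)) v else format(v, digits = 15))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a flat key = value config file into a scenario config
#' @param path Path written by [write_config()].
#' @return A [scenario_config()].
#' @export
read_scenario_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[[`, character(1), 1L)
  vals <- vapply(kv, function(p) paste(p[-1], collapse = " = "), character(1))
  get1 <- function(k, as = as.numeric) if (k %in% keys) as(vals[keys == k]) else NULL
  num <- function(k) get1(k, as.numeric)
  chr <- function(k) get1(k, as.character)
  dist <- list(kind = chr("distance.kind"))
  if (identical(dist$kind, "fixed")) dist$km <- num("distance.km")
  else {
    dist$meanlog <- num("distance.meanlog"); dist$sdlog <- num("distance.sdlog")
    dist$min_km <- num("distance.min_km")
  }
  brg <- list(kind = chr("bearing.kind"))
  if (identical(brg$kind, "vonmises")) {
    brg$mu_deg <- num("bearing.mu_deg"); brg$kappa <- num("bearing.kappa")
  }
  scenario_config(
    seed = num("seed"), n_species = num("n_species"),
    n_inside = num("n_inside"), n_marginal = num("n_marginal"),
    n_extralimital = num("n_extralimital"),
    core_semi_major_km = num("core_semi_major_km"),
    core_semi_minor_km = num("core_semi_minor_km"),
    species_spacing_km = num("species_spacing_km"),
    lon0 = num("lon0"), lat0 = num("lat0"),
    distance = dist, bearing = brg,
    marginal_band_km = c(num("marginal_band_km.1"), num("marginal_band_km.2")),
    year_weights = c(pre = num("year_weights.pre"),
                     recent = num("year_weights.recent"),
                     missing = num("year_weights.missing")),
    year_pre = c(num("year_pre.1"), num("year_pre.2")),
    year_recent = c(num("year_recent.1"), num("year_recent.2")),
    dubious_rate = num("dubious_rate"),
    uncertainty = list(min_m = num("uncertainty.min_m"),
                       max_m = num("uncertainty.max_m"),
                       missing_frac = num("uncertainty.missing_frac")),
    hu_cell_km = num("hu_cell_km"), n_units = num("n_units"))
}

#' Serialize a scenario to a directory of interchange files
#'
#' Writes `occurrences.csv`, `marginal_records.csv`, `truth.csv`,
#' `hu_layer.geojson`, `management_units.geojson`, `study_region.geojson`,
#' `grouping.csv`, and `config.txt`.
#'
#' @param scenario A `synthetic_scenario`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_occurrences(scenario$occurrences, file.path(dir, "occurrences.csv"))
  marg <- dplyr::bind_rows(lapply(names(scenario$marginal), function(sp) {
    m <- scenario$marginal[[sp]]
    tibble::tibble(species = sp, longitude = m[, 1], latitude = m[, 2])
  }))
  readr::write_csv(marg, file.path(dir, "marginal_records.csv"))
  readr::write_csv(scenario$truth, file.path(dir, "truth.csv"), na = "")
  write_geojson(scenario$hu$geometries,
                data.frame(huc8 = scenario$hu$codes),
                file.path(dir, "hu_layer.geojson"), scenario$spec)
  write_geojson(scenario$units$geometries, as.data.frame(scenario$units$units),
                file.path(dir, "management_units.geojson"), scenario$spec)
  write_geojson(list(project_poly(scenario$study_region, scenario$spec)),
                data.frame(name = "study_region"),
                file.path(dir, "study_region.geojson"), scenario$spec)
  readr::write_csv(tibble::tibble(species = names(scenario$grouping),
                                  group = unname(scenario$grouping)),
                   file.path(dir, "grouping.csv"))
  write_config(scenario$config, file.path(dir, "config.txt"))
  invisible(dir)
}

#' Read a serialized scenario directory
#'
#' Reconstructs the scenario through the package's own readers; regeneration
#' from the embedded config is bit-identical to the original.
#' @param dir Directory written by [write_scenario()].
#' @return A list mirroring `synthetic_scenario` (occurrences, marginal
#'   records, layers, truth, grouping, config, projection spec).
#' @export
read_scenario <- function(dir) {
  config <- read_scenario_config(file.path(dir, "config.txt"))
  spec <- local_azimuthal(config$lon0, config$lat0)
  occ <- read_occurrences(file.path(dir, "occurrences.csv"), split = FALSE)
  marg_tbl <- readr::read_csv(file.path(dir, "marginal_records.csv"),
                              show_col_types = FALSE, progress = FALSE)
  marginal <- lapply(split(marg_tbl, marg_tbl$species), function(d)
    cbind(d$longitude, d$latitude))
  truth <- readr::read_csv(file.path(dir, "truth.csv"), show_col_types = FALSE,
                           progress = FALSE,
                           col_types = readr::cols(
                             record_id = "c", species = "c", status = "c",
                             distance_km = "d", bearing_deg = "d",
                             year = "i", excluded = "l",
                             hu_code = "c", unit_abbreviations = "c"))
  hu_gj <- read_geojson(file.path(dir, "hu_layer.geojson"), spec)
  hu <- hu_layer(hu_gj$properties$huc8, hu_gj$geometries)
  mu_gj <- read_geojson(file.path(dir, "management_units.geojson"), spec)
  units <- management_layer(mu_gj$properties, mu_gj$geometries)
  sr_gj <- read_geojson(file.path(dir, "study_region.geojson"), spec)
  grouping_tbl <- readr::read_csv(file.path(dir, "grouping.csv"),
                                  show_col_types = FALSE, progress = FALSE)
  list(config = config, spec = spec, occurrences = occ, marginal = marginal,
       study_region = unproject_poly(sr_gj$geometries[[1]], spec),
       hu = hu, units = units,
       grouping = stats::setNames(grouping_tbl$group, grouping_tbl$species),
       truth = truth)
}
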