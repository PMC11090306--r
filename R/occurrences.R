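# Occurrence-record ingest, validation, precision filtering, dubious-record
# flagging, and taxonomic harmonization. Records are held in tibbles with one
# row per record and a semicolon-joined `flags` column; no operation ever
# silently drops a row (filters partition, flaggers annotate).

OCC_FLAGS <- c("dubious_coordinates", "dubious_year", "missing_uncertainty",
               "taxonomy_unresolved")

BASIS_LEVELS <- c("specimen", "tissue", "machine_observation",
                  "human_observation", "unknown")

#' Default Darwin Core field mapping
#'
#' Maps the package's internal occurrence fields to Darwin Core column names.
#' Override entries to read tables with non-standard headers.
#' @return Named character vector (internal field -> column name).
#' @export
dwc_fields <- function() {
  c(species = "scientificName",
    latitude = "decimalLatitude",
    longitude = "decimalLongitude",
    uncertainty_m = "coordinateUncertaintyInMeters",
    year = "year",
    basis = "basisOfRecord",
    record_id = "occurrenceID",
    source = "institutionCode")
}

# -- flag helpers (sets kept sorted & unique so flagging is idempotent and
#    serialization is deterministic) ------------------------------------------

flags_add <- function(flags, new, where = TRUE) {
  ifelse(where,
         vapply(strsplit(ifelse(is.na(flags) | flags == "", new, paste(flags, new, sep = ";")), ";"),
                function(f) paste(sort(unique(f)), collapse = ";"), character(1)),
         flags)
}

#' Test whether records carry a given flag
#' @param occ An occurrence tibble.
#' @param flag Flag name (e.g., `"dubious_coordinates"`).
#' @return Logical vector.
#' @export
has_flag <- function(occ, flag) {
  vapply(strsplit(ifelse(is.na(occ$flags), "", occ$flags), ";"),
         function(f) flag %in% f, logical(1))
}

is_dubious <- function(occ) {
  has_flag(occ, "dubious_coordinates") | has_flag(occ, "dubious_year") |
    has_flag(occ, "taxonomy_unresolved")
}

# Records usable for spatial analysis: finite in-bounds coordinates and not
# flagged dubious (the default "verified only" policy; see classify_occurrences).
occ_analyzable <- function(occ, include_flagged = FALSE) {
  ok <- is.finite(occ$longitude) & is.finite(occ$latitude)
  if (!include_flagged) ok <- ok & !is_dubious(occ)
  ok
}

.map_basis <- function(x) {
  key <- tolower(gsub("[^A-Za-z]", "", as.character(x)))
  out <- rep("unknown", length(x))
  out[key %in% c("preservedspecimen", "fossilspecimen", "specimen", "wholespecimen")] <- "specimen"
  out[key %in% c("materialsample", "tissue", "tissuesample")] <- "tissue"
  out[key %in% c("machineobservation")] <- "machine_observation"
  out[key %in% c("humanobservation", "observation")] <- "human_observation"
  out
}

# ---- read / write -----------------------------------------------------------

#' Read a Darwin Core style occurrence table
#'
#' Reads a delimited text table (comma or tab, auto-detected from the header
#' unless `delim` is given) into one occurrence set per species. Rows with
#' unparseable or out-of-bounds coordinates are kept and flagged
#' `dubious_coordinates`, never dropped; input row order is preserved.
#'
#' @param path Path to a UTF-8 delimited text file with a header row.
#' @param field_map Named character vector mapping internal fields to column
#'   names; see [dwc_fields()]. `species`, `latitude`, and `longitude` are
#'   mandatory.
#' @param delim Field delimiter; `NULL` auto-detects `","` vs `"\t"`.
#' @param split If `TRUE` (default) return a named list of per-species
#'   tibbles; otherwise a single tibble.
#' @return A named list of occurrence tibbles (or one tibble), each with
#'   columns `record_id`, `species`, `raw_name`, `longitude`, `latitude`,
#'   `uncertainty_m`, `year`, `basis`, `source`, `flags`.
#' @export
read_occurrences <- function(path, field_map = dwc_fields(), delim = NULL,
                             split = TRUE) {
  if (!file.exists(path)) stop("read_occurrences: file not found: ", path, call. = FALSE)
  if (is.null(delim)) {
    hdr <- readLines(path, n = 1L)
    delim <- if (grepl("\t", hdr)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           progress = FALSE, show_col_types = FALSE)
  for (f in c("species", "latitude", "longitude")) {
    col <- field_map[[f]]
    if (is.null(col) || !(col %in% names(raw)))
      stop(sprintf("read_occurrences: mandatory column '%s' (field '%s') missing", col, f),
           call. = FALSE)
  }
  if (nrow(raw) == 0L) return(if (split) list() else empty_occurrences())
  get <- function(f) {
    col <- field_map[[f]]
    if (!is.null(col) && col %in% names(raw)) raw[[col]] else rep(NA_character_, nrow(raw))
  }
  lat <- suppressWarnings(as.numeric(get("latitude")))
  lon <- suppressWarnings(as.numeric(get("longitude")))
  unc <- suppressWarnings(as.numeric(get("uncertainty_m")))
  yr <- suppressWarnings(as.integer(as.numeric(get("year"))))
  rid <- get("record_id")
  rid <- ifelse(is.na(rid) | rid == "", sprintf("rec%06d", seq_len(nrow(raw))), rid)
  occ <- tibble::tibble(
    record_id = rid,
    species = as.character(get("species")),
    raw_name = as.character(get("species")),
    longitude = lon, latitude = lat,
    uncertainty_m = unc,
    year = yr,
    basis = .map_basis(get("basis")),
    source = as.character(get("source")),
    flags = "")
  bad_coord <- !is.finite(occ$longitude) | !is.finite(occ$latitude) |
    abs(occ$longitude) > 180 | abs(occ$latitude) > 90
  occ$flags <- flags_add(occ$flags, "dubious_coordinates", bad_coord)
  bad_unc <- is.finite(occ$uncertainty_m) & occ$uncertainty_m < 0
  occ$uncertainty_m[bad_unc] <- NA_real_
  if (split) split_occurrences(occ) else occ
}

empty_occurrences <- function() {
  tibble::tibble(record_id = character(), species = character(),
                 raw_name = character(), longitude = numeric(),
                 latitude = numeric(), uncertainty_m = numeric(),
                 year = integer(), basis = character(), source = character(),
                 flags = character())
}

#' Split a combined occurrence table into per-species sets
#' @param occ An occurrence tibble.
#' @return Named list of tibbles, one per species, input order preserved
#'   within species.
#' @export
split_occurrences <- function(occ) {
  sp <- unique(occ$species)
  stats::setNames(lapply(sp, function(s) occ[occ$species == s, , drop = FALSE]), sp)
}

#' Write an occurrence table
#'
#' Writes the cleaned table in the same delimited layout it was read from,
#' with Darwin Core column names plus a semicolon-joined `flags` column.
#' @param occ An occurrence tibble (or list of them, which is row-bound).
#' @param path Output path.
#' @param delim Field delimiter (default comma).
#' @export
write_occurrences <- function(occ, path, delim = ",") {
  if (is.list(occ) && !is.data.frame(occ)) occ <- dplyr::bind_rows(occ)
  fm <- dwc_fields()
  out <- tibble::tibble(
    occurrenceID = occ$record_id,
    scientificName = occ$species,
    decimalLatitude = occ$latitude,
    decimalLongitude = occ$longitude,
    coordinateUncertaintyInMeters = occ$uncertainty_m,
    year = occ$year,
    basisOfRecord = occ$basis,
    institutionCode = occ$source,
    flags = occ$flags)
  readr::write_delim(out, path, delim = delim, na = "")
  invisible(path)
}

# ---- filtering and flagging -------------------------------------------------

#' Partition an occurrence set by coordinate precision
#'
#' Records with reported coordinate uncertainty strictly below
#' `max_uncertainty_m` are kept; records with uncertainty at or above it are
#' dropped (returned separately — the partition conserves every row). Records
#' with no reported uncertainty are kept but flagged `missing_uncertainty`,
#' so the choice is auditable and reversible.
#'
#' @param occ An occurrence tibble.
#' @param max_uncertainty_m Precision cutoff in meters (default 5,000 m,
#'   i.e., "coordinate precision < 5 km").
#' @return A list with elements `kept` and `dropped`.
#' @export
filter_by_precision <- function(occ, max_uncertainty_m = 5000) {
  stopifnot(max_uncertainty_m > 0)
  missing_unc <- !is.finite(occ$uncertainty_m)
  keep <- missing_unc | occ$uncertainty_m < max_uncertainty_m
  occ$flags <- flags_add(occ$flags, "missing_uncertainty", missing_unc)
  list(kept = occ[keep, , drop = FALSE], dropped = occ[!keep, , drop = FALSE])
}

#' Flag dubious occurrence records
#'
#' Adds flags for records outside the study region (beyond `tolerance_km`),
#' with implausible event years, at exactly (0, 0) ("null island"), or with
#' out-of-bounds coordinates. Flagging only — no record is removed, and the
#' operation is idempotent.
#'
#' @param occ An occurrence tibble.
#' @param study_region Optional study-region polygon in lon/lat (a
#'   [planar_poly()] whose coordinates are decimal degrees), or `NULL` to
#'   skip the spatial check.
#' @param spec [projection_spec()] used for the spatial check (required when
#'   `study_region` is given).
#' @param year_bounds Plausible `c(min_year, max_year)` for event years.
#' @param tolerance_km Distance beyond the study region boundary tolerated
#'   before a record is flagged.
#' @return The occurrence tibble with updated `flags`.
#' @export
flag_dubious <- function(occ, study_region = NULL, spec = NULL,
                         year_bounds = c(1700L, 2021L), tolerance_km = 5) {
  stopifnot(year_bounds[1] <= year_bounds[2])
  bad_coord <- !is.finite(occ$longitude) | !is.finite(occ$latitude) |
    abs(occ$longitude) > 180 | abs(occ$latitude) > 90
  null_island <- is.finite(occ$longitude) & is.finite(occ$latitude) &
    occ$longitude == 0 & occ$latitude == 0
  occ$flags <- flags_add(occ$flags, "dubious_coordinates", bad_coord | null_island)
  bad_year <- !is.na(occ$year) & (occ$year < year_bounds[1] | occ$year > year_bounds[2])
  occ$flags <- flags_add(occ$flags, "dubious_year", bad_year)
  if (!is.null(study_region)) {
    if (is.null(spec))
      stop("flag_dubious: a projection_spec is required with study_region", call. = FALSE)
    region <- project_poly(study_region, spec)
    usable <- is.finite(occ$longitude) & is.finite(occ$latitude) &
      abs(occ$longitude) <= 180 & abs(occ$latitude) <= 89.9 & !null_island
    if (any(usable)) {
      xy <- project_points(cbind(occ$longitude[usable], occ$latitude[usable]), spec)
      inside <- pp_contains(region, xy[, 1], xy[, 2])
      d <- rep(0, sum(usable))
      if (any(!inside))
        d[!inside] <- pp_nearest_boundary(region, xy[!inside, 1], xy[!inside, 2])$dist
      out_of_region <- logical(nrow(occ))
      out_of_region[usable] <- !inside & d > tolerance_km * 1000
      occ$flags <- flags_add(occ$flags, "dubious_coordinates", out_of_region)
    }
  }
  occ
}

#' Harmonize species names against a synonym table
#'
#' Replaces each record's species name by the accepted binomial from the
#' synonym table. Names absent from the table are left unchanged and flagged
#' `taxonomy_unresolved`.
#'
#' @param occ An occurrence tibble.
#' @param table A synonym table: a named character vector
#'   (`raw name -> accepted name`) or a two-column data.frame
#'   (`raw`, `accepted`).
#' @return The occurrence tibble with harmonized `species` (and `raw_name`
#'   preserving the as-read names).
#' @export
apply_taxonomy <- function(occ, table) {
  if (is.data.frame(table)) table <- stats::setNames(as.character(table[[2]]),
                                                     as.character(table[[1]]))
  if (anyDuplicated(names(table)))
    stop("apply_taxonomy: synonym table maps a raw name more than once", call. = FALSE)
  mapped <- unname(table[occ$raw_name])
  unresolved <- is.na(mapped)
  occ$species <- ifelse(unresolved, occ$raw_name, mapped)
  occ$flags <- flags_add(occ$flags, "taxonomy_unresolved", unresolved)
  occ
}
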