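world_schema_text <- function() {
  paste(
    "# Synthetic world table schemas",
    "",
    "## grid.csv  (one row per grid cell)",
    "- cell_id        character, unique cell identifier",
    "- country_id     character, EEZ the cell falls in",
    "- ecoregion_id   character, marine ecoregion the cell falls in",
    "- area_km2       double, cell area in km^2",
    "- <layer>_<period>  double, raw threat value of layer <layer> in",
    "                 period <period> (2008 or 2013); one column per layer",
    "                 per period in which it was measured; unitless intensity",
    "",
    "## layer_meta.csv  (one row per threat layer)",
    "- layer_id       character",
    "- category       character: fishing_pressure, benthic_structure,",
    "                 direct_human, climate, land_based, shipping, other",
    "- measured_2008  logical, layer measured in 2008",
    "- measured_2013  logical, layer measured in 2013",
    "- stoppable      logical, abatable by an effectively managed MPA alone",
    "                 (NA until classify_stoppable() is applied)",
    "",
    "## zones.csv  (one row per country x ecoregion unit)",
    "- country_id     character",
    "- ecoregion_id   character",
    "- zone_area_km2  double, zone area in km^2",
    "",
    "## mpas.csv  (one row per MPA x zone allocation)",
    "- mpa_id             character; rows sharing an mpa_id are one MPA",
    "- country_id         character, country of the allocation's zone",
    "- ecoregion_id       character",
    "- allocation_km2     double, area of this MPA inside this zone, km^2",
    "- total_area_km2     double, total MPA area (sum of its allocations)",
    "- iucn_category      character: Ia, Ib, II, III, IV, V, VI,",
    "                     not_applicable, not_reported, not_assigned",
    "- status             character: designated, proposed, ...",
    "- is_unesco_biosphere logical",
    "- has_boundary       logical, delineated boundary data available",
    "- is_marine          logical",
    "- establishment_year integer or empty (missing)",
    sep = "\n"
  )
}

mpa_col_classes <- function() {
  c(mpa_id = "character", country_id = "character",
    ecoregion_id = "character", allocation_km2 = "numeric",
    total_area_km2 = "numeric", iucn_category = "character",
    status = "character", is_unesco_biosphere = "logical",
    has_boundary = "logical", is_marine = "logical",
    establishment_year = "integer")
}

# base read.csv: strtod parses doubles with correct rounding, so values
# written by readr (shortest round-trip representation) are recovered
# exactly
read_csv_exact <- function(path, colClasses) {
  tibble::as_tibble(utils::read.csv(path, colClasses = colClasses,
                                    check.names = FALSE))
}

#' Write a synthetic world to a directory of CSV files
#'
#' Emits `grid.csv`, `layer_meta.csv`, `zones.csv`, `mpas.csv`, the
#' generating configuration as `config.json`, the pre-corruption years as
#' `true_years.csv`, and a `schema.md` documenting all columns and units.
#' Values written by [readr::write_csv()] round-trip exactly through
#' [read_world()].
#'
#' @param world A `synthetic_world`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "synthetic_world"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(world$grid, file.path(dir, "grid.csv"))
  readr::write_csv(world$layer_meta, file.path(dir, "layer_meta.csv"))
  readr::write_csv(world$zones, file.path(dir, "zones.csv"))
  readr::write_csv(world$mpas, file.path(dir, "mpas.csv"))
  readr::write_csv(world$truth$true_years, file.path(dir, "true_years.csv"))
  cfg <- world$truth$config
  cfg$threat_distribution_params <- NULL  # tibble-valued; regenerated on load
  cfg$total_protected_fraction_by_period <-
    as.list(cfg$total_protected_fraction_by_period)
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(world_schema_text(), file.path(dir, "schema.md"))
  invisible(dir)
}

#' Read the synthetic world tables back from a directory
#'
#' @param dir Directory written by [write_world()].
#' @return A list with `grid`, `layer_meta`, `zones`, `mpas` and, when
#'   present, `true_years` and `config` (the reloaded generator settings).
#' @export
read_world <- function(dir) {
  grid_head <- names(utils::read.csv(file.path(dir, "grid.csv"), nrows = 0,
                                     check.names = FALSE))
  grid_classes <- stats::setNames(
    ifelse(grid_head %in% c("cell_id", "country_id", "ecoregion_id"),
           "character", "numeric"),
    grid_head
  )
  out <- list(
    grid = read_csv_exact(file.path(dir, "grid.csv"), grid_classes),
    layer_meta = read_csv_exact(
      file.path(dir, "layer_meta.csv"),
      c(layer_id = "character", category = "character",
        measured_2008 = "logical", measured_2013 = "logical",
        stoppable = "logical")
    ),
    zones = read_csv_exact(
      file.path(dir, "zones.csv"),
      c(country_id = "character", ecoregion_id = "character",
        zone_area_km2 = "numeric")
    ),
    mpas = read_csv_exact(file.path(dir, "mpas.csv"), mpa_col_classes())
  )
  ty <- file.path(dir, "true_years.csv")
  if (file.exists(ty)) {
    out$true_years <- read_csv_exact(
      ty, c(mpa_id = "character", establishment_year = "integer")
    )
  }
  cj <- file.path(dir, "config.json")
  if (file.exists(cj)) {
    raw <- jsonlite::read_json(cj, simplifyVector = TRUE)
    out$config <- do.call(world_config, raw[setdiff(
      names(raw), "threat_distribution_params"
    )])
  }
  out
}
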