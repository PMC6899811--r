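#' Classify threat layers as stoppable or unstoppable
#'
#' A stoppable threat is one that an effectively managed MPA can abate on
#' its own. By default every fishing-pressure, benthic-structure and
#' direct-human-impact layer is stoppable and every other category
#' (climate, land-based, shipping, other) is not, because those threats
#' originate from land or from diffuse sources outside the MPA's control.
#' A rule table can override the default per layer, e.g. to run the
#' fishing-only sensitivity analysis.
#'
#' @param layer_meta Threat-layer metadata with `layer_id` and `category`.
#' @param rule_table Optional two-column table (`layer_id`, `stoppable`)
#'   overriding the category default for the listed layers.
#' @return `layer_meta` with the `stoppable` flag filled in.
#' @export
classify_stoppable <- function(layer_meta, rule_table = NULL) {
  known <- c("fishing_pressure", "benthic_structure", "direct_human",
             "climate", "land_based", "shipping", "other")
  bad <- setdiff(unique(layer_meta$category), known)
  if (length(bad) > 0) {
    stop("unknown threat category: ", paste(bad, collapse = ", "))
  }
  stoppable_cats <- c("fishing_pressure", "benthic_structure", "direct_human")
  layer_meta$stoppable <- layer_meta$category %in% stoppable_cats
  if (!is.null(rule_table)) {
    stopifnot(all(c("layer_id", "stoppable") %in% names(rule_table)))
    missing_ids <- setdiff(rule_table$layer_id, layer_meta$layer_id)
    if (length(missing_ids) > 0) {
      stop("rule_table names unknown layers: ", paste(missing_ids, collapse = ", "))
    }
    idx <- match(rule_table$layer_id, layer_meta$layer_id)
    layer_meta$stoppable[idx] <- as.logical(rule_table$stoppable)
  }
  layer_meta
}

#' The fishing-only sensitivity rule table
#'
#' Marks only fishing-pressure layers as stoppable, for the sensitivity
#' analysis in which benthic structures and direct human impacts are
#' considered too difficult to manage through protection alone.
#'
#' @param layer_meta Threat-layer metadata.
#' @return A rule table usable as `rule_table` in [classify_stoppable()].
#' @export
fishing_only_rule <- function(layer_meta) {
  tibble::tibble(
    layer_id = layer_meta$layer_id,
    stoppable = layer_meta$category == "fishing_pressure"
  )
}

analysis_layers <- function(layer_meta) {
  keep <- layer_meta$measured_2008 & layer_meta$measured_2013
  layer_meta[keep, , drop = FALSE]
}

#' Min-max normalize threat layers across both periods
#'
#' Rescales each layer's cell values to \[0, 1\] using the pooled minimum
#' and maximum over the 2008 and 2013 values together, so that a layer's
#' two periods stay on a common scale. Layers not measured in both periods
#' are dropped from the output (with a message), mirroring the exclusion of
#' the shipping layer from the analysis. A layer that is constant across
#' both periods normalizes to 0 everywhere.
#'
#' @param grid Grid-cell table with `<layer_id>_<period>` value columns.
#' @param layer_meta Threat-layer metadata.
#' @return The grid with normalized value columns for every layer measured
#'   in both periods.
#' @export
normalize_across_periods <- function(grid, layer_meta) {
  dropped <- layer_meta$layer_id[!(layer_meta$measured_2008 & layer_meta$measured_2013)]
  if (length(dropped) > 0) {
    message("dropping layers not measured in both periods: ",
            paste(dropped, collapse = ", "))
    drop_cols <- intersect(
      c(paste0(dropped, "_2008"), paste0(dropped, "_2013")), names(grid)
    )
    grid <- grid[, setdiff(names(grid), drop_cols), drop = FALSE]
  }
  lm2 <- analysis_layers(layer_meta)
  for (lid in lm2$layer_id) {
    cols <- paste0(lid, c("_2008", "_2013"))
    if (!all(cols %in% names(grid))) {
      stop("grid lacks value columns for layer ", lid)
    }
    v <- unlist(grid[, cols], use.names = FALSE)
    if (any(v < 0, na.rm = TRUE)) {
      stop("negative threat values in layer ", lid)
    }
    lo <- min(v)
    hi <- max(v)
    for (cc in cols) {
      grid[[cc]] <- if (hi > lo) (grid[[cc]] - lo) / (hi - lo) else 0
    }
  }
  grid
}

#' Mean stoppable threat per zone
#'
#' Zonal statistics: each cell's score is the unweighted mean of its
#' normalized stoppable-layer values for the requested period; the zone
#' value is the area-weighted mean of cell scores. With `scope = "country"`
#' the zones are country-by-ecoregion units; with `scope = "global"` an
#' ecoregion's cells are pooled across all countries.
#'
#' @param grid Normalized grid ([normalize_across_periods()]).
#' @param layer_meta Layer metadata with stoppable flags assigned
#'   ([classify_stoppable()]).
#' @param zones Zone table (used to check that every zone has cells).
#' @param period `"2008"` or `"2013"`.
#' @param scope `"country"` (default) or `"global"`.
#' @return A tibble with `ecoregion_id`, `mean_stoppable_threat`, `n_cells`
#'   and, for country scope, `country_id`.
#' @export
mean_stoppable_threat <- function(grid, layer_meta, zones,
                                  period = c("2013", "2008"),
                                  scope = c("country", "global")) {
  period <- match.arg(period)
  scope <- match.arg(scope)
  if (all(is.na(layer_meta$stoppable))) {
    stop("stoppable flags not assigned; run classify_stoppable() first")
  }
  lm2 <- analysis_layers(layer_meta)
  stop_ids <- lm2$layer_id[isTRUE_vec(lm2$stoppable)]
  if (length(stop_ids) == 0) stop("no stoppable layers")
  cols <- paste0(stop_ids, "_", period)
  missing_cols <- setdiff(cols, names(grid))
  if (length(missing_cols) > 0) {
    stop("grid lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  score <- rowMeans(as.matrix(grid[, cols, drop = FALSE]))
  keys <- if (scope == "country") c("country_id", "ecoregion_id") else "ecoregion_id"
  df <- tibble::tibble(
    country_id = grid$country_id, ecoregion_id = grid$ecoregion_id,
    area = grid$area_km2, score = score
  )
  out <- dplyr::summarise(
    dplyr::group_by(df, dplyr::across(dplyr::all_of(keys))),
    mean_stoppable_threat = stats::weighted.mean(.data$score, .data$area),
    n_cells = dplyr::n(),
    .groups = "drop"
  )
  # every zone in scope must hold at least one cell
  zk <- dplyr::distinct(zones[, intersect(keys, names(zones)), drop = FALSE])
  empty <- dplyr::anti_join(zk, out, by = keys)
  if (nrow(empty) > 0) {
    stop("zones with zero cells: ",
         paste(apply(empty, 1, paste, collapse = "/"), collapse = ", "))
  }
  out$period <- period
  dplyr::arrange(out, dplyr::across(dplyr::all_of(keys)))
}

isTRUE_vec <- function(x) !is.na(x) & x
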