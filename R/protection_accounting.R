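#' IUCN category groupings
#'
#' The nested management-objective groupings used throughout the analysis:
#' `"I-II"` strict nature reserves (Ia, Ib, II); `"I-IV"` categories
#' primarily designated for biodiversity conservation; `"I-VI"` adds
#' sustainable-use categories; `"all"` additionally keeps MPAs listed as
#' not applicable / not reported / not assigned, i.e. every record that
#' passes the inclusion filters.
#'
#' @param grouping One of `"I-II"`, `"I-IV"`, `"I-VI"`, `"all"`.
#' @return Character vector of member IUCN categories.
#' @export
iucn_members <- function(grouping = c("all", "I-II", "I-IV", "I-VI")) {
  grouping <- match.arg(grouping)
  base <- list(
    "I-II" = c("Ia", "Ib", "II"),
    "I-IV" = c("Ia", "Ib", "II", "III", "IV"),
    "I-VI" = c("Ia", "Ib", "II", "III", "IV", "V", "VI"),
    "all" = c("Ia", "Ib", "II", "III", "IV", "V", "VI",
              "not_applicable", "not_reported", "not_assigned")
  )
  base[[grouping]]
}

#' Filter MPA records for analysis
#'
#' Keeps designated, marine protected areas with delineated boundary data,
#' and drops proposed sites, UNESCO Biosphere reserves and terrestrial
#' records, following the standard WDPA cleaning recommendations.
#'
#' @param mpas MPA table.
#' @return The retained rows.
#' @export
filter_mpas <- function(mpas) {
  keep <- mpas$is_marine &
    mpas$status == "designated" &
    !mpas$is_unesco_biosphere &
    mpas$has_boundary
  mpas[keep, , drop = FALSE]
}

#' Impute missing establishment years
#'
#' For each MPA without an establishment year, draws `n_reps` years with
#' replacement from the donor pool and assigns the (rounded) mean. The
#' donor pool is the set of same-country MPAs with a known year when that
#' pool has at least 5 members, and otherwise all MPAs with a known year.
#' With `per_country = TRUE` (the default) one shared imputed year is
#' computed per country and assigned to all of its missing records; with
#' `per_country = FALSE` each missing record receives its own draw.
#'
#' @param mpas MPA table (allocation rows; year is a record-level field).
#' @param n_reps Number of resampling draws (default 1000).
#' @param seed Integer seed.
#' @param per_country Assign one shared imputed year per country?
#' @param min_country_pool Minimum donor-pool size below which the global
#'   pool is used (default 5).
#' @return The MPA table with all establishment years present.
#' @export
impute_years <- function(mpas, n_reps = 1000, seed = 1L, per_country = TRUE,
                         min_country_pool = 5) {
  recs <- dplyr::distinct(mpas[, c("mpa_id", "country_id", "establishment_year")])
  known <- recs[!is.na(recs$establishment_year), ]
  missing <- recs[is.na(recs$establishment_year), ]
  if (nrow(missing) == 0) return(mpas)
  if (nrow(known) == 0) {
    stop("cannot impute establishment years: no record has a known year")
  }
  set.seed(as.integer(seed))
  global_pool <- known$establishment_year
  draw_mean <- function(country) {
    pool <- known$establishment_year[known$country_id == country]
    if (length(pool) < min_country_pool) pool <- global_pool
    as.integer(round(mean(sample(pool, n_reps, replace = TRUE))))
  }
  imputed <- stats::setNames(rep(NA_integer_, nrow(missing)), missing$mpa_id)
  if (per_country) {
    for (ctry in unique(missing$country_id)) {
      y <- draw_mean(ctry)
      imputed[missing$mpa_id[missing$country_id == ctry]] <- y
    }
  } else {
    for (i in seq_len(nrow(missing))) {
      imputed[missing$mpa_id[i]] <- draw_mean(missing$country_id[i])
    }
  }
  fill <- is.na(mpas$establishment_year)
  mpas$establishment_year[fill] <- imputed[mpas$mpa_id[fill]]
  mpas
}

#' Area and proportion protected per zone
#'
#' Sums the zone allocations of MPAs established by the end of `period`
#' whose IUCN category belongs to `grouping`, and divides by zone area.
#' Proportions are capped at 1 (with a warning reporting the uncapped
#' values) where overlapping designations push a zone past its area. With
#' `scope = "global"`, allocations and areas are pooled per ecoregion
#' across countries.
#'
#' @param mpas Filtered MPA table with all years present.
#' @param zones Zone table.
#' @param period `"2008"` or `"2013"`.
#' @param grouping IUCN grouping (see [iucn_members()]).
#' @param scope `"country"` or `"global"`.
#' @return A tibble with the zone keys, `period`, `iucn_grouping`,
#'   `protected_km2` (capped), `zone_area_km2` and `proportion_protected`.
#' @export
protection_by_zone <- function(mpas, zones, period = c("2013", "2008"),
                               grouping = "all",
                               scope = c("country", "global")) {
  period <- match.arg(period)
  scope <- match.arg(scope)
  members <- iucn_members(grouping)
  if (anyNA(mpas$establishment_year)) {
    stop("MPA table has missing establishment years; run impute_years() first")
  }
  zone_keys <- dplyr::distinct(zones[, c("country_id", "ecoregion_id")])
  unknown <- dplyr::anti_join(
    dplyr::distinct(mpas[, c("country_id", "ecoregion_id")]),
    zone_keys, by = c("country_id", "ecoregion_id")
  )
  if (nrow(unknown) > 0) {
    stop("MPA allocations to unknown zones: ",
         paste(paste(unknown$country_id, unknown$ecoregion_id, sep = "/"),
               collapse = ", "))
  }
  active <- mpas[mpas$iucn_category %in% members &
                   mpas$establishment_year <= as.integer(period), ,
                 drop = FALSE]
  keys <- if (scope == "country") c("country_id", "ecoregion_id") else "ecoregion_id"
  ztab <- dplyr::summarise(
    dplyr::group_by(zones, dplyr::across(dplyr::all_of(keys))),
    zone_area_km2 = sum(.data$zone_area_km2), .groups = "drop"
  )
  ptab <- dplyr::summarise(
    dplyr::group_by(active, dplyr::across(dplyr::all_of(keys))),
    protected_km2 = sum(.data$allocation_km2), .groups = "drop"
  )
  out <- dplyr::left_join(ztab, ptab, by = keys)
  out$protected_km2[is.na(out$protected_km2)] <- 0
  over <- out$protected_km2 > out$zone_area_km2 * (1 + 1e-9)
  if (any(over)) {
    warning(sprintf(
      "%d zone(s) exceed their area before capping (max uncapped proportion %.3f); proportions capped at 1",
      sum(over), max(out$protected_km2 / out$zone_area_km2)
    ))
  }
  out$protected_km2 <- pmin(out$protected_km2, out$zone_area_km2)
  out$proportion_protected <- out$protected_km2 / out$zone_area_km2
  out$period <- period
  out$iucn_grouping <- grouping
  dplyr::arrange(out, dplyr::across(dplyr::all_of(keys)))
}

#' Change in protection between 2008 and 2013
#'
#' Difference of the two period summaries from [protection_by_zone()]:
#' protected area added per zone between 2008 and 2013, and the
#' corresponding change in proportion protected.
#'
#' @inheritParams protection_by_zone
#' @return A tibble with the zone keys, `added_km2` and
#'   `added_proportion`.
#' @export
protection_change <- function(mpas, zones, grouping = "all",
                              scope = c("country", "global")) {
  scope <- match.arg(scope)
  p08 <- protection_by_zone(mpas, zones, "2008", grouping, scope)
  p13 <- protection_by_zone(mpas, zones, "2013", grouping, scope)
  keys <- if (scope == "country") c("country_id", "ecoregion_id") else "ecoregion_id"
  out <- dplyr::left_join(
    p13[, c(keys, "zone_area_km2", "protected_km2", "proportion_protected")],
    p08[, c(keys, "protected_km2", "proportion_protected")],
    by = keys, suffix = c("_2013", "_2008")
  )
  out$added_km2 <- out$protected_km2_2013 - out$protected_km2_2008
  out$added_proportion <- out$proportion_protected_2013 - out$proportion_protected_2008
  out$iucn_grouping <- grouping
  out
}
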