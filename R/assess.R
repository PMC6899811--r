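#' Observed vs random impact metric per country and globally
#'
#' For each country, classifies its ecoregion units as high or low threat
#' (strictly above vs at-or-below the median mean stoppable threat --
#' country-specific median by default), computes the observed impact metric
#' from 2013 protection, runs the random-allocation null with the country's
#' median MPA size, and judges significance against the null's 95% CI.
#' A `GLOBAL` row pools ecoregions across countries and treats the world as
#' one estate with the global median MPA size.
#'
#' @param mpas Filtered MPA table with all establishment years present.
#' @param zones Zone table.
#' @param zone_threat Country-scope output of [mean_stoppable_threat()] for
#'   the period being assessed.
#' @param grouping IUCN grouping (see [iucn_members()]).
#' @param n_sims Simulations per unit (default 1000).
#' @param seed Integer seed; per-country child seeds are derived from it.
#' @param ci_mode CI construction for the null (see
#'   [random_allocation_null()]).
#' @param threat_split `"country"` (default): each country's high/low split
#'   uses its own median threat; `"global"`: all zones are split at the
#'   median across every zone.
#' @param include_global Append the pooled `GLOBAL` row?
#' @return A tibble with one row per country (plus `GLOBAL`): observed and
#'   null impact metrics, CI, verdict, observed and mean random high-threat
#'   protection, class areas, budget and median MPA size.
#' @export
assess_impact <- function(mpas, zones, zone_threat, grouping = "all",
                          n_sims = 1000, seed = 1L,
                          ci_mode = c("normal", "percentile"),
                          threat_split = c("country", "global"),
                          include_global = TRUE) {
  ci_mode <- match.arg(ci_mode)
  threat_split <- match.arg(threat_split)
  prot <- protection_by_zone(mpas, zones, "2013", grouping, "country")
  units <- dplyr::left_join(
    prot,
    zone_threat[, c("country_id", "ecoregion_id", "mean_stoppable_threat")],
    by = c("country_id", "ecoregion_id")
  )
  if (anyNA(units$mean_stoppable_threat)) {
    stop("zones missing from the zone-threat table")
  }
  recs <- dplyr::distinct(mpas[, c("mpa_id", "country_id", "total_area_km2")])
  global_median_pa <- if (nrow(recs) > 0) stats::median(recs$total_area_km2) else NA_real_
  global_med_threat <- stats::median(units$mean_stoppable_threat)

  one_unit <- function(u, label, med_threat, median_pa, unit_seed) {
    cls <- ifelse(u$mean_stoppable_threat > med_threat, "high", "low")
    p_H <- sum(u$protected_km2[cls == "high"])
    p_L <- sum(u$protected_km2[cls == "low"])
    a_H <- sum(u$zone_area_km2[cls == "high"])
    a_L <- sum(u$zone_area_km2[cls == "low"])
    obs <- impact(p_H, p_L, a_H, a_L)
    budget <- p_H + p_L
    if (is.na(median_pa) || median_pa <= 0) median_pa <- max(budget, 1)
    null <- random_allocation_null(u$zone_area_km2, cls, budget, median_pa,
                                   n_sims = n_sims, seed = unit_seed,
                                   ci_mode = ci_mode)
    tibble::tibble(
      country_id = label,
      n_ecoregions = nrow(u),
      observed_I = as.numeric(obs),
      one_sided = attr(obs, "one_sided") | null$one_sided,
      random_mean_I = null$mean_I,
      ci_low = null$ci_low, ci_high = null$ci_high,
      ci_method = null$ci_method, n_sims = n_sims,
      verdict = significance(as.numeric(obs), null),
      observed_high_threat_protection = p_H,
      random_high_threat_protection = null$mean_p_H,
      a_H = a_H, a_L = a_L,
      budget_km2 = budget, median_pa_km2 = median_pa
    )
  }

  countries <- sort(unique(zones$country_id))
  rows <- vector("list", length(countries) + include_global)
  for (i in seq_along(countries)) {
    ctry <- countries[i]
    u <- units[units$country_id == ctry, , drop = FALSE]
    med <- if (threat_split == "country") {
      stats::median(u$mean_stoppable_threat)
    } else {
      global_med_threat
    }
    ctry_recs <- recs$total_area_km2[recs$country_id == ctry]
    median_pa <- if (length(ctry_recs) > 0) stats::median(ctry_recs) else global_median_pa
    rows[[i]] <- one_unit(u, ctry, med, median_pa,
                          unit_seed = derive_seed(seed, i))
  }
  if (include_global) {
    gl <- dplyr::summarise(
      dplyr::group_by(units, .data$ecoregion_id),
      mean_stoppable_threat = stats::weighted.mean(.data$mean_stoppable_threat,
                                                   .data$zone_area_km2),
      protected_km2 = min(sum(.data$protected_km2), sum(.data$zone_area_km2)),
      zone_area_km2 = sum(.data$zone_area_km2),
      .groups = "drop"
    )
    rows[[length(countries) + 1L]] <- one_unit(
      gl, "GLOBAL", stats::median(gl$mean_stoppable_threat),
      global_median_pa, unit_seed = derive_seed(seed, 0L)
    )
  }
  dplyr::bind_rows(rows)
}

# Deterministic 32-bit child seed for unit index k under top-level seed.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 131 + 7919 * as.numeric(k)) %% 2147483629)
}
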