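#' Configuration for a synthetic world
#'
#' Builds and validates the parameter set for [generate_world()]. Defaults
#' emulate the study conditions of the global MPA placement analysis: 232
#' marine ecoregions of which 63.4% span more than one country's EEZ, 20
#' countries, 12 threat layers measured in both 2008 and 2013 (8 of them
#' stoppable), 4.3% of national waters protected by 2008 rising to 9.0% by
#' 2013, and a fifth of protected-area records missing their establishment
#' year.
#'
#' @param n_countries Number of countries (EEZs).
#' @param n_ecoregions Number of marine ecoregions.
#' @param transboundary_fraction Fraction of ecoregions whose area spans more
#'   than one country.
#' @param grid_cells_per_ecoregion Grid cells per ecoregion (raised internally
#'   so every country-by-ecoregion zone holds at least one cell).
#' @param n_threat_layers Number of threat layers measured in both periods.
#' @param n_stoppable_layers Number of those layers that an effectively
#'   managed MPA can abate (fishing pressure, benthic structures, direct
#'   human impact categories).
#' @param include_partial_layer If `TRUE`, add a shipping layer measured only
#'   in 2013; analysis stages must drop it because it is not measured in both
#'   periods.
#' @param threat_distribution_params Optional tibble with columns `layer_id`,
#'   `shape`, `scale_2008`, `scale_2013` giving the gamma parameters of each
#'   layer's cell values per period. Defaults to shape 2 with per-layer scales
#'   and a 15% mean increase from 2008 to 2013.
#' @param bias_beta Placement bias. MPA sites are drawn with probability
#'   proportional to `exp(bias_beta * z)` where `z` is the standardized zone
#'   mean stoppable threat: 0 places randomly, positive values target
#'   high-threat zones, negative values avoid them.
#' @param total_protected_fraction_by_period Named numeric vector mapping
#'   period (`"2008"`, `"2013"`) to the cumulative fraction of total marine
#'   area protected by that period.
#' @param missing_year_fraction Fraction of MPA records whose establishment
#'   year is removed (see [corrupt_years()]).
#' @param transboundary_threat_multiplier Multiplier applied to stoppable
#'   threat values in transboundary ecoregions (1 = no enrichment). Above 1
#'   it reproduces the empirical pattern of border-crossing ecoregions
#'   carrying more abatable threat.
#' @param mpa_size_meanlog,mpa_size_sdlog Lognormal parameters of MPA sizes
#'   (km^2). The distribution is right-skewed so the median differs from the
#'   mean, which is what makes the median-size rule of the random null
#'   meaningful; the spread is kept moderate so the null's median-size
#'   allocation chunks have granularity comparable to the simulated estate.
#' @param zone_area_meanlog,zone_area_sdlog Lognormal parameters of zone
#'   (country-by-ecoregion) areas, km^2; the heavy right tail gives a few
#'   very large ecoregions, which exercises the capacity capping of the null
#'   model.
#' @param decoy_fraction Fraction (of the valid MPA count) of additional
#'   records that violate one inclusion rule each (proposed status, UNESCO
#'   biosphere flag, missing boundary, terrestrial); [filter_mpas()] must
#'   remove them.
#' @param seed Integer seed; one world per seed, fully reproducible.
#'
#' @return A list of class `world_config`.
#' @seealso [generate_world()]
#' @export
world_config <- function(n_countries = 20,
                         n_ecoregions = 232,
                         transboundary_fraction = 0.634,
                         grid_cells_per_ecoregion = 4,
                         n_threat_layers = 12,
                         n_stoppable_layers = 8,
                         include_partial_layer = TRUE,
                         threat_distribution_params = NULL,
                         bias_beta = 0,
                         total_protected_fraction_by_period = c("2008" = 0.043, "2013" = 0.090),
                         missing_year_fraction = 0.2,
                         transboundary_threat_multiplier = 1,
                         mpa_size_meanlog = log(1e4),
                         mpa_size_sdlog = 0.3,
                         zone_area_meanlog = log(5e4),
                         zone_area_sdlog = 1.2,
                         decoy_fraction = 0.1,
                         seed = 1L) {
  stopifnot(
    n_countries >= 1, n_ecoregions >= 1,
    transboundary_fraction >= 0, transboundary_fraction <= 1,
    grid_cells_per_ecoregion >= 1,
    n_threat_layers >= 1,
    n_stoppable_layers >= 1, n_stoppable_layers <= n_threat_layers,
    missing_year_fraction >= 0, missing_year_fraction <= 1,
    decoy_fraction >= 0,
    mpa_size_sdlog >= 0, zone_area_sdlog >= 0
  )
  periods <- names(total_protected_fraction_by_period)
  if (!setequal(periods, c("2008", "2013"))) {
    stop("total_protected_fraction_by_period must be named with periods \"2008\" and \"2013\"")
  }
  for (p in periods) {
    f <- total_protected_fraction_by_period[[p]]
    if (f < 0 || f > 1) {
      stop(sprintf("infeasible protection fraction %.3f for period %s", f, p))
    }
  }
  if (total_protected_fraction_by_period[["2008"]] >
      total_protected_fraction_by_period[["2013"]]) {
    stop("protected fraction in 2008 cannot exceed that in 2013")
  }
  cfg <- list(
    n_countries = as.integer(n_countries),
    n_ecoregions = as.integer(n_ecoregions),
    transboundary_fraction = transboundary_fraction,
    grid_cells_per_ecoregion = as.integer(grid_cells_per_ecoregion),
    n_threat_layers = as.integer(n_threat_layers),
    n_stoppable_layers = as.integer(n_stoppable_layers),
    include_partial_layer = isTRUE(include_partial_layer),
    threat_distribution_params = threat_distribution_params,
    bias_beta = bias_beta,
    total_protected_fraction_by_period = total_protected_fraction_by_period[c("2008", "2013")],
    missing_year_fraction = missing_year_fraction,
    transboundary_threat_multiplier = transboundary_threat_multiplier,
    mpa_size_meanlog = mpa_size_meanlog,
    mpa_size_sdlog = mpa_size_sdlog,
    zone_area_meanlog = zone_area_meanlog,
    zone_area_sdlog = zone_area_sdlog,
    decoy_fraction = decoy_fraction,
    seed = as.integer(seed)
  )
  structure(cfg, class = "world_config")
}

# Deterministic child seed for a named generation stage, keeping the value
# within the 32-bit integer range.
child_seed <- function(seed, stage) {
  offsets <- c(structure = 1L, threat = 2L, mpas = 3L, decoys = 4L, years = 5L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  as.integer((as.numeric(seed) %% 1000003) * 1000 + offsets[[stage]])
}

# Threat-layer roster. With the default 12 layers / 8 stoppable the roster
# mirrors the families of the cumulative-human-impact layers: six fishing
# pressures, benthic structures, direct human impact (all stoppable), three
# climate layers and one land-based layer (unstoppable).
default_layer_roster <- function(n_threat_layers, n_stoppable_layers) {
  if (n_threat_layers == 12L && n_stoppable_layers == 8L) {
    tibble::tibble(
      layer_id = c(
        "fishing_demersal_destructive", "fishing_demersal_nondest_low_bycatch",
        "fishing_demersal_nondest_high_bycatch", "fishing_pelagic_low_bycatch",
        "fishing_pelagic_high_bycatch", "fishing_artisanal",
        "benthic_structures", "direct_human_impact",
        "sst_anomaly", "ocean_acidification", "uv_radiation",
        "nutrient_pollution"
      ),
      category = c(
        rep("fishing_pressure", 6), "benthic_structure", "direct_human",
        rep("climate", 3), "land_based"
      )
    )
  } else {
    stop_cat <- c("fishing_pressure", "benthic_structure", "direct_human")
    unst_cat <- c("climate", "land_based")
    n_un <- n_threat_layers - n_stoppable_layers
    cats <- c(
      rep_len(stop_cat, n_stoppable_layers),
      if (n_un > 0) rep_len(unst_cat, n_un)
    )
    tibble::tibble(
      layer_id = sprintf("%s_%02d", cats, seq_len(n_threat_layers)),
      category = cats
    )
  }
}

default_threat_params <- function(layer_ids) {
  n <- length(layer_ids)
  scale08 <- 0.3 + 0.05 * (seq_len(n) - 1)
  tibble::tibble(
    layer_id = layer_ids,
    shape = 2,
    scale_2008 = scale08,
    scale_2013 = 1.15 * scale08
  )
}

iucn_category_levels <- function() {
  c("Ia", "Ib", "II", "III", "IV", "V", "VI",
    "not_applicable", "not_reported", "not_assigned")
}

# Empirically plausible mix of reported IUCN categories in a national MPA
# estate, including the large unreported share.
iucn_category_probs <- function() {
  c(Ia = 0.03, Ib = 0.02, II = 0.10, III = 0.05, IV = 0.15, V = 0.10,
    VI = 0.15, not_applicable = 0.10, not_reported = 0.20,
    not_assigned = 0.10)
}

#' Generate a synthetic world
#'
#' Creates a reproducible synthetic data set with the structure of the real
#' analysis inputs: a grid-cell table with per-layer, per-period threat
#' values; a threat-layer metadata table; a zone (country-by-ecoregion)
#' table; and an MPA record table whose placement carries a known bias
#' toward or away from high-threat zones.
#'
#' MPA sites are placed sequentially: a zone is drawn with probability
#' proportional to `exp(bias_beta * z)` (with `z` the standardized zone mean
#' stoppable threat) among zones with remaining capacity, an area drawn from
#' the lognormal size distribution is allocated (capped by the zone's
#' remaining area and the period budget), and the process repeats until the
#' period's protected-area budget is spent. Establishment years fall in
#' 1985-2008 for the 2008 estate and 2009-2013 for area added afterwards.
#'
#' @param config A [world_config()].
#' @return A list of class `synthetic_world` with elements `grid`,
#'   `layer_meta`, `zones`, `mpas` and `truth` (the generating parameters,
#'   the pre-corruption establishment years, and the zone attractiveness
#'   weights).
#' @examples
#' w <- generate_world(world_config(n_countries = 3, n_ecoregions = 12, seed = 1))
#' nrow(w$zones)
#' @export
generate_world <- function(config) {
  stopifnot(inherits(config, "world_config"))

  ## --- structure: countries, ecoregions, zones, cells -----------------
  set.seed(child_seed(config$seed, "structure"))
  n_eco <- config$n_ecoregions
  n_ctry <- config$n_countries
  eco_ids <- sprintf("ECO%03d", seq_len(n_eco))
  ctry_ids <- sprintf("C%02d", seq_len(n_ctry))

  n_trans <- round(config$transboundary_fraction * n_eco)
  trans_eco <- if (n_trans > 0) sample(eco_ids, n_trans) else character(0)

  eco_countries <- lapply(eco_ids, function(e) {
    if (e %in% trans_eco && n_ctry >= 2) {
      k <- if (n_ctry >= 3) sample(2:3, 1, prob = c(0.7, 0.3)) else 2L
      sample(ctry_ids, k)
    } else {
      sample(ctry_ids, 1)
    }
  })
  names(eco_countries) <- eco_ids

  zones <- tibble::tibble(
    ecoregion_id = rep(eco_ids, lengths(eco_countries)),
    country_id = unlist(eco_countries, use.names = FALSE)
  )
  zones$zone_area_km2 <- stats::rlnorm(nrow(zones),
                                       config$zone_area_meanlog,
                                       config$zone_area_sdlog)
  zones <- dplyr::arrange(zones, .data$country_id, .data$ecoregion_id)
  zones <- zones[, c("country_id", "ecoregion_id", "zone_area_km2")]

  # at least one cell per zone; remaining cells of an ecoregion spread evenly
  cells <- dplyr::group_by(zones, .data$ecoregion_id)
  cells <- dplyr::mutate(cells,
    n_cells = {
      nz <- dplyr::n()
      total <- max(config$grid_cells_per_ecoregion, nz)
      base <- total %/% nz
      extra <- total %% nz
      base + as.integer(seq_len(nz) <= extra)
    }
  )
  cells <- dplyr::ungroup(cells)

  grid <- tidyr::uncount(cells, weights = .data$n_cells, .id = "cell_in_zone")
  # split each zone's area over its cells with a flat Dirichlet draw
  grid <- dplyr::group_by(grid, .data$country_id, .data$ecoregion_id)
  grid <- dplyr::mutate(grid, area_km2 = {
    w <- stats::rgamma(dplyr::n(), shape = 1)
    .data$zone_area_km2 * w / sum(w)
  })
  grid <- dplyr::ungroup(grid)
  grid$cell_id <- sprintf("CELL%05d", seq_len(nrow(grid)))
  grid <- grid[, c("cell_id", "country_id", "ecoregion_id", "area_km2")]

  ## --- threat layers ---------------------------------------------------
  set.seed(child_seed(config$seed, "threat"))
  roster <- default_layer_roster(config$n_threat_layers, config$n_stoppable_layers)
  layer_meta <- tibble::tibble(
    layer_id = roster$layer_id,
    category = roster$category,
    measured_2008 = TRUE,
    measured_2013 = TRUE,
    stoppable = NA
  )
  if (config$include_partial_layer) {
    layer_meta <- dplyr::bind_rows(layer_meta, tibble::tibble(
      layer_id = "shipping", category = "shipping",
      measured_2008 = FALSE, measured_2013 = TRUE, stoppable = NA
    ))
  }
  params <- config$threat_distribution_params
  if (is.null(params)) params <- default_threat_params(roster$layer_id)

  stoppable_cats <- c("fishing_pressure", "benthic_structure", "direct_human")
  # ecoregion-level intensity multiplier clusters human pressure spatially
  eco_mult <- stats::setNames(stats::rlnorm(n_eco, 0, 0.5), eco_ids)
  trans_mult <- ifelse(grid$ecoregion_id %in% trans_eco,
                       config$transboundary_threat_multiplier, 1)

  n_cell <- nrow(grid)
  for (i in seq_len(nrow(roster))) {
    lid <- roster$layer_id[i]
    stp <- roster$category[i] %in% stoppable_cats
    pr <- params[params$layer_id == lid, ]
    if (nrow(pr) != 1) stop("missing threat_distribution_params for layer ", lid)
    for (period in c("2008", "2013")) {
      sc <- if (period == "2008") pr$scale_2008 else pr$scale_2013
      v <- stats::rgamma(n_cell, shape = pr$shape, scale = sc)
      if (stp) v <- v * eco_mult[grid$ecoregion_id] * trans_mult
      grid[[paste0(lid, "_", period)]] <- unname(v)
    }
  }
  if (config$include_partial_layer) {
    grid[["shipping_2013"]] <- stats::rgamma(n_cell, shape = 2, scale = 0.4)
  }

  ## --- MPA estate -------------------------------------------------------
  set.seed(child_seed(config$seed, "mpas"))
  # zone attractiveness: area-weighted mean over cells of the mean raw
  # stoppable value (both periods pooled); standardized before the softmax
  stop_layers <- roster$layer_id[roster$category %in% stoppable_cats]
  stop_cols <- c(paste0(stop_layers, "_2008"), paste0(stop_layers, "_2013"))
  cell_score <- rowMeans(as.matrix(grid[, stop_cols]))
  zone_threat <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(
      country_id = grid$country_id, ecoregion_id = grid$ecoregion_id,
      area = grid$area_km2, score = cell_score
    ), .data$country_id, .data$ecoregion_id),
    threat = stats::weighted.mean(.data$score, .data$area), .groups = "drop"
  )
  zone_tab <- dplyr::left_join(zones, zone_threat,
                               by = c("country_id", "ecoregion_id"))
  z <- as.numeric(scale(zone_tab$threat))
  if (anyNA(z)) z <- rep(0, nrow(zone_tab))  # single zone or zero variance
  zone_tab$weight <- exp(config$bias_beta * z)

  total_area <- sum(zones$zone_area_km2)
  f08 <- config$total_protected_fraction_by_period[["2008"]]
  f13 <- config$total_protected_fraction_by_period[["2013"]]
  budgets <- c("2008" = f08 * total_area, "2013" = (f13 - f08) * total_area)

  capacity <- zone_tab$zone_area_km2
  weight <- zone_tab$weight
  tol <- 1e-9 * total_area
  recs <- list()
  k <- 0L
  for (period in c("2008", "2013")) {
    b <- budgets[[period]]
    yr_range <- if (period == "2008") 1985:2008 else 2009:2013
    while (b > tol) {
      open <- which(capacity > tol)
      if (length(open) == 0) {
        stop(sprintf("infeasible protection fraction for period %s: no remaining capacity", period))
      }
      i <- if (length(open) == 1) open else {
        open[sample.int(length(open), 1, prob = weight[open])]
      }
      size <- stats::rlnorm(1, config$mpa_size_meanlog, config$mpa_size_sdlog)
      alloc <- min(size, capacity[i], b)
      capacity[i] <- capacity[i] - alloc
      b <- b - alloc
      k <- k + 1L
      recs[[k]] <- list(
        country_id = zone_tab$country_id[i],
        ecoregion_id = zone_tab$ecoregion_id[i],
        allocation_km2 = alloc,
        establishment_year = sample(yr_range, 1)
      )
    }
  }
  mpas <- dplyr::bind_rows(lapply(recs, tibble::as_tibble))
  if (nrow(mpas) == 0) {
    mpas <- tibble::tibble(country_id = character(), ecoregion_id = character(),
                           allocation_km2 = numeric(),
                           establishment_year = integer())
  }
  n_valid <- nrow(mpas)
  mpas$status <- "designated"
  mpas$is_unesco_biosphere <- FALSE
  mpas$has_boundary <- TRUE
  mpas$is_marine <- TRUE
  if (n_valid > 0) {
    mpas$iucn_category <- sample(names(iucn_category_probs()), n_valid,
                                 replace = TRUE, prob = iucn_category_probs())
  } else {
    mpas$iucn_category <- character(0)
  }

  ## --- decoy records that the filters must remove ----------------------
  set.seed(child_seed(config$seed, "decoys"))
  n_decoy <- round(config$decoy_fraction * n_valid)
  if (n_decoy > 0) {
    zi <- sample.int(nrow(zone_tab), n_decoy, replace = TRUE)
    size <- stats::rlnorm(n_decoy, config$mpa_size_meanlog, config$mpa_size_sdlog)
    decoys <- tibble::tibble(
      country_id = zone_tab$country_id[zi],
      ecoregion_id = zone_tab$ecoregion_id[zi],
      allocation_km2 = pmin(size, zone_tab$zone_area_km2[zi]),
      establishment_year = sample(1985:2013, n_decoy, replace = TRUE),
      status = "designated",
      is_unesco_biosphere = FALSE,
      has_boundary = TRUE,
      is_marine = TRUE,
      iucn_category = sample(names(iucn_category_probs()), n_decoy,
                             replace = TRUE, prob = iucn_category_probs())
    )
    defect <- sample(c("proposed", "biosphere", "no_boundary", "terrestrial"),
                     n_decoy, replace = TRUE)
    decoys$status[defect == "proposed"] <- "proposed"
    decoys$is_unesco_biosphere[defect == "biosphere"] <- TRUE
    decoys$has_boundary[defect == "no_boundary"] <- FALSE
    decoys$is_marine[defect == "terrestrial"] <- FALSE
    mpas <- dplyr::bind_rows(mpas, decoys)
  }
  mpas$mpa_id <- sprintf("MPA%05d", seq_len(nrow(mpas)))
  mpas$total_area_km2 <- mpas$allocation_km2
  mpas$establishment_year <- as.integer(mpas$establishment_year)
  mpas <- mpas[, c("mpa_id", "country_id", "ecoregion_id", "allocation_km2",
                   "total_area_km2", "iucn_category", "status",
                   "is_unesco_biosphere", "has_boundary", "is_marine",
                   "establishment_year")]

  true_years <- mpas[, c("mpa_id", "establishment_year")]
  mpas <- corrupt_years(mpas, config$missing_year_fraction,
                        seed = child_seed(config$seed, "years"))

  structure(
    list(
      grid = grid,
      layer_meta = layer_meta,
      zones = zones,
      mpas = mpas,
      truth = list(
        config = config,
        true_years = true_years,
        zone_attractiveness = zone_tab[, c("country_id", "ecoregion_id",
                                           "threat", "weight")],
        transboundary_ecoregions = sort(trans_eco),
        budgets_km2 = budgets,
        total_area_km2 = total_area
      )
    ),
    class = "synthetic_world"
  )
}

#' @export
print.synthetic_world <- function(x, ...) {
  cfg <- x$truth$config
  cat(sprintf(
    "<synthetic_world> %d countries, %d ecoregions (%d zones), %d cells, %d MPA records, bias_beta = %g, seed = %d\n",
    cfg$n_countries, cfg$n_ecoregions, nrow(x$zones), nrow(x$grid),
    dplyr::n_distinct(x$mpas$mpa_id), cfg$bias_beta, cfg$seed
  ))
  invisible(x)
}

#' Remove establishment years from a fraction of MPA records
#'
#' Sets the establishment year to `NA` for exactly
#' `round(missing_year_fraction * n)` of the `n` distinct MPA records,
#' chosen reproducibly from `seed`. This creates the missing-data condition
#' that [impute_years()] repairs.
#'
#' @param mpas MPA table (one or more allocation rows per `mpa_id`).
#' @param missing_year_fraction Proportion in \[0, 1\].
#' @param seed Integer seed.
#' @return The MPA table with years removed.
#' @export
corrupt_years <- function(mpas, missing_year_fraction, seed) {
  stopifnot(missing_year_fraction >= 0, missing_year_fraction <= 1)
  ids <- unique(mpas$mpa_id)
  n_missing <- round(missing_year_fraction * length(ids))
  if (n_missing == 0) return(mpas)
  set.seed(as.integer(seed))
  drop <- sample(ids, n_missing)
  mpas$establishment_year[mpas$mpa_id %in% drop] <- NA_integer_
  mpas
}
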