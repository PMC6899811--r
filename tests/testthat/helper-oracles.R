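# Small worlds and independent brute-force oracles used across the suite.

tiny_config <- function(seed, beta = 0, n_countries = 4, n_ecoregions = 16,
                        missing_year_fraction = 0.2, ...) {
  world_config(
    n_countries = n_countries, n_ecoregions = n_ecoregions,
    transboundary_fraction = 0.5, grid_cells_per_ecoregion = 3,
    bias_beta = beta, missing_year_fraction = missing_year_fraction,
    seed = seed, ...
  )
}

# World sized so a country's 2013 estate spans ~40+ median-size allocation
# chunks: the empirical percentile interval of the null is then smooth
# enough to act as a reference distribution.
calibration_config <- function(seed, beta = 0) {
  world_config(
    n_countries = 1, n_ecoregions = 12, transboundary_fraction = 0,
    grid_cells_per_ecoregion = 3, bias_beta = beta,
    total_protected_fraction_by_period = c("2008" = 0.02, "2013" = 0.09),
    missing_year_fraction = 0, decoy_fraction = 0,
    zone_area_meanlog = log(2e5), seed = seed
  )
}

prepare_world <- function(world) {
  lm <- classify_stoppable(world$layer_meta)
  grid <- suppressMessages(normalize_across_periods(world$grid, lm))
  mpas <- filter_mpas(world$mpas)
  if (anyNA(mpas$establishment_year)) {
    mpas <- impute_years(mpas, seed = world$truth$config$seed)
  }
  list(world = world, layer_meta = lm, grid = grid, mpas = mpas)
}

# Brute-force recomputation of a country's observed impact metric straight
# from the emitted tables: explicit loops, no package aggregation helpers.
oracle_observed_impact <- function(prep, country = NULL) {
  w <- prep$world
  lm <- prep$layer_meta
  grid <- prep$grid
  stop_ids <- lm$layer_id[!is.na(lm$stoppable) & lm$stoppable &
                            lm$measured_2008 & lm$measured_2013]
  zones <- w$zones
  if (!is.null(country)) zones <- zones[zones$country_id == country, ]
  thr <- numeric(nrow(zones))
  for (i in seq_len(nrow(zones))) {
    cells <- grid[grid$country_id == zones$country_id[i] &
                    grid$ecoregion_id == zones$ecoregion_id[i], ]
    num <- 0; den <- 0
    for (j in seq_len(nrow(cells))) {
      sc <- mean(sapply(stop_ids, function(l) cells[[paste0(l, "_2013")]][j]))
      num <- num + sc * cells$area_km2[j]
      den <- den + cells$area_km2[j]
    }
    thr[i] <- num / den
  }
  cls <- ifelse(thr > median(thr), "high", "low")
  prot <- numeric(nrow(zones))
  m <- prep$mpas
  for (i in seq_len(nrow(zones))) {
    sel <- m$country_id == zones$country_id[i] &
      m$ecoregion_id == zones$ecoregion_id[i] &
      m$establishment_year <= 2013
    prot[i] <- min(sum(m$allocation_km2[sel]), zones$zone_area_km2[i])
  }
  p_H <- sum(prot[cls == "high"]); p_L <- sum(prot[cls == "low"])
  a_H <- sum(zones$zone_area_km2[cls == "high"])
  a_L <- sum(zones$zone_area_km2[cls == "low"])
  (if (a_H > 0) p_H / a_H else 0) - (if (a_L > 0) p_L / a_L else 0)
}

# Type-7 quantile written out by hand (sorted order statistics with linear
# interpolation), independent of stats::quantile.
oracle_quantile7 <- function(x, p) {
  xs <- sort(x)
  n <- length(xs)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  xs[lo] + (h - lo) * (xs[pmin(lo + 1, n)] - xs[lo])
}

# Independent sort-and-bin classifier: quartile bins, sectors, threat class
# and risk categories recomputed from first principles.
oracle_classify <- function(ecoregion_id, protection, threat) {
  bin <- function(x) {
    q <- sapply(c(0.25, 0.5, 0.75), function(p) oracle_quantile7(x, p))
    out <- integer(length(x))
    for (i in seq_along(x)) {
      out[i] <- if (x[i] <= q[1]) 1L else if (x[i] <= q[2]) 2L
      else if (x[i] <= q[3]) 3L else 4L
    }
    out
  }
  pq <- bin(protection)
  tq <- bin(threat)
  med_t <- oracle_quantile7(threat, 0.5)
  med_p <- oracle_quantile7(protection, 0.5)
  risk_levels <- c("low_risk", "moderate_risk", "high_risk", "crisis")
  data.frame(
    ecoregion_id = ecoregion_id,
    protection_quartile = pq, threat_quartile = tq,
    sector = (pq - 1L) * 4L + tq,
    threat_class = ifelse(threat > med_t, "high", "low"),
    risk_category = ifelse(protection > med_p, NA_character_, risk_levels[tq]),
    stringsAsFactors = FALSE
  )
}

# Textbook Pearson goodness-of-fit statistic.
oracle_chisq <- function(observed, expected) {
  s <- 0
  for (i in seq_along(observed)) {
    s <- s + (observed[i] - expected[i])^2 / expected[i]
  }
  s
}

# A handmade MPA table: one allocation row per entry of `alloc`.
make_mpas <- function(country, ecoregion, alloc, year,
                      iucn = "not_reported", status = "designated",
                      biosphere = FALSE, boundary = TRUE, marine = TRUE) {
  n <- length(alloc)
  tibble::tibble(
    mpa_id = sprintf("M%03d", seq_len(n)),
    country_id = rep_len(country, n),
    ecoregion_id = rep_len(ecoregion, n),
    allocation_km2 = alloc,
    total_area_km2 = alloc,
    iucn_category = rep_len(iucn, n),
    status = rep_len(status, n),
    is_unesco_biosphere = rep_len(biosphere, n),
    has_boundary = rep_len(boundary, n),
    is_marine = rep_len(marine, n),
    establishment_year = as.integer(rep_len(year, n))
  )
}
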