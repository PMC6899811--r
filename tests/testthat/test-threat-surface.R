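make_layer_meta <- function(categories, measured_2008 = TRUE,
                            measured_2013 = TRUE) {
  tibble::tibble(
    layer_id = paste0("L", seq_along(categories)),
    category = categories,
    measured_2008 = rep_len(measured_2008, length(categories)),
    measured_2013 = rep_len(measured_2013, length(categories)),
    stoppable = NA
  )
}

test_that("default stoppable rule follows threat category", {
  lm <- classify_stoppable(make_layer_meta(c(
    "fishing_pressure", "benthic_structure", "direct_human",
    "climate", "land_based", "shipping"
  )))
  expect_equal(lm$stoppable, c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_error(
    classify_stoppable(make_layer_meta("volcanism")),
    "unknown threat category"
  )
})

test_that("rule table overrides support the fishing-only sensitivity run", {
  lm <- make_layer_meta(c("fishing_pressure", "benthic_structure",
                          "direct_human", "climate"))
  fishing_only <- classify_stoppable(lm, fishing_only_rule(lm))
  expect_equal(fishing_only$stoppable, c(TRUE, FALSE, FALSE, FALSE))
  # the sensitivity run can never label more layers stoppable than default
  default <- classify_stoppable(lm)
  expect_lte(sum(fishing_only$stoppable), sum(default$stoppable))
  expect_error(
    classify_stoppable(lm, tibble::tibble(layer_id = "nope", stoppable = TRUE)),
    "unknown layers"
  )
})

grid_one_layer <- function(v2008, v2013, eco = "E1", ctry = "C1") {
  n <- length(v2008)
  tibble::tibble(
    cell_id = paste0("c", seq_len(n)),
    country_id = rep_len(ctry, n), ecoregion_id = rep_len(eco, n),
    area_km2 = 1, L1_2008 = v2008, L1_2013 = v2013
  )
}

test_that("normalization pools extremes across both periods", {
  lm <- classify_stoppable(make_layer_meta("fishing_pressure"))
  g <- normalize_across_periods(grid_one_layer(c(0, 5), c(10, 5)), lm)
  expect_equal(sort(c(g$L1_2008, g$L1_2013)), c(0, 0.5, 0.5, 1))
  # hand-computed pooled min-max: pooled range [1, 5]
  g2 <- normalize_across_periods(grid_one_layer(c(1, 3), c(3, 5)), lm)
  expect_equal(g2$L1_2008, c(0, 0.5))
  expect_equal(g2$L1_2013, c(0.5, 1))
  # constant layer maps to zero, not NaN
  g3 <- normalize_across_periods(grid_one_layer(c(4, 4), c(4, 4)), lm)
  expect_equal(c(g3$L1_2008, g3$L1_2013), rep(0, 4))
  expect_error(
    normalize_across_periods(grid_one_layer(c(-1, 2), c(0, 1)), lm),
    "negative"
  )
})

test_that("layers not measured in both periods are dropped before analysis", {
  lm <- classify_stoppable(dplyr::bind_rows(
    make_layer_meta("fishing_pressure"),
    tibble::tibble(layer_id = "L2", category = "shipping",
                   measured_2008 = FALSE, measured_2013 = TRUE,
                   stoppable = NA)
  ))
  g <- grid_one_layer(c(0, 5), c(10, 5))
  g$L2_2013 <- c(1, 2)
  expect_message(out <- normalize_across_periods(g, lm), "L2")
  expect_false("L2_2013" %in% names(out))
})

test_that("zonal means match direct arithmetic and a brute-force cell loop", {
  lm <- classify_stoppable(make_layer_meta(c("fishing_pressure", "climate")))
  # one zone, equal areas, one stoppable layer: plain mean
  g <- tibble::tibble(
    cell_id = c("c1", "c2"), country_id = "C1", ecoregion_id = "E1",
    area_km2 = 1,
    L1_2008 = c(0.1, 0.1), L1_2013 = c(0.2, 0.4),
    L2_2008 = c(0.9, 0.9), L2_2013 = c(0.9, 0.9)
  )
  zones <- tibble::tibble(country_id = "C1", ecoregion_id = "E1",
                          zone_area_km2 = 2)
  zt <- mean_stoppable_threat(g, lm, zones, "2013")
  expect_equal(zt$mean_stoppable_threat, 0.3)
  expect_equal(zt$n_cells, 2L)

  # two stoppable layers: per-cell score is their unweighted mean
  lm2 <- classify_stoppable(make_layer_meta(c("fishing_pressure",
                                              "direct_human")))
  g2 <- g
  g2$L2_2013 <- c(0.6, 0.6)
  zt2 <- mean_stoppable_threat(g2, lm2, zones, "2013")
  expect_equal(zt2$mean_stoppable_threat, mean(c(mean(c(0.2, 0.6)),
                                                 mean(c(0.4, 0.6)))))

  # synthetic world vs independent cell loop, area-weighted
  w <- generate_world(tiny_config(seed = 61))
  prep <- prepare_world(w)
  zt3 <- mean_stoppable_threat(prep$grid, prep$layer_meta, w$zones, "2013")
  stop_ids <- prep$layer_meta$layer_id[
    !is.na(prep$layer_meta$stoppable) & prep$layer_meta$stoppable
  ]
  for (k in sample(nrow(zt3), 3)) {
    cells <- prep$grid[prep$grid$country_id == zt3$country_id[k] &
                         prep$grid$ecoregion_id == zt3$ecoregion_id[k], ]
    num <- 0; den <- 0
    for (j in seq_len(nrow(cells))) {
      sc <- mean(sapply(stop_ids, function(l) cells[[paste0(l, "_2013")]][j]))
      num <- num + sc * cells$area_km2[j]; den <- den + cells$area_km2[j]
    }
    expect_equal(zt3$mean_stoppable_threat[k], num / den, tolerance = 1e-12)
  }
})

test_that("zonal means are order-invariant and nest into global means", {
  w <- generate_world(tiny_config(seed = 62))
  prep <- prepare_world(w)
  zt <- mean_stoppable_threat(prep$grid, prep$layer_meta, w$zones, "2013")
  shuffled <- prep$grid[sample(nrow(prep$grid)), ]
  zt_s <- mean_stoppable_threat(shuffled, prep$layer_meta, w$zones, "2013")
  expect_equal(zt, zt_s)

  glob <- mean_stoppable_threat(prep$grid, prep$layer_meta, w$zones, "2013",
                                scope = "global")
  # the global-ecoregion mean equals the area-weighted combination of its
  # country-level zone means
  joined <- dplyr::left_join(zt, w$zones, by = c("country_id", "ecoregion_id"))
  comb <- dplyr::summarise(
    dplyr::group_by(joined, ecoregion_id),
    m = stats::weighted.mean(mean_stoppable_threat, zone_area_km2),
    .groups = "drop"
  )
  expect_equal(glob$mean_stoppable_threat,
               comb$m[match(glob$ecoregion_id, comb$ecoregion_id)],
               tolerance = 1e-12)
})

test_that("zones without any grid cell are reported as errors", {
  lm <- classify_stoppable(make_layer_meta("fishing_pressure"))
  g <- grid_one_layer(c(0, 5), c(10, 5))
  zones <- tibble::tibble(country_id = c("C1", "C1"),
                          ecoregion_id = c("E1", "E9"),
                          zone_area_km2 = c(2, 7))
  expect_error(mean_stoppable_threat(g, lm, zones, "2013"), "E9")
})
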