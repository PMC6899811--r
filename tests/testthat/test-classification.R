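test_that("distinct values split evenly into quartiles; ties fall low", {
  df <- tibble::tibble(
    ecoregion_id = paste0("E", 1:8),
    protection = (1:8) / 10,
    threat = (8:1) / 10
  )
  cl <- quartile_sector_classify(df)
  expect_equal(unname(table(cl$protection_quartile)), rep(2L, 4),
               ignore_attr = TRUE)
  expect_equal(unname(table(cl$threat_quartile)), rep(2L, 4),
               ignore_attr = TRUE)
  # sector is a bijection of the two quartiles
  expect_equal(cl$sector, (cl$protection_quartile - 1L) * 4L + cl$threat_quartile)

  # all-zero protection: everyone ties into quartile 1
  df0 <- df
  df0$protection <- 0
  cl0 <- suppressMessages(quartile_sector_classify(df0))
  expect_true(all(cl0$protection_quartile == 1L))

  expect_error(quartile_sector_classify(df[1:3, ]), "at least 4")
})

test_that("classification matches the independent sort-and-bin oracle", {
  for (s in c(1, 2, 3)) {
    set.seed(s)
    n <- 60
    protection <- ifelse(runif(n) < 0.4, 0, runif(n, 0, 0.6))
    threat <- rlnorm(n, -2, 0.8)
    df <- tibble::tibble(ecoregion_id = sprintf("E%03d", 1:n),
                         protection = protection, threat = threat)
    cl <- risk_categories(suppressMessages(quartile_sector_classify(df)))
    oc <- oracle_classify(df$ecoregion_id, protection, threat)
    expect_equal(cl$sector, oc$sector)
    expect_equal(cl$threat_class, oc$threat_class)
    expect_equal(cl$risk_category, oc$risk_category)
  }
})

test_that("classification is invariant to input row order", {
  set.seed(4)
  df <- tibble::tibble(ecoregion_id = sprintf("E%03d", 1:40),
                       protection = runif(40), threat = runif(40))
  cl <- risk_categories(quartile_sector_classify(df))
  perm <- sample(40)
  cl2 <- risk_categories(quartile_sector_classify(df[perm, ]))
  cl2 <- cl2[match(cl$ecoregion_id, cl2$ecoregion_id), ]
  expect_equal(cl$sector, cl2$sector)
  expect_equal(cl$risk_category, cl2$risk_category)
})

test_that("uniform-sector chi-square has 6.25% expectation and textbook statistic", {
  # perfectly uniform: statistic 0, p = 1
  df <- tibble::tibble(
    ecoregion_id = paste0("E", 1:16),
    protection = rep(1:4, each = 4) / 4,
    threat = rep(1:4, times = 4) / 4
  )
  cl <- quartile_sector_classify(df)
  expect_equal(sort(cl$sector), 1:16)
  res <- suppressWarnings(chi_square_uniform_sectors(cl))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$expected / nrow(cl), rep(1 / 16, 16))
  expect_equal(res$df, 15L)

  # all mass in one sector: statistic is 15 * n
  cl1 <- cl
  cl1$sector <- 1L
  res1 <- suppressWarnings(chi_square_uniform_sectors(cl1))
  expect_equal(res1$statistic, 15 * 16)

  # synthetic counts vs the hand formula and stats::chisq.test
  set.seed(9)
  cl2 <- cl[sample(16, 100, replace = TRUE, prob = c(8, rep(1, 15))), ]
  res2 <- suppressWarnings(chi_square_uniform_sectors(cl2))
  expect_equal(res2$statistic,
               unname(oracle_chisq(res2$observed, rep(100 / 16, 16))))
  ref <- suppressWarnings(stats::chisq.test(res2$observed,
                                            p = rep(1 / 16, 16)))
  expect_equal(res2$statistic, unname(ref$statistic))
  expect_equal(res2$p_value, unname(ref$p.value))
})

test_that("strategy split separates targeting from avoiding protection", {
  summary_tbl <- tibble::tibble(
    ecoregion_id = paste0("E", 1:4),
    protected_km2 = c(10, 20, 0, 0),
    zone_area_km2 = c(100, 100, 100, 100),
    proportion_protected = c(0.1, 0.2, 0, 0)
  )
  cls <- tibble::tibble(ecoregion_id = paste0("E", 1:4),
                        threat_class = c("low", "low", "high", "high"))
  sp <- strategy_split(summary_tbl, cls)
  expect_equal(sp$targeting_share, 0)
  expect_equal(sp$by_class$proportion_protected[sp$by_class$threat_class == "low"],
               0.15)
  # equal proportional protection in both classes: ratio 1
  summary_eq <- summary_tbl
  summary_eq$protected_km2 <- 10
  summary_eq$proportion_protected <- 0.1
  sp_eq <- strategy_split(summary_eq, cls)
  props <- sp_eq$by_class$proportion_protected
  expect_equal(props[1] / props[2], 1)
  expect_equal(sp_eq$targeting_share, 0.5)
})

test_that("risk categories go only to poorly protected ecoregions", {
  df <- tibble::tibble(
    ecoregion_id = paste0("E", 1:8),
    protection = c(0, 0, 0.1, 0.1, 0.5, 0.5, 0.9, 0.9),
    threat = (1:8) / 8
  )
  cl <- risk_categories(quartile_sector_classify(df))
  expect_true(all(is.na(cl$risk_category[cl$protection > median(df$protection)])))
  # poorly protected + top threat quartile = crisis
  expect_equal(cl$risk_category[cl$protection == 0 & cl$threat_quartile == 1],
               rep("low_risk", 2))
  low <- cl[!is.na(cl$risk_category), ]
  expect_equal(low$risk_category[low$threat_quartile == 4],
               rep("crisis", sum(low$threat_quartile == 4)))
})

test_that("transboundary test matches hand computation on a contrived table", {
  # 16 poorly protected ecoregions: single-country uniform (2 per category),
  # transboundary skewed toward crisis
  cl <- tibble::tibble(
    ecoregion_id = sprintf("E%02d", 1:16),
    protection = 0,
    threat = 1:16,
    threat_quartile = rep(1:4, 4),
    risk_category = c(rep(c("low_risk", "moderate_risk", "high_risk", "crisis"), 2),
                      c("low_risk", "crisis", "crisis", "crisis",
                        "moderate_risk", "crisis", "crisis", "high_risk"))
  )
  zones <- tibble::tibble(
    ecoregion_id = c(sprintf("E%02d", 1:16), sprintf("E%02d", 9:16)),
    country_id = c(rep("C1", 16), rep("C2", 8)),
    zone_area_km2 = 1
  )
  res <- suppressWarnings(transboundary_test(cl, zones))
  obs_single <- c(2, 2, 2, 2)
  obs_trans <- c(1, 1, 1, 5)
  hand <- oracle_chisq(obs_single, rep(2, 4)) + oracle_chisq(obs_trans, rep(2, 4))
  expect_equal(res$statistic, hand)
  expect_equal(res$df, 6L)
  expect_equal(unname(res$expected["transboundary", ]), rep(2, 4))
  expect_equal(res$share_transboundary, 0.5)

  # both classes uniform: statistic 0
  cl_u <- cl
  cl_u$risk_category <- rep(c("low_risk", "moderate_risk", "high_risk", "crisis"), 4)
  res_u <- suppressWarnings(transboundary_test(cl_u, zones))
  expect_equal(res_u$statistic, 0)

  # a border class with no poorly protected members is skipped with warning
  cl_na <- cl
  cl_na$risk_category[9:16] <- NA
  w_na <- testthat::capture_warnings(res_na <- transboundary_test(cl_na, zones))
  expect_match(w_na, "skipped", all = FALSE)
  expect_equal(res_na$df, 3L)
})

test_that("transboundary threat enrichment produces crisis enrichment", {
  w <- generate_world(tiny_config(seed = 81, n_countries = 6,
                                  n_ecoregions = 48,
                                  transboundary_threat_multiplier = 4))
  prep <- prepare_world(w)
  tg <- mean_stoppable_threat(prep$grid, prep$layer_meta, w$zones, "2013",
                              scope = "global")
  pg <- protection_by_zone(prep$mpas, w$zones, "2013", scope = "global")
  cl <- risk_categories(suppressMessages(quartile_sector_classify(tibble::tibble(
    ecoregion_id = pg$ecoregion_id,
    protection = pg$proportion_protected,
    threat = tg$mean_stoppable_threat[match(pg$ecoregion_id, tg$ecoregion_id)]
  ))))
  trans <- w$truth$transboundary_ecoregions
  crisis_rate <- function(ids) {
    sub <- cl$risk_category[cl$ecoregion_id %in% ids]
    mean(sub == "crisis", na.rm = TRUE)
  }
  expect_gt(crisis_rate(trans), crisis_rate(setdiff(cl$ecoregion_id, trans)))
})
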