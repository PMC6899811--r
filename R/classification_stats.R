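#' Quartile bin assignment
#'
#' Breakpoints are the 25th, 50th and 75th percentiles computed with linear
#' interpolation between order statistics ([stats::quantile()] type 7).
#' Values at or below a breakpoint fall in the lower bin, so ties -- e.g.
#' many ecoregions with zero protection -- all land in the bottom bin.
#'
#' @param x Numeric vector.
#' @return Integer bins 1-4.
#' @export
quartile_bin <- function(x) {
  br <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  1L + (x > br[1]) + (x > br[2]) + (x > br[3])
}

#' Classify ecoregions into the 16 protection-by-threat sectors
#'
#' Assigns each ecoregion a protection quartile and a threat quartile
#' (breakpoints taken across all ecoregions), the resulting sector (1-16,
#' a bijection over the 4 x 4 grid), the high/low threat class (high means
#' strictly above the overall median threat) and the corresponding
#' protection strategy: MPAs in high-threat ecoregions target stoppable
#' threats, those in low-threat ecoregions avoid them.
#'
#' @param df Tibble with columns `ecoregion_id`, `protection` (proportion
#'   of area protected) and `threat` (mean stoppable threat).
#' @return The input plus `protection_quartile`, `threat_quartile`,
#'   `sector`, `threat_class` and `strategy`.
#' @export
quartile_sector_classify <- function(df) {
  stopifnot(all(c("ecoregion_id", "protection", "threat") %in% names(df)))
  if (nrow(df) < 4) stop("need at least 4 ecoregions to form quartiles")
  if (anyDuplicated(df$ecoregion_id)) stop("duplicated ecoregion_id")
  df$protection_quartile <- quartile_bin(df$protection)
  df$threat_quartile <- quartile_bin(df$threat)
  df$sector <- (df$protection_quartile - 1L) * 4L + df$threat_quartile
  df$threat_class <- ifelse(df$threat > stats::median(df$threat), "high", "low")
  df$strategy <- ifelse(df$threat_class == "high", "targeting", "avoiding")
  n_ties <- sum(df$protection == min(df$protection))
  if (n_ties > nrow(df) / 4) {
    message(sprintf(
      "%d of %d ecoregions tie at the minimum protection value; ties fall in quartile 1",
      n_ties, nrow(df)
    ))
  }
  df
}

new_chisq_result <- function(statistic, df, observed, expected) {
  structure(
    list(
      statistic = statistic,
      df = df,
      p_value = stats::pchisq(statistic, df, lower.tail = FALSE),
      observed = observed,
      expected = expected
    ),
    class = "chisq_result"
  )
}

#' @export
print.chisq_result <- function(x, ...) {
  cat(sprintf("chi-square = %.3f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Chi-square test of uniform sector occupancy
#'
#' Under random placement, each of the 16 protection-by-threat sectors is
#' expected to hold 6.25% of the ecoregions. This goodness-of-fit test
#' compares observed sector counts against that uniform expectation
#' (df = 15), without continuity correction.
#'
#' @param classification Output of [quartile_sector_classify()].
#' @return A `chisq_result` with statistic, df, p-value, observed counts
#'   and expected counts.
#' @export
chi_square_uniform_sectors <- function(classification) {
  n <- nrow(classification)
  if (n == 0) stop("no ecoregions to test")
  observed <- tabulate(classification$sector, nbins = 16L)
  names(observed) <- paste0("sector_", 1:16)
  expected <- rep(n / 16, 16)
  if (any(expected < 5)) {
    warning(sprintf("expected count per sector is %.2f (< 5); chi-square approximation is rough", n / 16))
  }
  statistic <- sum((observed - expected)^2 / expected)
  new_chisq_result(statistic, 15L, observed, expected)
}

#' Split protection into targeting and avoiding strategies
#'
#' Aggregates a per-ecoregion protection summary by high/low threat class:
#' protected area, class area, the area-weighted proportion protected
#' (total protected / total class area) and the unweighted mean of
#' per-ecoregion proportions, plus the share of all protected area that
#' targets threat (i.e. sits in high-threat ecoregions).
#'
#' @param protection_summary Global-scope output of [protection_by_zone()]
#'   (or [protection_change()] renamed to the same columns).
#' @param classification Output of [quartile_sector_classify()] providing
#'   `threat_class` per ecoregion.
#' @return A list with `by_class` (one row per threat class) and
#'   `targeting_share`.
#' @export
strategy_split <- function(protection_summary, classification) {
  joined <- dplyr::inner_join(
    protection_summary,
    classification[, c("ecoregion_id", "threat_class")],
    by = "ecoregion_id"
  )
  by_class <- dplyr::summarise(
    dplyr::group_by(joined, .data$threat_class),
    mean_ecoregion_proportion = mean(.data$proportion_protected),
    protected_km2 = sum(.data$protected_km2),
    class_area_km2 = sum(.data$zone_area_km2),
    proportion_protected = sum(.data$protected_km2) / sum(.data$zone_area_km2),
    n_ecoregions = dplyr::n(),
    .groups = "drop"
  )
  total <- sum(by_class$protected_km2)
  high <- by_class$protected_km2[by_class$threat_class == "high"]
  targeting_share <- if (total > 0) sum(high) / total else NA_real_
  list(by_class = by_class, targeting_share = targeting_share)
}

#' Assign risk categories to poorly protected ecoregions
#'
#' Ecoregions whose proportion protected is not above the overall median
#' are poorly protected; they are divided by their stoppable-threat
#' quartile into low risk (bottom quartile), moderate risk, high risk and
#' crisis (top quartile). Well-protected ecoregions get no risk category.
#'
#' @param classification Output of [quartile_sector_classify()].
#' @return The classification with a `risk_category` column (`NA` for
#'   ecoregions above median protection).
#' @export
risk_categories <- function(classification) {
  med <- stats::median(classification$protection)
  poorly <- !(classification$protection > med)
  levels <- c("low_risk", "moderate_risk", "high_risk", "crisis")
  classification$risk_category <- ifelse(
    poorly, levels[classification$threat_quartile], NA_character_
  )
  classification
}

#' Chi-square test of risk category vs transboundary status
#'
#' Poorly protected ecoregions are labeled transboundary (area in more
#' than one country) or single-country. Because risk categories are
#' quartiles of stoppable threat, 25% of each border class is expected in
#' each category; the test compares observed counts within each class
#' against that uniform expectation. A border class with no poorly
#' protected ecoregions is skipped with a warning.
#'
#' @param classification Output of [risk_categories()].
#' @param zones Zone table giving each ecoregion's country multiplicity.
#' @return A `chisq_result` whose `observed`/`expected` are class-by-
#'   category tables, with additional elements `share_transboundary` (share
#'   of all ecoregions spanning >1 country) and `n_poorly_protected`.
#' @export
transboundary_test <- function(classification, zones) {
  if (!"risk_category" %in% names(classification)) {
    stop("risk categories not assigned; run risk_categories() first")
  }
  mult <- dplyr::summarise(
    dplyr::group_by(zones, .data$ecoregion_id),
    n_countries = dplyr::n_distinct(.data$country_id), .groups = "drop"
  )
  cl <- dplyr::left_join(classification, mult, by = "ecoregion_id")
  if (anyNA(cl$n_countries)) stop("ecoregions missing from the zone table")
  cl$border_class <- ifelse(cl$n_countries > 1, "transboundary", "single_country")
  share_trans <- mean(cl$border_class == "transboundary")

  poorly <- cl[!is.na(cl$risk_category), , drop = FALSE]
  cats <- c("low_risk", "moderate_risk", "high_risk", "crisis")
  classes <- c("single_country", "transboundary")
  observed <- matrix(0, 2, 4, dimnames = list(classes, cats))
  for (b in classes) {
    for (cc in cats) {
      observed[b, cc] <- sum(poorly$border_class == b & poorly$risk_category == cc)
    }
  }
  use <- rowSums(observed) > 0
  if (any(!use)) {
    warning("border class with no poorly protected ecoregions skipped: ",
            paste(classes[!use], collapse = ", "))
  }
  if (!any(use)) stop("no poorly protected ecoregions to test")
  expected <- observed
  expected[] <- NA_real_
  expected[use, ] <- rowSums(observed)[use] / 4
  statistic <- sum((observed[use, , drop = FALSE] -
                      expected[use, , drop = FALSE])^2 /
                     expected[use, , drop = FALSE])
  if (any(expected[use, ] < 5)) {
    warning("expected counts below 5; chi-square approximation is rough")
  }
  res <- new_chisq_result(statistic, 3L * sum(use), observed, expected)
  res$share_transboundary <- share_trans
  res$n_poorly_protected <- nrow(poorly)
  res
}
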