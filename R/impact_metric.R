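#' Country impact metric
#'
#' The impact metric for an MPA estate is the difference between the
#' proportion of high-threat ecoregion area protected and the proportion
#' of low-threat ecoregion area protected:
#' `I = p_H / a_H - p_L / a_L`. It is bounded between -1 (only low-threat
#' ecoregions protected, completely) and 1 (only high-threat ecoregions
#' protected, completely), and equals 0 when both classes are protected in
#' equal proportion. If a country has no area in one class, that class's
#' term is 0 and the value is flagged one-sided via the `"one_sided"`
#' attribute.
#'
#' @param p_H Protected area in high-threat ecoregions, km^2.
#' @param p_L Protected area in low-threat ecoregions, km^2.
#' @param a_H Total area of high-threat ecoregions, km^2.
#' @param a_L Total area of low-threat ecoregions, km^2.
#' @return The impact metric in \[-1, 1\] (vectorized).
#' @examples
#' impact(150, 100, 600, 400)  # equal proportions: 0
#' impact(0, 400, 600, 400)    # only low-threat protected: -1
#' impact(600, 0, 600, 400)    # only high-threat protected: +1
#' @export
impact <- function(p_H, p_L, a_H, a_L) {
  tol <- 1e-9
  if (any(p_H < 0) || any(p_L < 0) || any(a_H < 0) || any(a_L < 0)) {
    stop("areas must be nonnegative")
  }
  if (any(a_H + a_L <= 0)) stop("a_H + a_L must be positive")
  if (any(p_H > a_H * (1 + tol) + tol) || any(p_L > a_L * (1 + tol) + tol)) {
    stop("protected area exceeds class area; cap upstream")
  }
  term_H <- ifelse(a_H > 0, p_H / pmax(a_H, .Machine$double.xmin), 0)
  term_L <- ifelse(a_L > 0, p_L / pmax(a_L, .Machine$double.xmin), 0)
  out <- pmin(1, pmax(-1, term_H - term_L))
  attr(out, "one_sided") <- (a_H == 0) | (a_L == 0)
  out
}

#' Random-allocation null model for the impact metric
#'
#' Simulates the counterfactual in which a country protects area randomly:
#' ecoregions are drawn uniformly with replacement and each draw allocates
#' an area equal to the country's median MPA size -- capped by the drawn
#' ecoregion's remaining capacity (so no proportion protected ever exceeds
#' 1) and by the remaining budget -- until the total area protected in 2013
#' is reached. The impact metric of each simulated estate is computed; the
#' null value is the mean over simulations and significance is judged
#' against a 95% confidence interval.
#'
#' CI construction (`ci_mode`): `"normal"` (the default) uses
#' `mean +/- 1.96 * sd / sqrt(n_sims)` -- the CI of the mean -- switching
#' automatically to a bootstrap percentile CI of the mean (1,000 resamples)
#' when a Shapiro-Wilk test rejects normality of the simulated metrics at
#' alpha = 0.05. `"percentile"` instead takes the 2.5% and 97.5% quantiles
#' of the simulated metric distribution itself; unlike the mean-CI it does
#' not shrink with `n_sims` and is the appropriate reference for judging a
#' single observed estate.
#'
#' @param areas Ecoregion areas (km^2) of the country's units.
#' @param threat_class Character vector (`"high"`/`"low"`) parallel to
#'   `areas`.
#' @param budget Total area protected in 2013, km^2.
#' @param median_pa_size Median MPA size in the country, km^2 (> 0).
#' @param n_sims Number of simulations (default 1000).
#' @param seed Integer seed.
#' @param ci_mode `"normal"` or `"percentile"` (see Details).
#' @param keep_allocations If `TRUE`, also return the `n_sims` by
#'   `length(areas)` matrix of simulated per-ecoregion allocations.
#' @return A list of class `random_null`: `sims_I`, `sims_p_H`, `mean_I`,
#'   `ci_low`, `ci_high`, `ci_method` (`"normal"`, `"bootstrap"` or
#'   `"percentile"`), `mean_p_H`, `n_sims`, `one_sided`, and optionally
#'   `allocations`.
#' @export
random_allocation_null <- function(areas, threat_class, budget,
                                   median_pa_size, n_sims = 1000, seed = 1L,
                                   ci_mode = c("normal", "percentile"),
                                   keep_allocations = FALSE) {
  ci_mode <- match.arg(ci_mode)
  stopifnot(length(areas) == length(threat_class), length(areas) >= 1,
            all(areas > 0), n_sims >= 2)
  if (!all(threat_class %in% c("high", "low"))) {
    stop("threat_class must be \"high\" or \"low\"")
  }
  if (median_pa_size <= 0) stop("median_pa_size must be positive")
  total <- sum(areas)
  if (budget > total * (1 + 1e-9)) {
    stop("protection budget exceeds total ecoregion capacity")
  }
  a_H <- sum(areas[threat_class == "high"])
  a_L <- sum(areas[threat_class == "low"])
  n_eco <- length(areas)
  is_high <- threat_class == "high"
  tol <- 1e-9 * max(total, 1)

  set.seed(as.integer(seed))
  sims_I <- numeric(n_sims)
  sims_p_H <- numeric(n_sims)
  allocations <- if (keep_allocations) matrix(0, n_sims, n_eco) else NULL
  batch <- max(16L, ceiling(budget / median_pa_size) * 2L)
  for (s in seq_len(n_sims)) {
    alloc <- numeric(n_eco)
    remaining <- budget
    draws <- integer(0)
    d <- 0L
    while (remaining > tol) {
      d <- d + 1L
      if (d > length(draws)) {
        draws <- sample.int(n_eco, batch, replace = TRUE)
        d <- 1L
      }
      i <- draws[d]
      cap <- areas[i] - alloc[i]
      if (cap <= tol) {
        if (total - sum(alloc) <= tol) {
          stop("all ecoregions saturated with budget remaining")
        }
        next
      }
      add <- min(median_pa_size, cap, remaining)
      alloc[i] <- alloc[i] + add
      remaining <- remaining - add
    }
    p_H <- sum(alloc[is_high])
    p_L <- sum(alloc) - p_H
    sims_I[s] <- as.numeric(impact(p_H, p_L, a_H, a_L))
    sims_p_H[s] <- p_H
    if (keep_allocations) allocations[s, ] <- alloc
  }

  mean_I <- mean(sims_I)
  sd_I <- stats::sd(sims_I)
  if (ci_mode == "percentile") {
    ci <- stats::quantile(sims_I, c(0.025, 0.975), names = FALSE, type = 7)
    ci_method <- "percentile"
  } else if (sd_I == 0) {
    ci <- c(mean_I, mean_I)
    ci_method <- "normal"
  } else {
    sw <- stats::shapiro.test(if (n_sims > 5000) sims_I[
      round(seq(1, n_sims, length.out = 5000))
    ] else sims_I)
    if (sw$p.value < 0.05) {
      boot_means <- vapply(seq_len(1000), function(b) {
        mean(sims_I[sample.int(n_sims, n_sims, replace = TRUE)])
      }, numeric(1))
      ci <- stats::quantile(boot_means, c(0.025, 0.975), names = FALSE, type = 7)
      ci_method <- "bootstrap"
    } else {
      half <- 1.96 * sd_I / sqrt(n_sims)
      ci <- c(mean_I - half, mean_I + half)
      ci_method <- "normal"
    }
  }
  structure(
    list(
      sims_I = sims_I, sims_p_H = sims_p_H,
      mean_I = mean_I, ci_low = ci[1], ci_high = ci[2],
      ci_method = ci_method, mean_p_H = mean(sims_p_H),
      n_sims = n_sims, a_H = a_H, a_L = a_L,
      one_sided = (a_H == 0) || (a_L == 0),
      allocations = allocations
    ),
    class = "random_null"
  )
}

#' Judge an observed impact metric against the random null
#'
#' An observed metric outside the null's 95% confidence interval differs
#' significantly from random placement: above the interval the estate does
#' better than random at covering high-threat area, below it worse.
#'
#' @param observed_I Observed impact metric.
#' @param null A `random_null` (or any list with `ci_low`, `ci_high`).
#' @return `"better_than_random"`, `"worse_than_random"` or
#'   `"not_significant"`.
#' @export
significance <- function(observed_I, null) {
  if (observed_I > null$ci_high) {
    "better_than_random"
  } else if (observed_I < null$ci_low) {
    "worse_than_random"
  } else {
    "not_significant"
  }
}

#' Protection-bias ratios
#'
#' Summary ratios comparing protection of low- and high-threat ecoregions
#' and the observed estate against the random null: (i) the ratio of the
#' proportion protected in low-threat ecoregions to that in high-threat
#' ecoregions, (ii) the ratio of mean random high-threat protection to
#' observed high-threat protection, and (iii) the percentage less
#' high-threat protection observed than random,
#' `100 * (1 - observed / random)`.
#'
#' @param split Output of [strategy_split()].
#' @param null A `random_null` for the same units and budget.
#' @return A tibble with `low_high_protection_ratio`,
#'   `random_observed_high_ratio` and `percent_less_than_random`.
#' @export
bias_ratios <- function(split, null) {
  by_class <- split$by_class
  prop <- stats::setNames(by_class$proportion_protected, by_class$threat_class)
  obs_p_H <- sum(by_class$protected_km2[by_class$threat_class == "high"])
  low_high <- if (isTRUE(prop[["high"]] > 0)) {
    prop[["low"]] / prop[["high"]]
  } else {
    warning("zero observed high-threat protection; ratio is infinite")
    Inf
  }
  rand_obs <- if (obs_p_H > 0) {
    null$mean_p_H / obs_p_H
  } else {
    warning("zero observed high-threat protection; ratio is infinite")
    Inf
  }
  pct_less <- if (null$mean_p_H > 0) 100 * (1 - obs_p_H / null$mean_p_H) else NA_real_
  tibble::tibble(
    low_high_protection_ratio = low_high,
    random_observed_high_ratio = rand_obs,
    percent_less_than_random = pct_less
  )
}
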