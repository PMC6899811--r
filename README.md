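# mpabias

Tools for asking a simple question of a marine protected area (MPA) estate:
**is protection placed where abatable human threats are, or where they are
not?** Many national estates have grown rapidly by designating large reserves
in remote, lightly used waters. That raises headline coverage statistics while
leaving the ecoregions under the heaviest fishing, coastal development and
habitat destruction pressure as exposed as before. `mpabias` provides a
self-contained synthetic world to emulate that situation, and the full
analysis chain to quantify it.

## The impact metric

For a set of ecoregions split at the median of mean abatable threat into a
high-threat class (total area `a_H`, protected area `p_H`) and a low-threat
class (`a_L`, `p_L`), the impact metric is

```
I = p_H / a_H - p_L / a_L
```

`I` lies in `[-1, 1]`:

* `I = 0` — protection is proportionally equal across the two classes;
* `I = -1` — only low-threat area is protected, and all of it is;
* `I = +1` — only high-threat area is protected, and all of it is.

The observed `I` alone is hard to interpret, because even random placement
produces nonzero values in finite estates. So `mpabias` compares it against a
**random-allocation null**: 1,000 simulated estates that drop median-MPA-sized
chunks into ecoregions drawn uniformly at random (capped at each ecoregion's
remaining capacity) until the real estate's total protected area is spent. An
estate whose observed `I` falls below the null's 95% confidence interval
protects high-threat area *worse than random*.

## What is in the package

* **Synthetic world generator** — countries, ecoregions, a multi-layer threat
  stack with abatable and non-abatable layers, and an MPA record table with
  realistic pathologies (records failing inclusion filters, missing
  establishment years). A single `bias_beta` knob steers placement toward
  (`> 0`) or away from (`< 0`) threatened zones, giving a known ground truth.
* **Threat surface** — layer classification into abatable ("stoppable")
  categories, pooled min-max normalization across periods, area-weighted zone
  and ecoregion means.
* **Protection accounting** — inclusion filters, nested IUCN category
  groupings, donor-pool imputation of missing establishment years, per-period
  protection tallies and changes.
* **Classification statistics** — 16-sector protection-quartile × threat-
  quartile classification, chi-square tests against the uniform 6.25%
  expectation, risk categories for poorly protected ecoregions, and a
  transboundary enrichment test against the 25%-per-category expectation.
* **Impact metric** — `impact()`, the random-allocation null with normal,
  bootstrap and percentile confidence-interval modes, significance verdicts
  and headline bias ratios.
* **Pipeline** — `run_pipeline()` runs everything from either a fresh
  simulation or a world on disk and writes a complete, reproducible artifact
  set.

## Worked example

```r
library(mpabias)

# the metric at its proportional-equality anchor
impact(p_H = 150, p_L = 100, a_H = 600, a_L = 400)
#> [1] 0
#> attr(,"one_sided")
#> [1] FALSE

# a small world whose protection avoids threatened zones (bias_beta = -1.5)
world <- generate_world(world_config(n_countries = 4, n_ecoregions = 16,
                                     grid_cells_per_ecoregion = 3,
                                     bias_beta = -1.5, seed = 42))
world
#> <synthetic_world> 4 countries, 16 ecoregions (29 zones), 48 cells,
#>   41 MPA records, bias_beta = -1.5, seed = 42

meta   <- classify_stoppable(world$layer_meta)
grid   <- normalize_across_periods(world$grid, meta)
#> dropping layers not measured in both periods: shipping
threat <- mean_stoppable_threat(grid, meta, world$zones, "2013")
mpas   <- impute_years(filter_mpas(world$mpas), seed = 42)

res <- assess_impact(mpas, world$zones, threat, n_sims = 1000, seed = 42)
res[, c("country_id", "observed_I", "random_mean_I",
        "ci_low", "ci_high", "verdict")]
#>   country_id observed_I random_mean_I    ci_low ci_high           verdict
#> 1        C01     -0.550      -0.07498 -0.084702 -0.0635 worse_than_random
#> 2        C02     -0.054       0.03624  0.033119  0.0392 worse_than_random
#> 3        C03     -0.161      -0.03032 -0.032810 -0.0278 worse_than_random
#> 4        C04     -0.125       0.11428  0.109408  0.1193 worse_than_random
#> 5     GLOBAL     -0.104       0.00218  0.000426  0.0039 worse_than_random
```

All four countries — and the pooled global estate — protect high-threat area
significantly worse than a random allocation of the same budget, which is
exactly the bias the generator was told to plant.

## The analysis workflow

The full study lives in numbered scripts under `analysis/`, each a thin
driver over the package that writes tables to `results/`:

| script | what it does |
| --- | --- |
| `analysis/01_simulate.R` | simulate the study world (20 countries, 232 ecoregions, avoiding bias) and write it to `results/world/` |
| `analysis/02_threat.R` | classify layers, normalize, compute zone and ecoregion threat means |
| `analysis/03_protection.R` | filter MPA records, impute years, tally protection by period and IUCN grouping |
| `analysis/04_classify.R` | 16-sector classification, uniformity and transboundary chi-square tests |
| `analysis/05_impact.R` | impact metric vs the 1,000-simulation random null, per country and globally |
| `analysis/06_sensitivity.R` | rerun under strict IUCN categories I–II and a fishing-only threat definition |

Run them in order from the repository root:

```sh
for f in analysis/0*.R; do Rscript "$f"; done
```

Every script is deterministic given the seeds written in the scripts;
`results/` is fully regenerable and therefore not committed.

## Vignette

`vignettes/methods.Rmd` documents the generator's model and parameters, the
statistical choices (quantile convention, tie handling, confidence-interval
modes, imputation rules) and the limitations of the synthetic world.
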