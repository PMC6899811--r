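#!/usr/bin/env Rscript

# Step 2: build the abatable ("stoppable") threat surface.
#
# Classifies each threat layer as stoppable or not, drops layers not
# measured in both periods, min-max normalizes each layer across the pooled
# 2008+2013 values, and averages the stoppable layers into one mean threat
# per zone (country x ecoregion) and per ecoregion globally.

suppressPackageStartupMessages(library(mpabias))
suppressPackageStartupMessages(library(readr))

world <- read_world("results/world")

meta <- classify_stoppable(world$layer_meta)
grid_norm <- normalize_across_periods(world$grid, meta)

for (period in c("2008", "2013")) {
  zt <- mean_stoppable_threat(grid_norm, meta, world$zones, period)
  gt <- mean_stoppable_threat(grid_norm, meta, world$zones, period,
                              scope = "global")
  write_csv(zt, sprintf("results/zone_threat_%s.csv", period))
  write_csv(gt, sprintf("results/ecoregion_threat_%s.csv", period))
}
write_csv(meta, "results/layer_classification.csv")
write_csv(grid_norm, "results/grid_normalized.csv")
cat("threat tables written to results/\n")
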