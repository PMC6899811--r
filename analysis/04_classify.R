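#!/usr/bin/env Rscript

# Step 4: quartile-sector classification and goodness-of-fit tests.
#
# Cross-classifies ecoregions into 16 protection-quartile x threat-quartile
# sectors, tests the sector distribution against the uniform 6.25%
# expectation, assigns risk categories to poorly protected ecoregions, and
# tests whether transboundary ecoregions are enriched in the worse
# categories against the 25%-per-category expectation.

suppressPackageStartupMessages(library(mpabias))
suppressPackageStartupMessages(library(readr))

world <- read_world("results/world")
prot <- read_csv("results/protection_by_ecoregion_2013.csv",
                 show_col_types = FALSE)
thr <- read_csv("results/ecoregion_threat_2013.csv", show_col_types = FALSE)

df <- dplyr::inner_join(
  dplyr::select(prot, "ecoregion_id", protection = "proportion_protected"),
  dplyr::select(thr, "ecoregion_id", threat = "mean_stoppable_threat"),
  by = "ecoregion_id"
)
cl <- risk_categories(quartile_sector_classify(df))
write_csv(cl, "results/classification_2013.csv")

sectors <- chi_square_uniform_sectors(cl)
print(sectors)
trans <- transboundary_test(cl, world$zones)
print(trans)

jsonlite::write_json(
  list(
    sectors = list(statistic = sectors$statistic, df = sectors$df,
                   p_value = sectors$p_value,
                   observed = as.list(sectors$observed)),
    transboundary = list(statistic = trans$statistic, df = trans$df,
                         p_value = trans$p_value,
                         share_transboundary = trans$share_transboundary),
    risk_category_counts = as.list(table(cl$risk_category))
  ),
  "results/classification_tests.json", auto_unbox = TRUE, digits = NA
)
cat("classification tables written to results/\n")
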