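#!/usr/bin/env Rscript

# Step 1: simulate a synthetic marine world with an avoiding placement bias.
#
# The world has 20 coastal countries sharing 232 ecoregions, a 12-layer
# threat stack (8 abatable), two protection tranches (2008, 2013) and the
# usual data pathologies: decoy records that fail the inclusion filters and
# MPAs with missing establishment years. bias_beta < 0 steers new protection
# away from heavily threatened zones, the phenomenon the later steps try to
# detect. All downstream steps read the world from results/world/.

suppressPackageStartupMessages(library(mpabias))

seed <- 20260101L
config <- world_config(
  bias_beta = -1.5,
  missing_year_fraction = 0.2,
  decoy_fraction = 0.1,
  seed = seed
)

world <- generate_world(config)
print(world)

dir.create("results", showWarnings = FALSE)
write_world(world, "results/world")
cat("world written to results/world\n")
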