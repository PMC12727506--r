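#!/usr/bin/env Rscript
# Stage 4: compute per-pixel BII maps with uncertainty bounds.
#
# Combines the aggregated scores, the land-use/intensity grids, the
# ecoregion layer and the richness table into per-pixel BII (mean, lower,
# upper) for all species, vertebrates and plants, and per taxon class.

suppressPackageStartupMessages(library(biimapr))
reg <- load_group_registry()

agg <- read.csv("results/aggregated_scores.csv", stringsAsFactors = FALSE)
agg$biome[agg$biome == ""] <- NA
cls <- read_grid_csv("results/data/landuse_class.csv", "character")
th <- read_grid_csv("results/data/landuse_intensity.csv")
lu <- land_use_grid(cls, th, attr(cls, "geom"))
eco <- read_grid_csv("results/data/ecoregions.csv", "character")
rich <- read.csv("results/data/richness.csv", stringsAsFactors = FALSE)
eb <- read.csv("results/data/ecoregion_biomes.csv", stringsAsFactors = FALSE)

subsets <- c("all", "vertebrates", "plants",
             "amphibian", "reptile", "bird", "mammal",
             "forb", "tree_shrub", "graminoid")
summary_rows <- lapply(subsets, function(s) {
  map <- bii_map(lu, eco, rich, agg, reg, s, eb)
  write_bii_grid(map, file.path("results", paste0("bii_", s)))
  z <- zonal_bii(map)
  data.frame(subset = s, bii_pct = as_percent(z$mean),
             lower_pct = as_percent(z$lower), upper_pct = as_percent(z$upper))
})
tab <- do.call(rbind, summary_rows)
write.csv(tab, "results/bii_by_subset.csv", row.names = FALSE)

cat("regional BII by subset (%, with propagated 95% bounds):\n")
print(tab, row.names = FALSE)
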