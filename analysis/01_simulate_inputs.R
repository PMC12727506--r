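#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs.
#
# Writes, under results/data/: the per-expert intactness score table, the
# land-use class / intensity / ecoregion grids of the known landscape, the
# per-ecoregion richness table, and the species records for the
# threat-category analysis. Everything is a pure function of SEED.

suppressPackageStartupMessages(library(biimapr))
SEED <- 1L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

reg <- load_group_registry()
sc <- bii_scenario(seed = SEED, nrow = 60, ncol = 60)

ls <- simulate_landscape(sc)
rich <- simulate_richness(sc, reg)
rec <- simulate_expert_scores(sc, reg)
species <- simulate_species_records(
  bii_scenario(seed = SEED + 13L, species = list(n_species = 1000)), reg)

write.csv(rec, file.path(out, "expert_scores.csv"), row.names = FALSE)
write_grid_csv(ls$lu$class, file.path(out, "landuse_class.csv"), ls$lu$geom)
write_grid_csv(ls$lu$intensity, file.path(out, "landuse_intensity.csv"))
write_grid_csv(ls$ecoregions, file.path(out, "ecoregions.csv"))
write.csv(ls$ecoregion_biomes, file.path(out, "ecoregion_biomes.csv"),
          row.names = FALSE)
write.csv(rich$richness, file.path(out, "richness.csv"), row.names = FALSE)
write.csv(rich$total_richness, file.path(out, "plant_total_richness.csv"),
          row.names = FALSE)
write.csv(rich$biome_proportions, file.path(out, "plant_biome_proportions.csv"),
          row.names = FALSE)
write.csv(species, file.path(out, "species_records.csv"), row.names = FALSE)

write_run_report(file.path(out, "run_report.yaml"),
                 config = list(seed = SEED, nrow = sc$nrow, ncol = sc$ncol,
                               n_experts = sc$n_experts,
                               expert_sd = sc$expert_sd),
                 inputs = list(scenario = "bundled default"))

cat(sprintf("landscape: %d pixels, %d ecoregions; %d score records over %d combinations\n",
            prod(dim(ls$lu$class)), nrow(sc$ecoregions), nrow(rec),
            nrow(unique(rec[c("group_id", "land_use", "biome")]))))
cat(sprintf("analytic (truth) regional BII of this landscape: %.1f%%\n",
            as_percent(expected_bii(sc, rich$richness, reg))))
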