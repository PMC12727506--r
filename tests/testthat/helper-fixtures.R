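# Shared fixtures, all built in code.

# minimal registry: two vertebrate groups, one plant group
tiny_registry <- function() {
  data.frame(group_id = c("vgA", "vgB", "pgA"),
             taxon_class = c("bird", "mammal", "forb"),
             species_level = FALSE,
             stringsAsFactors = FALSE)
}

# score records for one combination from a plain numeric vector
records_from_scores <- function(scores, group = "vgA", land_use = "5",
                                biome = NA_character_) {
  n <- length(scores)
  structure(list(expert_id = paste0("e", seq_len(n)),
                 group_id = rep_len(group, n),
                 land_use = rep_len(land_use, n),
                 biome = rep_len(biome, n),
                 score = scores),
            class = "data.frame", row.names = seq_len(n))
}

# set mean and both bounds of selected score rows to a constant
set_score <- function(scores, value, group = NULL, land_use = NULL) {
  sel <- rep(TRUE, nrow(scores))
  if (!is.null(group)) sel <- sel & scores$group_id %in% group
  if (!is.null(land_use)) sel <- sel & scores$land_use %in% land_use
  scores$mean[sel] <- value
  scores$ci_lower[sel] <- value
  scores$ci_upper[sel] <- value
  scores
}

# a complete aggregated score table for tiny_registry on one biome,
# with every specific land use set to a constant per group
flat_scores <- function(value = 0.8, biome = "grassland",
                        registry = tiny_registry()) {
  codes <- land_use_codes()$code
  rows <- lapply(seq_len(nrow(registry)), function(i) {
    b <- if (registry$taxon_class[i] %in% c("forb", "tree_shrub", "graminoid"))
      biome else NA_character_
    data.frame(group_id = registry$group_id[i], land_use = codes, biome = b,
               mean = value, ci_lower = value, ci_upper = value,
               n_experts = 5L, single_expert = FALSE,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# uniform richness for tiny_registry over given ecoregions
flat_richness <- function(ecoregions = "e1", registry = tiny_registry(),
                          richness = 1) {
  expand.grid(ecoregion_id = ecoregions, group_id = registry$group_id,
              stringsAsFactors = FALSE) |>
    transform(richness = richness)
}

one_biome_map <- function(ecoregions = "e1") {
  data.frame(ecoregion_id = ecoregions, biome1 = "grassland",
             biome2 = NA_character_, stringsAsFactors = FALSE)
}

# homogeneous single-class landscape
flat_landscape <- function(class = "protected", nrow = 4, ncol = 4,
                           theta = NA_real_) {
  th <- if (has_intensity(class)) matrix(theta, nrow, ncol) else NULL
  land_use_grid(matrix(class, nrow, ncol), th)
}
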