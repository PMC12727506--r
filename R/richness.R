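## Per-ecoregion functional-group richness.
##
## Vertebrate richness is a species count per (ecoregion, group), built from
## species lists and a species-to-group mapping. Plant richness is
## proportional: the share of each broad plant group in a biome's flora,
## multiplied by the ecoregion's total vascular-plant richness.

#' Load the functional-group registry
#'
#' Reads the registry of functional response groups (group identifier, taxon
#' class, species-level flag). The bundled default is a synthetic stand-in
#' registry with the documented shape: 146 groups across four vertebrate
#' classes and three broad plant groups, with twelve species-level
#' large-mammal groups.
#'
#' @param path Optional path to a registry CSV; defaults to the bundled
#'   synthetic registry.
#' @return Data frame with columns `group_id`, `taxon_class`,
#'   `species_level`.
#' @export
load_group_registry <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "synthetic_group_registry.csv",
                        package = "biimapr", mustWork = TRUE)
  reg <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("group_id", "taxon_class", "species_level") %in% names(reg)))
  bad <- setdiff(unique(reg$taxon_class), c(.vertebrate_classes, .plant_classes))
  if (length(bad)) stop("unknown taxon class(es): ", paste(bad, collapse = ", "))
  if (any(reg$species_level & reg$taxon_class != "mammal"))
    stop("species-level groups are only defined within mammals")
  if (anyDuplicated(reg$group_id)) stop("duplicate group_id in registry")
  reg$species_level <- as.logical(reg$species_level)
  reg
}

.is_plant_group <- function(group_id, registry) {
  registry$taxon_class[match(group_id, registry$group_id)] %in% .plant_classes
}

#' Build species lists per ecoregion
#'
#' Either passes a precomputed species-by-ecoregion membership table through
#' (deduplicated), or intersects species range polygons with an ecoregion
#' zone grid: a species is listed in every ecoregion whose pixels its range
#' covers (any overlap counts, evaluated at pixel centres). Historical and
#' extinct ranges participate like any other when present in the input.
#'
#' @param ranges Either a data frame with columns `species_id`,
#'   `ecoregion_id` (membership mode) or a named list of polygons (each a
#'   list with numeric `x`, `y` vertex vectors) keyed by species id.
#' @param ecoregions Zone matrix of ecoregion ids (required in polygon mode).
#' @param geom [grid_geom()] of the zone grid (polygon mode).
#' @return Data frame with columns `species_id`, `ecoregion_id`.
#' @export
build_ecoregion_species_lists <- function(ranges, ecoregions = NULL, geom = NULL) {
  if (is.data.frame(ranges)) {
    stopifnot(all(c("species_id", "ecoregion_id") %in% names(ranges)))
    out <- unique(ranges[, c("species_id", "ecoregion_id")])
    rownames(out) <- NULL
    return(out)
  }
  stopifnot(is.list(ranges), is.matrix(ecoregions), inherits(geom, "grid_geom"))
  cen <- .geom_centres(geom)
  px <- rep(cen$x, each = geom$nrow); py <- rep(cen$y, times = geom$ncol)
  eco <- as.vector(ecoregions)
  out <- lapply(names(ranges), function(sp) {
    poly <- ranges[[sp]]
    if (is.null(poly$x) || length(poly$x) < 3) {
      warning("species '", sp, "' has empty or degenerate geometry; skipped")
      return(NULL)
    }
    inside <- point_in_polygon(px, py, poly$x, poly$y)
    hit <- unique(stats::na.omit(eco[inside]))
    if (!length(hit)) return(NULL)
    data.frame(species_id = sp, ecoregion_id = hit, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(species_id = character(),
                                      ecoregion_id = character())
  rownames(res) <- NULL
  res
}

#' Count vertebrate richness per (ecoregion, functional group)
#'
#' Maps every listed species to its functional response group and counts
#' species per (ecoregion, group). Species-level large-mammal groups, whose
#' mapping target is the species' own identifier, naturally receive richness
#' 1 wherever present. Ecoregions without species of a group get no row
#' (sparse representation), not a zero row.
#'
#' @param lists Species lists from [build_ecoregion_species_lists()].
#' @param mapping Data frame with columns `species_id`, `group_id`.
#' @param drop_unmapped Drop species absent from the mapping (with a count in
#'   a message) instead of erroring.
#' @return Richness table: data frame `ecoregion_id`, `group_id`, `richness`.
#' @export
vertebrate_richness <- function(lists, mapping, drop_unmapped = FALSE) {
  stopifnot(all(c("species_id", "group_id") %in% names(mapping)))
  if (anyDuplicated(mapping$species_id))
    stop("each species must map to exactly one group")
  g <- mapping$group_id[match(lists$species_id, mapping$species_id)]
  if (anyNA(g)) {
    lost <- unique(lists$species_id[is.na(g)])
    if (!drop_unmapped)
      stop("unmapped species: ", paste(utils::head(lost, 10), collapse = ", "))
    message(length(lost), " unmapped species dropped")
    lists <- lists[!is.na(g), , drop = FALSE]
    g <- g[!is.na(g)]
  }
  tab <- stats::aggregate(list(richness = lists$species_id),
                          by = list(ecoregion_id = lists$ecoregion_id,
                                    group_id = g),
                          FUN = length)
  tab <- tab[, c("ecoregion_id", "group_id", "richness")]
  tab[order(tab$ecoregion_id, tab$group_id), , drop = FALSE]
}

#' Classify a plant species into a broad functional group
#'
#' Family rule first: Poaceae, Cyperaceae, Juncaceae and Restionaceae are
#' graminoids regardless of growth form. Remaining species with growth form
#' tree, shrub, liana or epiphyte are trees and shrubs; those with growth
#' form herb, shrublet or vine are forbs. Anything else is `"unassigned"`
#' with a warning. Matching is case-insensitive.
#'
#' @param family,growth_form Character vectors (recycled to equal length).
#' @return Character vector over `{graminoid, tree_shrub, forb, unassigned}`.
#' @export
classify_plant_group <- function(family, growth_form) {
  fam <- tolower(trimws(family)); gf <- tolower(trimws(growth_form))
  n <- max(length(fam), length(gf))
  fam <- rep_len(fam, n); gf <- rep_len(gf, n)
  out <- rep("unassigned", n)
  out[fam %in% c("poaceae", "cyperaceae", "juncaceae", "restionaceae")] <- "graminoid"
  ts <- out == "unassigned" & gf %in% c("tree", "shrub", "liana", "epiphyte")
  out[ts] <- "tree_shrub"
  fb <- out == "unassigned" & gf %in% c("herb", "shrublet", "vine")
  out[fb] <- "forb"
  if (any(out == "unassigned"))
    warning(sum(out == "unassigned"), " species with unrecognised growth form left unassigned")
  out
}

#' Derive biome-level plant group proportions from occurrence records
#'
#' Classifies each distinct species observed in a biome with
#' [classify_plant_group()] and returns the share of species per broad group
#' per biome (unassigned species are excluded before normalisation).
#'
#' @param occurrences Data frame with columns `species_id`, `family`,
#'   `growth_form`, `biome`.
#' @return Data frame `biome`, `group_id`, `proportion` (summing to 1 per
#'   biome).
#' @export
plant_group_proportions <- function(occurrences) {
  stopifnot(all(c("species_id", "family", "growth_form", "biome") %in%
                names(occurrences)))
  occ <- unique(occurrences[, c("species_id", "family", "growth_form", "biome")])
  occ$group_id <- classify_plant_group(occ$family, occ$growth_form)
  occ <- occ[occ$group_id != "unassigned", , drop = FALSE]
  tab <- stats::aggregate(list(n = occ$species_id),
                          by = list(biome = occ$biome, group_id = occ$group_id),
                          FUN = length)
  tot <- stats::ave(tab$n, tab$biome, FUN = sum)
  data.frame(biome = tab$biome, group_id = tab$group_id,
             proportion = tab$n / tot, stringsAsFactors = FALSE)
}

#' Plant richness per (ecoregion, broad group)
#'
#' Multiplies biome-level group proportions by total vascular-plant richness
#' per ecoregion. Mosaic ecoregions (two biomes) use the mean of the two
#' biomes' proportions, renormalised to sum to 1.
#'
#' @param biome_group_proportions Data frame `biome`, `group_id`,
#'   `proportion`; proportions must sum to 1 per biome (tolerance 1e-9).
#' @param total_richness Data frame `ecoregion_id`, `total`.
#' @param ecoregion_biomes Data frame `ecoregion_id`, `biome1`, `biome2`
#'   (`biome2` is `NA` except for mosaics).
#' @return Richness table: data frame `ecoregion_id`, `group_id`, `richness`.
#' @export
plant_richness <- function(biome_group_proportions, total_richness,
                           ecoregion_biomes) {
  p <- biome_group_proportions
  sums <- tapply(p$proportion, p$biome, sum)
  off <- abs(sums - 1) > 1e-9
  if (any(off))
    stop("group proportions do not sum to 1 in biome(s): ",
         paste(names(sums)[off], collapse = ", "))
  if (!"biome2" %in% names(ecoregion_biomes))
    ecoregion_biomes$biome2 <- NA_character_
  groups <- sort(unique(p$group_id))
  props_of <- function(biome) {
    v <- p$proportion[match(paste(biome, groups),
                            paste(p$biome, p$group_id))]
    v[is.na(v)] <- 0
    v
  }
  out <- lapply(seq_len(nrow(ecoregion_biomes)), function(i) {
    e <- ecoregion_biomes$ecoregion_id[i]
    pr <- props_of(ecoregion_biomes$biome1[i])
    if (!is.na(ecoregion_biomes$biome2[i])) {
      pr <- (pr + props_of(ecoregion_biomes$biome2[i])) / 2
      pr <- pr / sum(pr)
    }
    tot <- total_richness$total[match(e, total_richness$ecoregion_id)]
    if (is.na(tot)) stop("no total richness for ecoregion '", e, "'")
    data.frame(ecoregion_id = e, group_id = groups, richness = pr * tot,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
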