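## The BII engine.
##
## Per-pixel BII is the richness-weighted mean of group intactness scores
## under the pixel's land use:
##
##   BII_pixel = sum_i R_i * I_ik / sum_i R_i
##
## where R_i is the richness of functional response group i in the pixel's
## ecoregion and I_ik its intactness under land use k. On classes with an
## intensity continuum, I_ik interpolates linearly between the class's
## low- and high-intensity score rows according to the pixel's theta.
## Confidence bounds propagate through the same linear operations.

#' Interpolate intactness between intensity endpoints
#'
#' `value = (1 - theta) * low + theta * high`, applied independently to the
#' mean and both confidence bounds, so theta = 0 reproduces the low-intensity
#' score row exactly and theta = 1 the high-intensity row.
#'
#' @param score_low,score_high Lists or one-row data frames with elements
#'   `mean`, `ci_lower`, `ci_upper`.
#' @param theta Intensity in \[0, 1\] (vectorised).
#' @return List with numeric elements `mean`, `lower`, `upper`.
#' @export
intactness_at_intensity <- function(score_low, score_high, theta) {
  if (any(is.na(theta)) || any(theta < 0 | theta > 1))
    stop("theta must lie in [0, 1]")
  mix <- function(a, b) (1 - theta) * a + theta * b
  list(mean  = mix(score_low$mean,     score_high$mean),
       lower = mix(score_low$ci_lower, score_high$ci_lower),
       upper = mix(score_low$ci_upper, score_high$ci_upper))
}

#' Richness-weighted BII for one pixel
#'
#' @param richness Non-negative richness weights R_i, aligned with `scores`.
#' @param scores Intactness scores I_ik in \[0, 2\].
#' @return `sum(R_i * I_ik) / sum(R_i)`, or `NA` when total richness is 0
#'   (undefined, not zero).
#' @export
bii_pixel <- function(richness, scores) {
  stopifnot(length(richness) == length(scores), all(richness >= 0))
  tot <- sum(richness)
  if (tot == 0) return(NA_real_)
  sum(richness * scores) / tot
}

## Resolve a subset selector to group ids.
.subset_groups <- function(subset, registry) {
  if (length(subset) == 1 && subset %in%
      c("all", "vertebrates", "plants", .vertebrate_classes, .plant_classes)) {
    keep <- switch(subset,
                   all = rep(TRUE, nrow(registry)),
                   vertebrates = registry$taxon_class %in% .vertebrate_classes,
                   plants = registry$taxon_class %in% .plant_classes,
                   registry$taxon_class == subset)
    registry$group_id[keep]
  } else {
    bad <- setdiff(subset, registry$group_id)
    if (length(bad)) stop("unknown group(s) in subset: ",
                          paste(bad, collapse = ", "))
    subset
  }
}

## Per-(ecoregion, class) endpoint triples for a group subset:
## richness-weighted mean/lower/upper at the low and high intensity codes.
.class_endpoints <- function(eco, groups, richness, scores_vert, scores_plant,
                             registry) {
  r <- richness[richness$ecoregion_id == eco &
                richness$group_id %in% groups &
                richness$richness > 0, , drop = FALSE]
  if (!nrow(r)) return(NULL)
  plant <- .is_plant_group(r$group_id, registry)
  lookup <- function(code) {
    s <- data.frame(mean = numeric(nrow(r)), ci_lower = numeric(nrow(r)),
                    ci_upper = numeric(nrow(r)))
    if (any(!plant)) {
      i <- match(paste(r$group_id[!plant], code),
                 paste(scores_vert$group_id, scores_vert$land_use))
      if (anyNA(i))
        stop(sprintf("no score for group '%s', land use '%s'",
                     r$group_id[!plant][which(is.na(i))[1]], code))
      s[!plant, ] <- scores_vert[i, c("mean", "ci_lower", "ci_upper")]
    }
    if (any(plant)) {
      i <- match(paste(eco, r$group_id[plant], code),
                 paste(scores_plant$ecoregion_id, scores_plant$group_id,
                       scores_plant$land_use))
      if (anyNA(i))
        stop(sprintf("no score for group '%s', land use '%s', ecoregion '%s'",
                     r$group_id[plant][which(is.na(i))[1]], code, eco))
      s[plant, ] <- scores_plant[i, c("mean", "ci_lower", "ci_upper")]
    }
    s
  }
  wmean <- function(s) {
    tot <- sum(r$richness)
    c(mean  = sum(r$richness * s$mean) / tot,
      lower = sum(r$richness * s$ci_lower) / tot,
      upper = sum(r$richness * s$ci_upper) / tot)
  }
  ep <- .lu_endpoints
  out <- lapply(seq_len(nrow(ep)), function(i)
    list(low = wmean(lookup(ep$low[i])), high = wmean(lookup(ep$high[i]))))
  names(out) <- ep$class
  out
}

#' Map per-pixel BII with uncertainty bounds
#'
#' Computes mean, lower-limit and upper-limit BII for every pixel from the
#' land-use grid (class + intensity), the ecoregion layer, the richness table
#' and the aggregated expert scores, for any taxon subset. Plant scores are
#' biome-level and are resolved to ecoregions (mosaics averaged) via
#' [resolve_mosaic_scores()]. Pixels whose ecoregion holds no species of the
#' subset are undefined (`NA`), not zero. BII is reported as a fraction;
#' conversion to percent is left to reporting.
#'
#' @param lu [land_use_grid()] with intensity computed.
#' @param ecoregions Matrix of ecoregion ids, co-registered with `lu`.
#' @param richness Richness table (`ecoregion_id`, `group_id`, `richness`).
#' @param scores Aggregated score table from [aggregate_scores()].
#' @param registry Functional-group registry ([load_group_registry()]).
#' @param subset `"all"`, `"vertebrates"`, `"plants"`, a taxon class, or a
#'   vector of group ids.
#' @param ecoregion_biomes Data frame `ecoregion_id`, `biome1`, `biome2`;
#'   required when the subset contains plant groups.
#' @return Object of class `bii_grid`: matrices `mean`, `lower`, `upper`,
#'   plus the subset tag and geometry.
#' @export
bii_map <- function(lu, ecoregions, richness, scores, registry,
                    subset = "all", ecoregion_biomes = NULL) {
  stopifnot(inherits(lu, "land_use_grid"))
  .check_same_dim(list(class = lu$class, ecoregions = ecoregions))
  groups <- .subset_groups(subset, registry)
  any_plants <- any(.is_plant_group(groups, registry))
  scores_vert <- scores[is.na(scores$biome), , drop = FALSE]
  scores_plant <- NULL
  if (any_plants) {
    if (is.null(ecoregion_biomes))
      stop("ecoregion_biomes is required when the subset includes plant groups")
    scores_plant <- resolve_mosaic_scores(scores, ecoregion_biomes)
  }
  shape <- dim(lu$class)
  mean_l <- matrix(NA_real_, shape[1], shape[2])
  low_l <- mean_l; up_l <- mean_l
  theta <- if (is.null(lu$intensity)) matrix(0, shape[1], shape[2]) else lu$intensity
  for (eco in unique(as.vector(ecoregions))) {
    if (is.na(eco)) next
    eps <- .class_endpoints(eco, groups, richness, scores_vert, scores_plant,
                            registry)
    if (is.null(eps)) next  # no subset species here: undefined pixels
    in_eco <- ecoregions == eco
    for (k in unique(lu$class[in_eco])) {
      sel <- in_eco & lu$class == k
      th <- if (.lu_has_intensity[k]) theta[sel] else 0
      if (any(is.na(th))) stop("undefined intensity on continuum class '", k, "'")
      e <- eps[[k]]
      mean_l[sel] <- (1 - th) * e$low["mean"]  + th * e$high["mean"]
      low_l[sel]  <- (1 - th) * e$low["lower"] + th * e$high["lower"]
      up_l[sel]   <- (1 - th) * e$low["upper"] + th * e$high["upper"]
    }
  }
  ok <- !is.na(mean_l)
  stopifnot(all(low_l[ok] <= mean_l[ok] + 1e-12),
            all(mean_l[ok] <= up_l[ok] + 1e-12))
  structure(list(mean = mean_l, lower = low_l, upper = up_l,
                 subset = paste(subset, collapse = ","), geom = lu$geom),
            class = "bii_grid")
}

#' @export
print.bii_grid <- function(x, ...) {
  cat(sprintf("<bii_grid> subset '%s', %d x %d pixels, mean BII %.3f (%.3f-%.3f)\n",
              x$subset, nrow(x$mean), ncol(x$mean),
              mean(x$mean, na.rm = TRUE), mean(x$lower, na.rm = TRUE),
              mean(x$upper, na.rm = TRUE)))
  invisible(x)
}

#' Average BII of one species across its range
#'
#' Unweighted mean, over the species' range pixels, of its functional
#' response group's per-pixel intactness (species-level large-mammal groups
#' use their own score rows via their group id).
#'
#' @param group_id The species' functional response group (or species-level
#'   group id).
#' @param range_mask Logical matrix of range membership, or a vector of
#'   ecoregion ids defining the range.
#' @param lu,ecoregions,richness,scores,registry,ecoregion_biomes As in
#'   [bii_map()].
#' @return List with `bii` (NA and `defined = FALSE` for an empty range) and
#'   `n_pixels`.
#' @export
bii_species <- function(group_id, range_mask, lu, ecoregions, richness,
                        scores, registry, ecoregion_biomes = NULL) {
  if (!is.matrix(range_mask))
    range_mask <- matrix(ecoregions %in% range_mask, nrow(ecoregions))
  if (!any(range_mask))
    return(list(bii = NA_real_, defined = FALSE, n_pixels = 0L))
  map <- bii_map(lu, ecoregions, richness, scores, registry,
                 subset = group_id, ecoregion_biomes = ecoregion_biomes)
  v <- map$mean[range_mask]
  list(bii = mean(v, na.rm = TRUE), defined = any(!is.na(v)),
       n_pixels = sum(range_mask))
}
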