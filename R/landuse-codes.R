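## Land-use vocabulary shared by every module.
##
## Six broad classes; nine specific land uses scored by experts. Four classes
## span an intensity continuum whose endpoints are a low- and a high-intensity
## specific land use. Smallholder cropland ("3a4a") is the shared low-intensity
## endpoint of both tree crops and crops.

.lu_classes <- c("settlement", "timber", "tree_crop", "crop",
                 "protected", "untransformed")

.lu_has_intensity <- c(settlement = TRUE, timber = FALSE, tree_crop = TRUE,
                       crop = TRUE, protected = FALSE, untransformed = TRUE)

.lu_codes <- data.frame(
  code  = c("1a", "1b", "2", "3a4a", "3b", "4b", "5", "6a", "6b"),
  label = c("mixed settlements", "dense urban", "timber plantations",
            "smallholder croplands", "tree croplands",
            "intensive croplands", "strictly protected",
            "near-natural", "intensive rangelands"),
  stringsAsFactors = FALSE
)

.lu_endpoints <- data.frame(
  class = .lu_classes,
  low   = c("1a", "2", "3a4a", "3a4a", "5", "6a"),
  high  = c("1b", "2", "3b",   "4b",   "5", "6b"),
  stringsAsFactors = FALSE
)

.transformed_classes <- c("settlement", "timber", "tree_crop", "crop")

.biomes <- c("forest", "humid_savanna", "acacia_savanna", "grassland",
             "shrubland", "thicket", "desert", "fynbos")

.vertebrate_classes <- c("amphibian", "reptile", "bird", "mammal")
.plant_classes <- c("forb", "tree_shrub", "graminoid")

#' Broad land-use classes
#'
#' The six broad land-use classes, in allocation priority order:
#' settlement, timber, tree_crop, crop, protected, untransformed.
#'
#' @return Character vector of class codes.
#' @export
land_use_classes <- function() .lu_classes

#' Specific land-use codes scored by experts
#'
#' The nine specific land uses for which experts provide intactness scores,
#' with a human-readable label each.
#'
#' @return Data frame with columns `code` and `label`.
#' @export
land_use_codes <- function() .lu_codes

#' Intensity-continuum endpoints per broad class
#'
#' Maps each broad land-use class to the specific land-use codes that form
#' the low- and high-intensity endpoints of its continuum. Classes without a
#' continuum (timber, protected) map to the same code twice.
#'
#' @return Data frame with columns `class`, `low`, `high`.
#' @export
intensity_endpoints <- function() .lu_endpoints

#' Does a broad class have an intensity continuum?
#'
#' @param class Character vector of broad class codes.
#' @return Logical vector.
#' @export
has_intensity <- function(class) {
  stopifnot(all(class %in% .lu_classes))
  unname(.lu_has_intensity[class])
}

#' Recognised biome identifiers
#'
#' The eight major biomes for which plant intactness is scored.
#'
#' @return Character vector.
#' @export
biome_codes <- function() .biomes
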