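## Zonal aggregation and the lost/remaining contribution decomposition.
##
## BII is averaged over the pixels of an area of interest (equal-area
## pixels, unweighted): BII_zone = (1/n) * sum BII_pixel. The contribution
## analysis splits each pixel's intactness into a remaining part min(BII, 1)
## and a lost part max(0, 1 - BII) — the cap keeps scores above 1 (groups
## exceeding reference abundance) from producing negative loss, and makes
## remaining + lost = 1 per pixel — and attributes both to the pixel's land
## use and intensity stratum.

.zone_vector <- function(zones, dims) {
  if (is.null(zones)) rep("all", prod(dims)) else {
    stopifnot(all(dim(zones) == dims))
    as.vector(zones)
  }
}

#' Zonal BII summary
#'
#' Unweighted mean of per-pixel BII (and of the lower/upper bound layers)
#' over each zone. Undefined pixels are excluded; a zone with no defined
#' pixel is flagged undefined rather than reported as 0.
#'
#' @param bii A `bii_grid` from [bii_map()].
#' @param zones Matrix of zone ids co-registered with `bii`, or `NULL` for a
#'   single whole-domain zone `"all"`.
#' @return Data frame `zone`, `mean`, `lower`, `upper`, `n_pixels`,
#'   `defined`.
#' @export
zonal_bii <- function(bii, zones = NULL) {
  stopifnot(inherits(bii, "bii_grid"))
  z <- .zone_vector(zones, dim(bii$mean))
  keep <- !is.na(z)
  f <- factor(z[keep])
  m <- as.vector(bii$mean)[keep]
  lo <- as.vector(bii$lower)[keep]
  up <- as.vector(bii$upper)[keep]
  ok <- !is.na(m)
  n_def <- as.integer(rowsum(as.numeric(ok), f))
  safe_mean <- function(v) {
    s <- rowsum(ifelse(ok, v, 0), f)
    as.vector(ifelse(n_def > 0, s / n_def, NA_real_))
  }
  data.frame(zone = levels(f),
             mean = safe_mean(m), lower = safe_mean(lo), upper = safe_mean(up),
             n_pixels = as.integer(table(f)),
             defined = n_def > 0,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Decompose remaining and lost BII by land use and intensity stratum
#'
#' For each zone, land-use class and intensity stratum (theta < threshold =
#' low, theta >= threshold = medium_high, `n/a` for classes without a
#' continuum), reports the share of the zone's extent, of its total remaining
#' BII and of its total lost BII. Within a zone each share column sums to 1;
#' when a zone has lost nothing, its lost shares are reported as 0 and the
#' rows are flagged.
#'
#' @param bii A `bii_grid` from [bii_map()].
#' @param lu The co-registered [land_use_grid()].
#' @param split_threshold Intensity split point (default 0.25).
#' @param zones Optional zone matrix; `NULL` for the whole domain.
#' @return Data frame `zone`, `land_use`, `intensity_stratum`,
#'   `extent_share`, `remaining_share`, `lost_share`, `no_loss`.
#' @export
contribution_decomposition <- function(bii, lu, split_threshold = 0.25,
                                       zones = NULL) {
  stopifnot(inherits(bii, "bii_grid"), inherits(lu, "land_use_grid"))
  .check_same_dim(list(bii = bii$mean, lu = lu$class))
  z <- .zone_vector(zones, dim(bii$mean))
  cls <- as.vector(lu$class)
  th <- if (is.null(lu$intensity)) rep(NA_real_, length(cls)) else
    as.vector(lu$intensity)
  stratum <- ifelse(!.lu_has_intensity[cls], "n/a",
                    ifelse(th >= split_threshold, "medium_high", "low"))
  m <- as.vector(bii$mean)
  rem <- pmin(m, 1)
  lost <- pmax(0, 1 - m)
  keep <- !is.na(z)
  df <- data.frame(zone = z, land_use = cls, stratum = stratum,
                   n = 1,
                   rem = ifelse(is.na(rem), 0, rem),
                   lost = ifelse(is.na(lost), 0, lost))[keep, , drop = FALSE]
  agg <- stats::aggregate(cbind(n, rem, lost) ~ zone + land_use + stratum,
                          data = df, FUN = sum)
  per_zone <- function(v) stats::ave(v, agg$zone, FUN = sum)
  tot_rem <- per_zone(agg$rem); tot_lost <- per_zone(agg$lost)
  out <- data.frame(zone = agg$zone, land_use = agg$land_use,
                    intensity_stratum = agg$stratum,
                    extent_share = agg$n / per_zone(agg$n),
                    remaining_share = ifelse(tot_rem > 0, agg$rem / tot_rem, 0),
                    lost_share = ifelse(tot_lost > 0, agg$lost / tot_lost, 0),
                    no_loss = tot_lost == 0,
                    stringsAsFactors = FALSE)
  out[order(out$zone, out$land_use, out$intensity_stratum), , drop = FALSE]
}

#' Fraction of transformed land per zone
#'
#' Share of pixels covered by the transformed classes (settlement, timber,
#' tree_crop, crop) in each zone.
#'
#' @param lu A [land_use_grid()].
#' @param zones Optional zone matrix; `NULL` for the whole domain.
#' @return Data frame `zone`, `transformed_fraction`, `n_pixels`.
#' @export
transformed_fraction <- function(lu, zones = NULL) {
  stopifnot(inherits(lu, "land_use_grid"))
  z <- .zone_vector(zones, dim(lu$class))
  keep <- !is.na(z)
  f <- factor(z[keep])
  tr <- as.vector(lu$class)[keep] %in% .transformed_classes
  data.frame(zone = levels(f),
             transformed_fraction = as.vector(rowsum(as.numeric(tr), f)) /
               as.integer(table(f)),
             n_pixels = as.integer(table(f)),
             stringsAsFactors = FALSE, row.names = NULL)
}
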