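## Land-use allocation and intensity scoring.
##
## Pixels are allocated to one of six broad classes by a priority decision
## tree (settlement first, untransformed last), then the four
## continuum classes receive an intensity score theta in [0, 1] built from
## minmax-scaled pressure proxies. Numeric thresholds and proxy sets are
## configuration data, not code: the shipped defaults are placeholders that
## callers are expected to revise against their own input layers.

#' Default allocation and intensity configuration
#'
#' Returns the shipped configuration: ordered threshold rules per class (all
#' conditions of a class must hold), the intensity-proxy variable sets per
#' continuum class, and the percentile cap applied when minmax-scaling
#' unbounded variables. Rule order is fixed at settlement, timber, tree_crop,
#' crop, protected; unmatched pixels become untransformed.
#'
#' @return Nested list with entries `rules`, `proxies`, `cap_percentile`.
#' @export
allocation_config <- function() {
  list(
    cap_percentile = 0.90,
    rules = list(
      settlement = list(list(var = "population_density", op = ">=", threshold = 1000)),
      timber     = list(list(var = "timber_cover",       op = ">=", threshold = 0.5)),
      tree_crop  = list(list(var = "tree_crop_cover",    op = ">=", threshold = 0.5)),
      crop       = list(list(var = "crop_cover",         op = ">=", threshold = 0.5)),
      protected  = list(list(var = "protected_strict",   op = ">=", threshold = 1))
    ),
    proxies = list(
      settlement    = list(list(var = "population_density", cap = TRUE)),
      tree_crop     = list(list(var = "population_density", cap = TRUE)),
      crop          = list(list(var = "nitrogen_input", cap = TRUE),
                           list(var = "field_size",     cap = FALSE)),
      untransformed = list(list(var = "livestock_density", cap = TRUE,
                                contextual = TRUE))
    )
  )
}

#' Read an allocation configuration from YAML
#'
#' Missing top-level entries fall back to the shipped defaults of
#' [allocation_config()].
#'
#' @param path Path to a YAML file.
#' @return Configuration list.
#' @export
read_allocation_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- allocation_config()
  for (k in names(base)) if (is.null(cfg[[k]])) cfg[[k]] <- base[[k]]
  bad <- setdiff(names(cfg$rules), .lu_classes)
  if (length(bad)) stop("rules for unknown class(es): ", paste(bad, collapse = ", "))
  cfg
}

.apply_rule <- function(layers, conds) {
  ok <- NULL
  for (cond in conds) {
    v <- layers[[cond$var]]
    if (is.null(v)) stop("allocation rule references missing layer '", cond$var, "'")
    hit <- switch(cond$op,
                  ">=" = v >= cond$threshold,
                  ">"  = v >  cond$threshold,
                  "<=" = v <= cond$threshold,
                  "<"  = v <  cond$threshold,
                  "==" = v == cond$threshold,
                  stop("unknown comparator '", cond$op, "'"))
    hit[is.na(hit)] <- FALSE
    ok <- if (is.null(ok)) hit else ok & hit
  }
  ok
}

#' Allocate pixels to broad land-use classes
#'
#' Applies the priority decision tree: the first class (in the fixed order
#' settlement, timber, tree_crop, crop, protected) whose rule matches claims
#' the pixel; anything left is untransformed. Because protected is evaluated
#' after the transformed classes, transformed land inside reserves is never
#' labelled protected.
#'
#' @param layers Named list of co-registered numeric matrices holding the
#'   variables referenced by the rules.
#' @param config Configuration from [allocation_config()] or
#'   [read_allocation_config()].
#' @param geom Optional [grid_geom()].
#' @return A [land_use_grid()] with the class layer set (no intensity yet).
#' @export
allocate_land_use <- function(layers, config = allocation_config(), geom = NULL) {
  stopifnot(length(layers) >= 1)
  dims <- .check_same_dim(layers)
  cls <- matrix(NA_character_, dims[1], dims[2])
  for (k in intersect(.lu_classes, names(config$rules))) {
    hit <- .apply_rule(layers, config$rules[[k]])
    cls[is.na(cls) & hit] <- k
  }
  cls[is.na(cls)] <- "untransformed"
  land_use_grid(cls, geom = geom)
}

#' Minmax-scale a numeric vector to \[0, 1\]
#'
#' Computes `(x - min) / (max - min)`, optionally replacing the maximum with
#' a percentile value (linear-interpolation quantile, R type 7) so unbounded
#' variables are not dominated by outliers; results are clipped to \[0, 1\].
#' Constant input maps to all zeros (lowest intensity).
#'
#' @param values Numeric vector; `NA`s are preserved.
#' @param cap_percentile Optional probability; when given, the quantile at
#'   this level replaces the maximum in the scaling.
#' @return Numeric vector in \[0, 1\] with `NA`s where input was `NA`.
#' @export
scale_minmax <- function(values, cap_percentile = NULL) {
  fin <- values[!is.na(values)]
  if (!length(fin)) stop("all values missing; cannot minmax-scale")
  lo <- min(fin)
  hi <- if (is.null(cap_percentile)) max(fin) else {
    stopifnot(cap_percentile > 0, cap_percentile <= 1)
    stats::quantile(fin, cap_percentile, names = FALSE, type = 7)
  }
  if (hi <= lo) return(ifelse(is.na(values), NA_real_, 0))
  pmin(1, pmax(0, (values - lo) / (hi - lo)))
}

#' Contextual bin from rainfall and soil-nutrient class
#'
#' Groups pixels into comparable sets for livestock-density scaling: mean
#' annual rainfall in half-open 400 mm bins (`[0,400)`, `[400,800)`, ...)
#' crossed with the soil-nutrient class (high, medium, low).
#'
#' @param mar Numeric vector of mean annual rainfall (mm, non-negative).
#' @param soil Character vector of soil-nutrient classes.
#' @return Character vector of bin identifiers, e.g. `"mar1:low"`.
#' @export
contextual_bin <- function(mar, soil) {
  stopifnot(length(mar) == length(soil))
  if (any(!is.na(mar) & mar < 0)) stop("negative rainfall")
  soil_l <- tolower(trimws(soil))
  bad <- setdiff(stats::na.omit(unique(soil_l)), c("high", "medium", "low"))
  if (length(bad)) stop("unknown soil-nutrient class(es): ",
                        paste(bad, collapse = ", "))
  ifelse(is.na(mar) | is.na(soil_l), NA_character_,
         paste0("mar", floor(mar / 400), ":", soil_l))
}

#' Score land-use intensity per pixel
#'
#' For every class with an intensity continuum: each configured proxy is
#' minmax-scaled within the class's pixels (livestock-type proxies scaled
#' within contextual rainfall-by-soil bins first), the scaled proxies are
#' averaged per pixel, and the average is rescaled by minmax within the
#' class, so theta = 0 is the least and theta = 1 the most intensive pixel of
#' that class. Classes with no pixels are skipped with a message.
#'
#' @param lu A [land_use_grid()] with the class layer set.
#' @param proxies Named list of co-registered numeric matrices; livestock
#'   binning additionally uses `proxies$mar` and `proxies$soil` (the latter a
#'   character matrix).
#' @param config Configuration from [allocation_config()].
#' @return The input grid with `intensity` filled on continuum classes.
#' @export
compute_intensity <- function(lu, proxies, config = allocation_config()) {
  stopifnot(inherits(lu, "land_use_grid"))
  .check_same_dim(c(list(class = lu$class),
                    proxies[vapply(proxies, is.numeric, TRUE)]))
  theta <- matrix(NA_real_, nrow(lu$class), ncol(lu$class))
  cap <- config$cap_percentile
  for (k in .lu_classes[.lu_has_intensity[.lu_classes]]) {
    sel <- lu$class == k
    if (!any(sel)) { message("class '", k, "' has no pixels; skipped"); next }
    spec <- config$proxies[[k]]
    if (is.null(spec)) stop("no intensity proxies configured for class '", k, "'")
    scaled <- vapply(spec, function(p) {
      v <- proxies[[p$var]]
      if (is.null(v)) stop("intensity proxy '", p$var, "' missing for class '", k, "'")
      v <- v[sel]
      capp <- if (isTRUE(p$cap)) cap else NULL
      if (isTRUE(p$contextual)) {
        if (is.null(proxies$mar) || is.null(proxies$soil))
          stop("contextual scaling needs 'mar' and 'soil' layers")
        bins <- contextual_bin(proxies$mar[sel], proxies$soil[sel])
        out <- rep(NA_real_, length(v))
        for (b in unique(stats::na.omit(bins))) {
          i <- which(!is.na(bins) & bins == b)
          out[i] <- scale_minmax(v[i], capp)
        }
        out
      } else scale_minmax(v, capp)
    }, numeric(sum(sel)))
    avg <- if (is.matrix(scaled)) rowMeans(scaled) else mean(scaled)
    theta[sel] <- scale_minmax(avg)
  }
  land_use_grid(lu$class, theta, lu$geom)
}
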