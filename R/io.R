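## File formats and zone layers.
##
## All tables are CSV. Grids travel as headerless CSV grid tables (one row
## per pixel row, row 1 = top of map); geometry is carried in a YAML sidecar
## or supplied by the caller. Zones come either as an id grid or as GeoJSON
## polygons rasterized by pixel-centre membership. BII layers written to
## disk use an explicit sentinel column value "NA" for undefined pixels,
## distinct from 0.

#' Write a grid matrix as a CSV grid table
#'
#' @param mat Matrix (numeric or character).
#' @param path Output path.
#' @param geom Optional [grid_geom()]; written as a YAML sidecar
#'   (`<path>.geom.yaml`) when given.
#' @export
write_grid_csv <- function(mat, path, geom = NULL) {
  utils::write.table(mat, path, sep = ",", row.names = FALSE,
                     col.names = FALSE, na = "NA")
  if (!is.null(geom))
    yaml::write_yaml(unclass(geom), paste0(path, ".geom.yaml"))
  invisible(path)
}

#' Read a CSV grid table
#'
#' @param path Path written by [write_grid_csv()].
#' @param what `"numeric"` or `"character"`.
#' @return Matrix; attribute `geom` if a sidecar is present.
#' @export
read_grid_csv <- function(path, what = c("numeric", "character")) {
  what <- match.arg(what)
  tab <- utils::read.table(path, sep = ",", header = FALSE,
                           colClasses = what, na.strings = "NA",
                           stringsAsFactors = FALSE)
  m <- as.matrix(tab)
  dimnames(m) <- NULL
  side <- paste0(path, ".geom.yaml")
  if (file.exists(side)) {
    g <- yaml::read_yaml(side)
    attr(m, "geom") <- do.call(grid_geom, g)
  }
  m
}

#' Even-odd point-in-polygon test
#'
#' Ray-casting membership test for a simple polygon (vertices in order,
#' implicitly closed). Points on edges follow the half-open convention of
#' the crossing rule.
#'
#' @param px,py Point coordinates (vectors).
#' @param vx,vy Polygon vertex coordinates.
#' @return Logical vector.
#' @export
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  stopifnot(n >= 3, length(vy) == n, length(px) == length(py))
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Read a zone layer
#'
#' Accepts either an id grid (CSV grid table; passed through) or a GeoJSON
#' `FeatureCollection` of polygons with an `id` property, rasterized onto
#' the analysis grid by pixel-centre membership. Zones must partition the
#' domain: a pixel centre claimed by two polygons is an error.
#'
#' @param path Path to `.csv` or `.geojson`/`.json`.
#' @param geom [grid_geom()] of the analysis grid (required for polygons;
#'   for CSV it falls back to the sidecar).
#' @return Character matrix of zone ids (`NA` outside all polygons).
#' @export
read_zone_layer <- function(path, geom = NULL) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    m <- read_grid_csv(path, "character")
    return(m)
  }
  if (!grepl("\\.(geo)?json$", path, ignore.case = TRUE))
    stop("zone layer must be a CSV id grid or GeoJSON polygons: ", path)
  if (is.null(geom)) stop("grid geometry is required to rasterize polygons")
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection: ", path)
  cen <- .geom_centres(geom)
  px <- rep(cen$x, each = geom$nrow)
  py <- rep(cen$y, times = geom$ncol)
  out <- rep(NA_character_, length(px))
  for (f in gj$features) {
    id <- f$properties$id
    if (is.null(id)) stop("polygon feature without an 'id' property")
    geomtype <- f$geometry$type
    rings <- switch(geomtype,
                    Polygon = list(f$geometry$coordinates),
                    MultiPolygon = f$geometry$coordinates,
                    stop("unsupported geometry type '", geomtype, "'"))
    hit <- rep(FALSE, length(px))
    for (poly in rings) {
      ring <- poly[[1]]  # outer ring; holes unsupported
      vx <- vapply(ring, function(p) p[[1]], 0)
      vy <- vapply(ring, function(p) p[[2]], 0)
      hit <- hit | point_in_polygon(px, py, vx, vy)
    }
    clash <- hit & !is.na(out)
    if (any(clash))
      stop("overlapping polygons: zones must partition the domain (id '",
           id, "')")
    out[hit] <- as.character(id)
  }
  matrix(out, geom$nrow, geom$ncol)
}

#' Write a BII grid to CSV layers
#'
#' Writes `<stem>_mean.csv`, `<stem>_lower.csv`, `<stem>_upper.csv` plus a
#' metadata YAML recording the subset tag; undefined pixels are written as
#' the sentinel "NA".
#'
#' @param bii A `bii_grid`.
#' @param stem Output path stem.
#' @export
write_bii_grid <- function(bii, stem) {
  stopifnot(inherits(bii, "bii_grid"))
  write_grid_csv(bii$mean, paste0(stem, "_mean.csv"), bii$geom)
  write_grid_csv(bii$lower, paste0(stem, "_lower.csv"))
  write_grid_csv(bii$upper, paste0(stem, "_upper.csv"))
  yaml::write_yaml(list(subset = bii$subset, undefined_sentinel = "NA"),
                   paste0(stem, "_meta.yaml"))
  invisible(stem)
}

#' Write a run report
#'
#' Records the configuration, input descriptions and any warnings of a
#' pipeline run as YAML next to its outputs.
#'
#' @param path Output path.
#' @param config Arbitrary configuration list (serialised verbatim).
#' @param inputs Named character vector/list describing inputs.
#' @param warnings Character vector of warnings gathered during the run.
#' @export
write_run_report <- function(path, config = list(), inputs = list(),
                             warnings = character()) {
  yaml::write_yaml(list(package = "biimapr",
                        version = as.character(utils::packageVersion("biimapr")),
                        config = config, inputs = as.list(inputs),
                        warnings = as.list(warnings)), path)
  invisible(path)
}

#' Format a BII fraction as percent
#'
#' Multiplies by 100 and rounds to one decimal: the presentation applied
#' only at the reporting boundary (internally BII is a fraction).
#'
#' @param x Numeric fractions.
#' @param digits Decimals (default 1).
#' @return Numeric percentages.
#' @export
as_percent <- function(x, digits = 1) round(100 * x, digits)
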