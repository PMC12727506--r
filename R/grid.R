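## Grid geometry and raster-style helpers.
##
## All grids are plain R matrices, pixel-registered, row-major, with an
## explicit geometry record (`grid_geom`). Row 1 is the top of the map; pixel
## (1,1) has its lower-left corner at (xmin, ymax - res). Pixels are assumed
## equal-area, so zonal statistics are unweighted pixel averages.

#' Grid geometry
#'
#' Describes the shape and placement of an aligned raster grid.
#'
#' @param nrow,ncol Grid dimensions (pixels).
#' @param xmin,ymin Coordinates of the lower-left corner of the grid.
#' @param res Pixel edge length (map units); pixels are square.
#' @param crs Free-text coordinate reference tag, carried through unmodified.
#' @return An object of class `grid_geom`.
#' @export
grid_geom <- function(nrow, ncol, xmin = 0, ymin = 0, res = 1, crs = "local") {
  stopifnot(nrow >= 1, ncol >= 1, res > 0)
  structure(list(nrow = as.integer(nrow), ncol = as.integer(ncol),
                 xmin = xmin, ymin = ymin, res = res, crs = crs),
            class = "grid_geom")
}

## x/y cell edge coordinates, length ncol+1 / nrow+1 (y increasing upward)
.geom_xedges <- function(g) g$xmin + g$res * (0:g$ncol)
.geom_yedges <- function(g) g$ymin + g$res * (0:g$nrow)

## pixel-centre coordinates for matrix cell (i, j); row 1 = top
.geom_centres <- function(g) {
  xs <- g$xmin + g$res * (seq_len(g$ncol) - 0.5)
  ys <- g$ymin + g$res * (g$nrow - seq_len(g$nrow) + 0.5)
  list(x = xs, y = ys)
}

.check_same_dim <- function(layers) {
  dims <- vapply(layers, function(m) paste(dim(m), collapse = "x"), "")
  if (length(unique(dims)) > 1L) {
    stop("misaligned grids: ", paste(sprintf("%s [%s]", names(dims), dims),
                                     collapse = ", "))
  }
  invisible(dim(layers[[1]]))
}

#' Land-use grid container
#'
#' Bundles a per-pixel broad land-use class layer with an optional intensity
#' layer. The class layer must be fully populated; intensity is defined only
#' on classes with an intensity continuum and lies in \[0, 1\] there.
#'
#' @param class Character matrix of broad class codes (see
#'   [land_use_classes()]).
#' @param intensity Optional numeric matrix of intensity scores in \[0, 1\]
#'   (`NA` where the class has no continuum).
#' @param geom Optional [grid_geom()].
#' @return An object of class `land_use_grid`.
#' @export
land_use_grid <- function(class, intensity = NULL, geom = NULL) {
  stopifnot(is.matrix(class))
  if (anyNA(class)) stop("class layer must be fully populated")
  bad <- setdiff(unique(as.vector(class)), .lu_classes)
  if (length(bad)) stop("unknown land-use class code(s): ",
                        paste(bad, collapse = ", "))
  if (!is.null(intensity)) {
    stopifnot(is.matrix(intensity), all(dim(intensity) == dim(class)))
    th <- intensity[!is.na(intensity)]
    if (length(th) && (min(th) < 0 || max(th) > 1))
      stop("intensity values must lie in [0, 1]")
  }
  if (is.null(geom)) geom <- grid_geom(nrow(class), ncol(class))
  structure(list(class = class, intensity = intensity, geom = geom),
            class = "land_use_grid")
}

#' @export
print.land_use_grid <- function(x, ...) {
  cat(sprintf("<land_use_grid> %d x %d pixels\n", nrow(x$class), ncol(x$class)))
  print(round(prop.table(table(x$class)), 3))
  invisible(x)
}

#' Resample a variable onto a target grid by area overlap
#'
#' Transfers a gridded variable to a differently-resolved, overlapping grid.
#' In `sum` mode each target pixel receives the source mass falling inside it
#' (each source value is treated as a per-pixel total and split in proportion
#' to overlap area), which conserves total mass up to edge effects. In
#' `weighted_mean` mode each target pixel receives the overlap-area-weighted
#' mean of the source values it intersects.
#'
#' @param values Numeric matrix on `src` geometry.
#' @param src,target [grid_geom()] of the source and target grids.
#' @param mode `"sum"` (land-cover fractions) or `"weighted_mean"`
#'   (everything else).
#' @return Numeric matrix on the target geometry.
#' @export
resample_overlap <- function(values, src, target,
                             mode = c("weighted_mean", "sum")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(values), nrow(values) == src$nrow,
            ncol(values) == src$ncol)
  ov1d <- function(dst_edges, src_edges) {
    nd <- length(dst_edges) - 1L; ns <- length(src_edges) - 1L
    m <- matrix(0, nd, ns)
    for (i in seq_len(nd)) {
      lo <- pmax(dst_edges[i], src_edges[-length(src_edges)])
      hi <- pmin(dst_edges[i + 1L], src_edges[-1L])
      m[i, ] <- pmax(0, hi - lo)
    }
    m
  }
  Rx <- ov1d(.geom_xedges(target), .geom_xedges(src))
  ## y edges ascend but matrix row 1 is the top row: reverse both axes
  Ry <- ov1d(rev(.geom_yedges(target)) * -1, rev(.geom_yedges(src)) * -1)
  if (all(Rx == 0) || all(Ry == 0)) stop("source and target extents are disjoint")
  if (mode == "sum") {
    Ry %*% (values / src$res^2) %*% t(Rx)
  } else {
    num <- Ry %*% values %*% t(Rx)
    den <- Ry %*% matrix(1, src$nrow, src$ncol) %*% t(Rx)
    out <- num / den
    out[den == 0] <- NA_real_
    out
  }
}

#' Fill missing pixels from the nearest provided value
#'
#' Each `NA` pixel takes the value of the nearest non-missing pixel
#' (Euclidean distance in grid coordinates). Distance ties are broken by the
#' row-major order of the candidate donors.
#'
#' @param grid Numeric matrix with at least one non-missing pixel.
#' @return The matrix with all `NA`s replaced.
#' @export
impute_missing <- function(grid) {
  stopifnot(is.matrix(grid))
  miss <- which(is.na(grid))
  if (!length(miss)) return(grid)
  don <- which(!is.na(grid))
  if (!length(don)) stop("grid is fully missing; nothing to impute from")
  nr <- nrow(grid)
  ## row-major donor order so which.min's first-minimum rule breaks ties
  rm_index <- function(idx) (((idx - 1L) %% nr)) * ncol(grid) + ((idx - 1L) %/% nr) + 1L
  don <- don[order(rm_index(don))]
  dr <- ((don - 1L) %% nr) + 1L; dc <- ((don - 1L) %/% nr) + 1L
  mr <- ((miss - 1L) %% nr) + 1L; mc <- ((miss - 1L) %/% nr) + 1L
  vals <- grid[don]
  for (k in seq_along(miss)) {
    d2 <- (dr - mr[k])^2 + (dc - mc[k])^2
    grid[miss[k]] <- vals[which.min(d2)]
  }
  grid
}
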