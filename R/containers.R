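#' Lake geometry: shoreline, islands and depth-labelled isobaths
#'
#' Container for the planar geometry of one lake: a closed shoreline polygon
#' (metres, planar metric coordinates), optional island rings, and isobath
#' polylines each labelled with a positive depth. The shoreline is the 0 m
#' depth contour.
#'
#' @param shoreline n x 2 numeric matrix of shoreline vertices (m). Treated
#'   as a closed ring.
#' @param isobaths list of isobath descriptors, each a list with elements
#'   `depth` (m, positive scalar), `coords` (n x 2 matrix) and optional
#'   `closed` (logical, default `TRUE`).
#' @param islands optional list of island rings (n x 2 matrices).
#' @param z_max maximum lake depth (m). Defaults to the deepest isobath.
#' @param flat_depth optional constant depth (m) used by
#'   [interpolate_depth()] when no isobaths are given.
#' @param lake_id identifier, default `"lake"`.
#'
#' @return An object of class `lake_geometry` with the fields above plus
#'   `lake_area_ha`, the shoreline polygon area in hectares (islands
#'   subtracted).
#' @export
lake_geometry <- function(shoreline, isobaths = list(), islands = list(),
                          z_max = NULL, flat_depth = NULL, lake_id = "lake") {
  shoreline <- as.matrix(shoreline)
  if (ncol(shoreline) != 2L || nrow(shoreline) < 3L)
    stop("shoreline must be an n x 2 matrix with at least 3 vertices")
  if (anyNA(shoreline)) stop("shoreline contains missing coordinates")
  if (.ring_self_intersects(shoreline))
    stop("shoreline polygon is degenerate (self-intersecting)")
  isobaths <- lapply(isobaths, function(iso) {
    if (is.null(iso$depth) || iso$depth <= 0)
      stop("every isobath needs a positive depth label")
    iso$coords <- as.matrix(iso$coords)
    if (is.null(iso$closed)) iso$closed <- TRUE
    iso
  })
  depths <- vapply(isobaths, function(i) i$depth, numeric(1))
  if (is.null(z_max)) z_max <- if (length(depths)) max(depths) else flat_depth
  if (is.null(z_max)) stop("z_max is required when no isobaths are given")
  if (length(depths) && any(depths > z_max + 1e-9))
    stop(sprintf("isobath at %.2f m is deeper than z_max = %.2f m",
                 max(depths), z_max))
  area <- polygon_area(shoreline) -
    sum(vapply(islands, polygon_area, numeric(1)))
  structure(
    list(shoreline = .ring_open(shoreline), islands = islands,
         isobaths = isobaths, z_max = z_max, flat_depth = flat_depth,
         lake_area_ha = area / 1e4, lake_id = lake_id),
    class = "lake_geometry")
}

# Segment-pair sweep; O(n^2) but rings here are modest (<= a few thousand).
#' @noRd
.ring_self_intersects <- function(ring) {
  p <- .ring_close(ring)
  n <- nrow(p) - 1L
  if (n > 2048L) return(FALSE)  # generator rings are star-shaped by design
  for (i in seq_len(n - 2L)) {
    jmax <- if (i == 1L) n - 1L else n
    js <- seq.int(i + 2L, jmax)
    if (!length(js)) next
    a1 <- p[i, ]; a2 <- p[i + 1L, ]
    b1 <- p[js, , drop = FALSE]; b2 <- p[js + 1L, , drop = FALSE]
    d1x <- a2[1L] - a1[1L]; d1y <- a2[2L] - a1[2L]
    d2x <- b2[, 1L] - b1[, 1L]; d2y <- b2[, 2L] - b1[, 2L]
    den <- d1x * d2y - d1y * d2x
    ok <- abs(den) > 1e-15
    t <- ((b1[, 1L] - a1[1L]) * d2y - (b1[, 2L] - a1[2L]) * d2x) / den
    u <- ((b1[, 1L] - a1[1L]) * d1y - (b1[, 2L] - a1[2L]) * d1x) / den
    if (any(ok & t > 1e-12 & t < 1 - 1e-12 & u > 1e-12 & u < 1 - 1e-12))
      return(TRUE)
  }
  FALSE
}

#' @export
print.lake_geometry <- function(x, ...) {
  cat(sprintf("<lake_geometry> %s: area %.1f ha, z_max %.1f m, %d isobath(s), %d island(s)\n",
              x$lake_id, x$lake_area_ha, x$z_max,
              length(x$isobaths), length(x$islands)))
  invisible(x)
}

#' Regular depth raster of a lake
#'
#' Cell-centre registered grid of water depth (m). `values` is masked to the
#' lake polygon (`NA` outside); `surface` optionally carries the unclipped
#' interpolated surface (negative "land" values outside the shoreline) used
#' by [slope_raster()] so that gradients at shore cells are unbiased.
#'
#' @param origin coordinates (x, y) of the centre of cell `[1, 1]`
#'   (lower-left cell).
#' @param cell_size cell edge length (m), default 1.
#' @param values depth matrix, `nrow` = number of y rows (south to north),
#'   `ncol` = number of x columns (west to east).
#' @param surface optional unclipped depth surface, same dimension.
#'
#' @return An object of class `depth_grid`.
#' @export
depth_grid <- function(origin, cell_size = 1, values, surface = NULL) {
  stopifnot(length(origin) == 2L, cell_size > 0, is.matrix(values))
  if (!is.null(surface)) stopifnot(identical(dim(surface), dim(values)))
  structure(list(origin = as.numeric(origin), cell_size = cell_size,
                 values = values, surface = surface),
            class = "depth_grid")
}

#' @export
print.depth_grid <- function(x, ...) {
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf("<depth_grid> %d x %d cells @ %g m, depth %.2f-%.2f m (%d wet cells)\n",
              nrow(x$values), ncol(x$values), x$cell_size,
              rng[1], rng[2], sum(!is.na(x$values))))
  invisible(x)
}

#' Cell-centre coordinate axes of a grid
#'
#' @param grid a `depth_grid` (or slope raster of the same shape).
#' @return list with `x` (column centres) and `y` (row centres), metres.
#' @export
grid_axes <- function(grid) {
  list(x = grid$origin[1L] + (seq_len(ncol(grid$values)) - 1L) * grid$cell_size,
       y = grid$origin[2L] + (seq_len(nrow(grid$values)) - 1L) * grid$cell_size)
}

#' Survey transect anchored on the shoreline
#'
#' @param transect_id identifier.
#' @param anchor length-2 numeric, shoreline anchor point (m).
#' @param onshore_normal_deg compass bearing of the inward (towards open
#'   water) perpendicular, degrees in \eqn{[0, 360)}.
#' @param width transect width (m), default 30.
#' @param c_max_tr observed maximum colonisation depth on the transect (m),
#'   may be `NA` before the survey is attached.
#' @param lake_id lake identifier.
#' @return An object of class `transect`.
#' @export
transect <- function(transect_id, anchor, onshore_normal_deg, width = 30,
                     c_max_tr = NA_real_, lake_id = "lake") {
  stopifnot(length(anchor) == 2L, width > 0)
  structure(list(transect_id = transect_id, anchor = as.numeric(anchor),
                 onshore_normal_deg = onshore_normal_deg %% 360,
                 width = width, c_max_tr = c_max_tr, lake_id = lake_id),
            class = "transect")
}

#' @export
print.transect <- function(x, ...) {
  cat(sprintf("<transect> %s @ (%.1f, %.1f), inward normal %.1f deg, width %g m\n",
              x$transect_id, x$anchor[1L], x$anchor[2L],
              x$onshore_normal_deg, x$width))
  invisible(x)
}
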