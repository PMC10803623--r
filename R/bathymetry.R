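# Bathymetry: contour-to-raster interpolation, Horn slope, zonal statistics.

#' Interpolate a depth raster from shoreline and isobaths
#'
#' Builds a cell-centre registered depth grid from the lake geometry. The
#' shoreline is the 0 m contour; depth at each cell is interpolated linearly
#' between the two nearest contours of distinct depth, by Euclidean distance
#' to the contour polylines. Inside the deepest closed isobath and outside
#' the shoreline the surface is continued linearly, so the grid carries a
#' smooth unclipped surface for slope derivation; reported depths are masked
#' to the lake polygon and clamped at 0.
#'
#' With no isobaths the geometry must carry a `flat_depth` tag, in which case
#' all wet cells get that constant depth.
#'
#' @param geometry a [lake_geometry()].
#' @param cell_size raster resolution in metres (default 1).
#' @param margin extra cells kept around the bounding box (default 2).
#' @param max_contour_vertices closed isobath rings are resampled down to
#'   this many vertices before distance and containment sweeps (default
#'   256); raise it for very convoluted real contours.
#' @return A [depth_grid()] honouring every labelled isobath to within half
#'   a cell.
#' @export
interpolate_depth <- function(geometry, cell_size = 1, margin = 2L,
                              max_contour_vertices = 256L) {
  stopifnot(inherits(geometry, "lake_geometry"), cell_size > 0)
  .check_isobath_topology(geometry)
  # resample closed rings so cost scales with the grid, not digitisation
  slim <- function(coords, closed) {
    if (closed && nrow(coords) > max_contour_vertices)
      resample_ring(coords, max_contour_vertices) else coords
  }
  geometry$isobaths <- lapply(geometry$isobaths, function(iso) {
    iso$coords <- slim(iso$coords, isTRUE(iso$closed)); iso
  })

  sh <- geometry$shoreline
  xr <- range(sh[, 1L]) + c(-1, 1) * margin * cell_size
  yr <- range(sh[, 2L]) + c(-1, 1) * margin * cell_size
  xs <- seq(xr[1L], xr[2L], by = cell_size)
  ys <- seq(yr[1L], yr[2L], by = cell_size)
  nx <- length(xs); ny <- length(ys)
  px <- rep(xs, each = ny)   # column-major over [ny, nx] matrix
  py <- rep(ys, times = nx)

  inside <- point_in_lake(px, py, geometry)

  depths <- vapply(geometry$isobaths, function(i) i$depth, numeric(1))
  levels <- sort(unique(c(0, depths)))

  if (length(levels) == 1L) {
    if (is.null(geometry$flat_depth))
      stop("no isobaths: geometry needs a flat_depth tag or >= 1 isobath")
    surface <- matrix(geometry$flat_depth, nrow = ny, ncol = nx)
    values <- surface
    values[!inside] <- NA_real_
    return(depth_grid(c(xs[1L], ys[1L]), cell_size, values,
                      surface = surface))
  }

  # distance from every cell centre to every contour level
  D <- matrix(Inf, nrow = length(px), ncol = length(levels))
  shoreline_rings <- c(list(list(coords = sh, closed = TRUE)),
                       lapply(geometry$islands,
                              function(r) list(coords = r, closed = TRUE)))
  for (k in seq_along(levels)) {
    plines <- if (levels[k] == 0) shoreline_rings else
      Filter(function(i) i$depth == levels[k], geometry$isobaths)
    for (pl in plines) {
      D[, k] <- pmin(D[, k],
                     dist_to_polyline(px, py, pl$coords,
                                      closed = isTRUE(pl$closed)))
    }
  }

  all_closed <- all(vapply(geometry$isobaths, function(i) isTRUE(i$closed),
                           logical(1)))
  if (all_closed) {
    # band interpolation: nesting depth of each cell among the closed
    # contours picks the bracketing levels; linear between them by
    # distance, linear continuation outside the bracketed range
    m <- length(levels) - 1L  # positive levels
    band <- as.integer(inside)  # 0 outside shoreline, else 1 + #rings in
    for (k in seq_len(m)) {
      rings_k <- Filter(function(i) i$depth == levels[k + 1L],
                        geometry$isobaths)
      in_k <- Reduce(`|`, lapply(rings_k, function(r)
        point_in_ring(px, py, r$coords)))
      band <- band + as.integer(in_k)
    }
    depth <- numeric(length(px))
    for (b in unique(band)) {
      sel <- band == b
      if (b == 0L) {            # outside the shoreline: continue negative
        d0 <- D[sel, 1L]; d1 <- D[sel, 2L]
        depth[sel] <- -levels[2L] * d0 / pmax(d1 - d0, cell_size / 2)
      } else if (b <= m) {      # between contour b-1 and contour b
        do_ <- D[sel, b]; di <- D[sel, b + 1L]
        depth[sel] <- (levels[b] * di + levels[b + 1L] * do_) / (do_ + di)
      } else {                  # inside the deepest contour: continue
        di <- D[sel, m + 1L]; do_ <- D[sel, m]
        depth[sel] <- levels[m + 1L] + (levels[m + 1L] - levels[m]) *
          di / pmax(do_ - di, cell_size / 2)
      }
    }
  } else {
    # open contours: interpolate between the two nearest distinct levels
    l1 <- max.col(-D, ties.method = "first")
    d1 <- D[cbind(seq_along(l1), l1)]
    D2 <- D
    D2[cbind(seq_along(l1), l1)] <- Inf
    l2 <- max.col(-D2, ties.method = "first")
    d2 <- D2[cbind(seq_along(l2), l2)]
    z1 <- levels[l1]; z2 <- levels[l2]
    depth <- (z1 * d2 + z2 * d1) / (d1 + d2)
    out <- !inside
    if (any(out)) {
      gap <- pmax(d2[out] - d1[out], cell_size / 2)
      depth[out] <- z1[out] - (z2[out] - z1[out]) * d1[out] / gap
    }
  }

  surface <- matrix(depth, nrow = ny, ncol = nx)
  values <- surface
  values[!matrix(inside, nrow = ny, ncol = nx)] <- NA_real_
  values[values < 0] <- 0
  depth_grid(c(xs[1L], ys[1L]), cell_size, values, surface = surface)
}

# Isobaths must lie within the shoreline and nest by depth.
#' @noRd
.check_isobath_topology <- function(geometry) {
  for (iso in geometry$isobaths) {
    ins <- point_in_ring(iso$coords[, 1L], iso$coords[, 2L],
                         geometry$shoreline)
    if (!all(ins))
      stop(sprintf("isobath at %.2f m crosses or lies outside the shoreline",
                   iso$depth))
  }
  isos <- geometry$isobaths
  if (length(isos) < 2L) return(invisible(TRUE))
  for (i in seq_along(isos)) {
    for (j in seq_along(isos)) {
      if (isos[[i]]$depth >= isos[[j]]$depth || !isTRUE(isos[[i]]$closed))
        next
      # deeper ring j must be wholly inside or wholly outside shallower i
      ins <- point_in_ring(isos[[j]]$coords[, 1L], isos[[j]]$coords[, 2L],
                           isos[[i]]$coords)
      if (any(ins) && !all(ins))
        stop(sprintf("isobaths at %.2f m and %.2f m cross each other",
                     isos[[i]]$depth, isos[[j]]$depth))
    }
  }
  invisible(TRUE)
}

#' Slope raster (degrees) from a depth grid
#'
#' Horn 3x3 finite differences, the operator behind the standard GIS slope
#' tool: per cell the gradient is a weighted difference of the eight
#' neighbours, and slope = arctan of the gradient magnitude. Raster edges
#' use nearest-neighbour padding. When the grid carries an unclipped
#' `surface` (as produced by [interpolate_depth()] and [make_lake()]) the
#' gradient is taken on it, so shore cells are not flattened by the mask;
#' the result is masked to wet cells either way.
#'
#' @param grid a [depth_grid()].
#' @return A grid-shaped object of class `slope_raster` with `values` in
#'   degrees (`NA` outside the lake).
#' @export
slope_raster <- function(grid) {
  stopifnot(inherits(grid, "depth_grid"))
  z <- if (!is.null(grid$surface)) grid$surface else grid$values
  if (sum(!is.na(z)) < 9L || nrow(z) < 3L || ncol(z) < 3L)
    stop("depth grid needs at least 3 x 3 valid cells")
  if (anyNA(z)) z <- .fill_na_nearest(z)
  cs <- grid$cell_size
  ny <- nrow(z); nx <- ncol(z)
  # nearest-neighbour padding
  zp <- rbind(z[1L, , drop = FALSE], z, z[ny, , drop = FALSE])
  zp <- cbind(zp[, 1L, drop = FALSE], zp, zp[, nx, drop = FALSE])
  sh <- function(di, dj) zp[(1L + di):(ny + di), (1L + dj):(nx + dj)]
  # Horn kernel: x increases with column, y with row
  gx <- ((sh(0L, 2L) + 2 * sh(1L, 2L) + sh(2L, 2L)) -
         (sh(0L, 0L) + 2 * sh(1L, 0L) + sh(2L, 0L))) / (8 * cs)
  gy <- ((sh(2L, 1L) * 2 + sh(2L, 0L) + sh(2L, 2L)) -
         (sh(0L, 1L) * 2 + sh(0L, 0L) + sh(0L, 2L))) / (8 * cs)
  slope <- atan(sqrt(gx^2 + gy^2)) * 180 / pi
  slope[is.na(grid$values)] <- NA_real_
  structure(list(origin = grid$origin, cell_size = cs, values = slope),
            class = c("slope_raster", "depth_grid"))
}

# Fill NA cells from valid neighbours (iterative dilation).
#' @noRd
.fill_na_nearest <- function(z) {
  for (pass in seq_len(max(dim(z)))) {
    nas <- which(is.na(z), arr.ind = TRUE)
    if (!nrow(nas)) break
    ny <- nrow(z); nx <- ncol(z)
    filled <- z
    for (k in seq_len(nrow(nas))) {
      i <- nas[k, 1L]; j <- nas[k, 2L]
      nb <- z[max(1L, i - 1L):min(ny, i + 1L),
              max(1L, j - 1L):min(nx, j + 1L)]
      v <- nb[!is.na(nb)]
      if (length(v)) filled[i, j] <- mean(v)
    }
    if (identical(filled, z)) break
    z <- filled
  }
  z[is.na(z)] <- 0
  z
}

#' Bilinear depth lookup at arbitrary points
#'
#' @param grid a [depth_grid()].
#' @param x,y point coordinates (m), vectorised.
#' @param use_surface use the unclipped surface when available.
#' @return depths (m); `NA` outside the grid extent.
#' @export
depth_at <- function(grid, x, y, use_surface = TRUE) {
  z <- if (use_surface && !is.null(grid$surface)) grid$surface else grid$values
  ax <- grid_axes(grid)
  cs <- grid$cell_size
  fx <- (x - ax$x[1L]) / cs + 1
  fy <- (y - ax$y[1L]) / cs + 1
  j0 <- pmin(pmax(floor(fx), 1L), ncol(z) - 1L)
  i0 <- pmin(pmax(floor(fy), 1L), nrow(z) - 1L)
  tx <- pmin(pmax(fx - j0, 0), 1)
  ty <- pmin(pmax(fy - i0, 0), 1)
  v00 <- z[cbind(i0, j0)]; v01 <- z[cbind(i0, j0 + 1L)]
  v10 <- z[cbind(i0 + 1L, j0)]; v11 <- z[cbind(i0 + 1L, j0 + 1L)]
  out <- (1 - ty) * ((1 - tx) * v00 + tx * v01) +
    ty * ((1 - tx) * v10 + tx * v11)
  out[fx < 0.5 | fy < 0.5 | fx > ncol(z) + 0.5 | fy > nrow(z) + 0.5] <- NA_real_
  out
}

#' Littoral zone of a transect on the depth grid
#'
#' The zone is a rectangle `width` metres wide along the transect's inward
#' normal, starting at the shoreline anchor and truncated where depth along
#' the centreline first reaches `max_depth` (1 m for the shallow littoral,
#' the isobath depth next to the lake's C_max for the deep littoral). If the
#' target depth is never reached the zone runs to where the centreline
#' leaves the lake, with a warning.
#'
#' @param transect a [transect()].
#' @param geometry the lake's [lake_geometry()].
#' @param grid the lake's [depth_grid()].
#' @param max_depth truncation depth (m).
#' @return list of class `transect_zone`: `cells` (data frame of row/col
#'   indices and centre coordinates of wet cells inside the rectangle),
#'   `length_m`, `truncated` (did the centreline reach `max_depth`).
#' @export
transect_zone <- function(transect, geometry, grid, max_depth) {
  stopifnot(inherits(transect, "transect"), inherits(grid, "depth_grid"),
            max_depth > 0)
  a <- transect$anchor
  if (dist_to_polyline(a[1L], a[2L], geometry$shoreline, closed = TRUE) >
      grid$cell_size)
    stop("transect anchor is more than one cell away from the shoreline")
  dir <- bearing_to_vec(transect$onshore_normal_deg)[1L, ]
  prp <- c(dir[2L], -dir[1L])

  step <- grid$cell_size / 2
  ax <- grid_axes(grid)
  tmax <- sqrt(diff(range(ax$x))^2 + diff(range(ax$y))^2)
  ts <- seq(step, tmax, by = step)
  pxs <- a[1L] + ts * dir[1L]
  pys <- a[2L] + ts * dir[2L]
  dep <- depth_at(grid, pxs, pys, use_surface = TRUE)
  inlake <- point_in_lake(pxs, pys, geometry) & !is.na(dep)
  first_out <- which(!inlake)[1L]
  reach <- which(inlake & dep >= max_depth)[1L]
  if (!is.na(reach) && (is.na(first_out) || reach < first_out)) {
    L <- ts[reach]
    truncated <- TRUE
  } else {
    L <- if (is.na(first_out)) tmax else if (first_out == 1L) 0 else
      ts[first_out - 1L]
    truncated <- FALSE
    warning(sprintf("transect %s: depth %.2f m never reached; zone runs %.1f m to the far shore",
                    transect$transect_id, max_depth, L))
  }

  xs <- rep(ax$x, each = length(ax$y))
  ys <- rep(ax$y, times = length(ax$x))
  u <- (xs - a[1L]) * dir[1L] + (ys - a[2L]) * dir[2L]
  v <- (xs - a[1L]) * prp[1L] + (ys - a[2L]) * prp[2L]
  wet <- !is.na(as.vector(grid$values))
  sel <- which(wet & u >= 0 & u <= L & abs(v) <= transect$width / 2)
  if (!length(sel)) stop(sprintf("transect %s: empty littoral zone",
                                 transect$transect_id))
  iy <- ((sel - 1L) %% length(ax$y)) + 1L
  ix <- ((sel - 1L) %/% length(ax$y)) + 1L
  structure(list(cells = data.frame(row = iy, col = ix,
                                    x = xs[sel], y = ys[sel]),
                 length_m = L, truncated = truncated,
                 transect_id = transect$transect_id),
            class = "transect_zone")
}

#' Mean slope over a transect zone
#'
#' Arithmetic mean of the slope raster over the zone cells (the zonal
#' statistics step of the GIS workflow).
#'
#' @param zone a [transect_zone()] (or a data frame with `row`/`col`).
#' @param slope a [slope_raster()].
#' @return mean slope in degrees.
#' @export
zonal_slope <- function(zone, slope) {
  cells <- if (inherits(zone, "transect_zone")) zone$cells else zone
  if (!nrow(cells)) stop("empty zone")
  v <- slope$values[cbind(cells$row, cells$col)]
  v <- v[!is.na(v)]
  if (!length(v)) stop("zone contains no valid slope cells")
  mean(v)
}

#' Convert a slope angle to percent grade
#'
#' Percent grade is `tan(angle) * 100`; reported values follow the printed
#' convention of rounding half-up to one decimal.
#'
#' @param angle_deg slope angle(s), degrees in \eqn{[0, 90)}.
#' @param report round half-up to 1 decimal (default `FALSE`).
#' @return percent grade.
#' @examples
#' deg_to_pct(8.42, report = TRUE)  # 14.8
#' @export
deg_to_pct <- function(angle_deg, report = FALSE) {
  if (any(is.na(angle_deg)) || any(angle_deg < 0) || any(angle_deg >= 90))
    stop("slope angle must lie in [0, 90) degrees")
  pct <- tan(.deg2rad(angle_deg)) * 100
  if (report) round_half_up(pct, 1L) else pct
}

#' Classify deep-littoral slope into steepness classes
#'
#' Gentle below 1.32 deg (2.3 % grade), steep above 8.42 deg (14.8 %),
#' moderate in between; both boundaries are strict, so the boundary values
#' themselves fall in the moderate class.
#'
#' @param sl_cmax_deg deep littoral slope(s), degrees.
#' @param thresholds named numeric `c(gentle = 1.32, steep = 8.42)`.
#' @return factor with levels `gentle`, `moderate`, `steep`.
#' @export
classify_slope <- function(sl_cmax_deg,
                           thresholds = c(gentle = 1.32, steep = 8.42)) {
  stopifnot(thresholds[["gentle"]] < thresholds[["steep"]])
  cls <- ifelse(sl_cmax_deg < thresholds[["gentle"]], "gentle",
         ifelse(sl_cmax_deg > thresholds[["steep"]], "steep", "moderate"))
  factor(cls, levels = c("gentle", "moderate", "steep"))
}

#' Per-transect littoral slopes from the full raster pipeline
#'
#' Convenience wrapper: slope raster, shallow (to 1 m) and deep (to the
#' isobath next to the lake's maximum colonisation depth) zonal slopes and
#' the steepness class for a set of transects.
#'
#' @param transects list of [transect()] objects.
#' @param geometry the [lake_geometry()].
#' @param grid the [depth_grid()].
#' @param cmax_iso_depth truncation depth (m) for the deep littoral; by
#'   default the labelled isobath nearest the lake-wide maximum C_max
#'   (ties towards the deeper isobath), or that C_max itself when the
#'   geometry has no isobaths.
#' @return data frame with one row per transect: `transect_id`,
#'   `sl_1m_deg`, `sl_cmax_deg`, `sl_1m_pct`, `sl_cmax_pct`, `slope_class`.
#' @export
transect_slopes <- function(transects, geometry, grid,
                            cmax_iso_depth = NULL) {
  slope <- slope_raster(grid)
  if (is.null(cmax_iso_depth)) {
    cmax <- suppressWarnings(max(vapply(transects, function(t) t$c_max_tr,
                                        numeric(1)), na.rm = TRUE))
    if (!is.finite(cmax)) cmax <- geometry$z_max
    depths <- vapply(geometry$isobaths, function(i) i$depth, numeric(1))
    cmax_iso_depth <- if (length(depths)) .nearest_isobath(depths, cmax)
                      else cmax
  }
  rows <- lapply(transects, function(tr) {
    z1 <- transect_zone(tr, geometry, grid, max_depth = 1)
    zc <- transect_zone(tr, geometry, grid, max_depth = cmax_iso_depth)
    s1 <- zonal_slope(z1, slope)
    sc <- zonal_slope(zc, slope)
    data.frame(transect_id = tr$transect_id, lake_id = tr$lake_id,
               sl_1m_deg = s1, sl_cmax_deg = sc,
               sl_1m_pct = deg_to_pct(s1, report = TRUE),
               sl_cmax_pct = deg_to_pct(sc, report = TRUE),
               slope_class = as.character(classify_slope(sc)))
  })
  do.call(rbind, rows)
}

# Labelled isobath nearest to cmax, ties broken towards the deeper one.
#' @noRd
.nearest_isobath <- function(depths, cmax) {
  depths <- sort(unique(depths))
  gap <- abs(depths - cmax)
  cand <- depths[gap == min(gap)]
  max(cand)
}
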