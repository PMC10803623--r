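# Synthetic lakes with analytically known bathymetry.
#
# Shapes are star-shaped around the centroid (circle, ellipse, or a radius
# perturbed by low-order Fourier terms), so every ray from the centre meets
# the shoreline exactly once and inward offsets of the shoreline are the
# exact level sets of distance-to-shore. Depth is a function of distance to
# the shoreline, which makes the true slope known in closed form at every
# cell.

#' Specification of a synthetic lake
#'
#' @param shape `"circle"`, `"ellipse"` or `"irregular"` (harmonic radius
#'   perturbation).
#' @param radius_m lake radius (m); for `"ellipse"` the semi-major axis.
#' @param axes_m length-2 semi-axes (m) for `"ellipse"`; default
#'   `c(radius_m, 0.7 * radius_m)`.
#' @param max_depth_m maximum depth (m).
#' @param profile depth-vs-shore-distance profile: `"conic"` (linear to
#'   `max_depth_m` at the lake centre), `"planar-shelf"` (constant grade
#'   `shelf_slope`, capped at `max_depth_m`) or `"two-slope"` (grade
#'   `slope1` down to `break_depth`, then `slope2`).
#' @param shelf_slope grade (rise per metre) of the planar shelf, default 0.1.
#' @param slope1,slope2,break_depth two-slope profile parameters.
#' @param n_transects number of survey transects; the national survey design
#'   places 8 to 27 per lake depending on lake size.
#' @param irregularity relative amplitude of the harmonic perturbation for
#'   `"irregular"` (kept small so the polygon stays simple and star-shaped).
#' @param n_vertices shoreline vertices (rounded up to a multiple of
#'   `n_transects` so anchors coincide with vertices).
#' @param seed integer seed; identical seeds give bit-identical lakes.
#' @return An object of class `lake_spec`.
#' @export
lake_spec <- function(shape = c("circle", "ellipse", "irregular"),
                      radius_m = 500, axes_m = NULL, max_depth_m = 10,
                      profile = c("conic", "planar-shelf", "two-slope"),
                      shelf_slope = 0.1, slope1 = 0.05, slope2 = 0.2,
                      break_depth = 2, n_transects = 12,
                      irregularity = 0.06, n_vertices = 512, seed = 1L) {
  shape <- match.arg(shape)
  profile <- match.arg(profile)
  stopifnot(radius_m > 0, max_depth_m > 0, n_transects >= 4,
            shelf_slope > 0, slope1 > 0, slope2 > 0, break_depth > 0)
  if (n_transects < 8 || n_transects > 27)
    message("note: surveys normally place 8-27 transects per lake")
  if (is.null(axes_m)) axes_m <- c(radius_m, 0.7 * radius_m)
  n_vertices <- as.integer(ceiling(n_vertices / n_transects) * n_transects)
  structure(list(shape = shape, radius_m = radius_m, axes_m = axes_m,
                 max_depth_m = max_depth_m, profile = profile,
                 shelf_slope = shelf_slope, slope1 = slope1, slope2 = slope2,
                 break_depth = break_depth, n_transects = n_transects,
                 irregularity = irregularity, n_vertices = n_vertices,
                 seed = as.integer(seed)),
            class = "lake_spec")
}

# Evaluate and restore RNG state so generators are pure given their seed.
#' @noRd
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# radius as a function of polar angle theta (math convention)
#' @noRd
.shape_radius <- function(spec, theta, harmonics = NULL) {
  switch(spec$shape,
    circle = rep(spec$radius_m, length(theta)),
    ellipse = {
      a <- spec$axes_m[1L]; b <- spec$axes_m[2L]
      a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
    },
    irregular = {
      r <- rep(1, length(theta))
      for (h in harmonics)
        r <- r + h$amp * cos(h$k * theta + h$phase)
      spec$radius_m * r
    })
}

# depth (m) at signed distance-to-shore d (negative = outside the lake)
#' @noRd
.profile_depth <- function(spec, d, d_max) {
  switch(spec$profile,
    conic = spec$max_depth_m * d / d_max,
    `planar-shelf` = pmin(spec$shelf_slope * d, spec$max_depth_m),
    `two-slope` = {
      b1 <- spec$break_depth / spec$slope1
      z <- ifelse(d <= b1, spec$slope1 * d,
                  spec$break_depth + spec$slope2 * (d - b1))
      pmin(z, spec$max_depth_m)
    })
}

# inverse of the profile: shore distance at which depth z is reached
#' @noRd
.profile_distance <- function(spec, z, d_max) {
  switch(spec$profile,
    conic = z * d_max / spec$max_depth_m,
    `planar-shelf` = z / spec$shelf_slope,
    `two-slope` = ifelse(z <= spec$break_depth, z / spec$slope1,
                         spec$break_depth / spec$slope1 +
                           (z - spec$break_depth) / spec$slope2))
}

#' Generate a synthetic lake: geometry, depth grid and transects
#'
#' Builds the shoreline polygon, labelled isobaths (inward offsets of the
#' shoreline at the depths where the profile crosses each level), the
#' analytic depth grid (with the continuous unclipped surface retained for
#' slope work), and evenly spaced transects anchored on the shoreline with
#' inward normals.
#'
#' @param spec a [lake_spec()].
#' @param cell_size depth grid resolution (m), default 1.
#' @param isobath_depths depths (m) at which to emit labelled isobaths;
#'   default roughly eight levels spanning the profile.
#' @param lake_id identifier.
#' @return list of class `synthetic_lake` with elements `spec`, `geometry`
#'   ([lake_geometry()]), `grid` ([depth_grid()]) and `transects` (list of
#'   [transect()]).
#' @export
make_lake <- function(spec, cell_size = 1, isobath_depths = NULL,
                      lake_id = "lake") {
  stopifnot(inherits(spec, "lake_spec"))
  harmonics <- if (spec$shape == "irregular") .with_seed(spec$seed, {
    lapply(2:4, function(k) list(k = k,
                                 amp = spec$irregularity * runif(1, 0.3, 1) / (k - 1),
                                 phase = runif(1, 0, 2 * pi)))
  }) else NULL

  nv <- spec$n_vertices
  theta <- seq(0, 2 * pi, length.out = nv + 1L)[-(nv + 1L)]
  r <- .shape_radius(spec, theta, harmonics)
  shoreline <- cbind(r * cos(theta), r * sin(theta))
  if (.ring_self_intersects(shoreline))
    stop("degenerate shoreline polygon (self-intersecting); reduce irregularity")

  # interior reach: maximum distance-to-shore, attained near the centroid
  d_max <- if (spec$shape == "circle") spec$radius_m else
    min(dist_to_polyline(0, 0, shoreline, closed = TRUE),
        min(r))  # star-shaped: centre is the deep point
  reach_depth <- .profile_depth(spec, d_max, d_max)

  if (is.null(isobath_depths)) {
    top <- min(spec$max_depth_m, reach_depth) * 0.95
    isobath_depths <- seq(top / 8, top, length.out = 8L)
  }
  isobaths <- lapply(isobath_depths, function(z) {
    dz <- .profile_distance(spec, z, d_max)
    if (dz >= d_max * 0.99) return(NULL)
    list(depth = z, coords = .inward_offset(shoreline, dz), closed = TRUE)
  })
  isobaths <- Filter(Negate(is.null), isobaths)

  geometry <- lake_geometry(shoreline, isobaths = isobaths,
                            z_max = min(spec$max_depth_m, reach_depth),
                            lake_id = lake_id)

  grid <- .analytic_grid(spec, geometry, cell_size, d_max)
  transects <- .place_transects(spec, shoreline, lake_id)
  structure(list(spec = spec, geometry = geometry, grid = grid,
                 transects = transects),
            class = "synthetic_lake")
}

# inward offset of the shoreline by distance d (vertex-normal offset;
# exact level set for smooth star-shaped rings with d below the minimum
# curvature radius)
#' @noRd
.inward_offset <- function(ring, d) {
  p <- .ring_open(ring)
  n <- nrow(p)
  nxt <- c(2:n, 1L); prv <- c(n, 1:(n - 1L))
  tx <- p[nxt, 1L] - p[prv, 1L]
  ty <- p[nxt, 2L] - p[prv, 2L]
  len <- sqrt(tx^2 + ty^2)
  # counter-clockwise ring: interior lies left of the travel direction
  nxv <- -ty / len; nyv <- tx / len
  inward <- cbind(p[, 1L] + d * nxv, p[, 2L] + d * nyv)
  if (polygon_area(inward) > polygon_area(p))  # ring was clockwise: flip
    inward <- cbind(p[, 1L] - d * nxv, p[, 2L] - d * nyv)
  inward
}

#' @noRd
.analytic_grid <- function(spec, geometry, cell_size, d_max) {
  sh <- geometry$shoreline
  xr <- range(sh[, 1L]) + c(-2, 2) * cell_size
  yr <- range(sh[, 2L]) + c(-2, 2) * cell_size
  xs <- seq(xr[1L], xr[2L], by = cell_size)
  ys <- seq(yr[1L], yr[2L], by = cell_size)
  px <- rep(xs, each = length(ys))
  py <- rep(ys, times = length(xs))
  inside <- point_in_lake(px, py, geometry)
  d <- if (spec$shape == "circle") {
    spec$radius_m - sqrt(px^2 + py^2)
  } else {
    s <- dist_to_polyline(px, py, sh, closed = TRUE)
    ifelse(inside, s, -s)
  }
  depth <- .profile_depth(spec, d, d_max)
  surface <- matrix(depth, nrow = length(ys), ncol = length(xs))
  values <- surface
  values[!matrix(inside, nrow = length(ys), ncol = length(xs))] <- NA_real_
  values[values < 0] <- 0
  depth_grid(c(xs[1L], ys[1L]), cell_size, values, surface = surface)
}

#' @noRd
.place_transects <- function(spec, shoreline, lake_id) {
  nv <- nrow(shoreline)
  idx <- seq(1L, nv, by = nv %/% spec$n_transects)[seq_len(spec$n_transects)]
  lapply(seq_along(idx), function(k) {
    i <- idx[k]
    a <- shoreline[i, ]
    prv <- shoreline[if (i == 1L) nv else i - 1L, ]
    nxt <- shoreline[if (i == nv) 1L else i + 1L, ]
    tx <- nxt[1L] - prv[1L]; ty <- nxt[2L] - prv[2L]
    len <- sqrt(tx^2 + ty^2)
    nx <- ty / len; nyv <- -tx / len
    probe <- a + 0.5 * c(nx, nyv)
    if (!point_in_ring(probe[1L], probe[2L], shoreline)) {
      nx <- -nx; nyv <- -nyv
    }
    transect(transect_id = sprintf("%s_T%02d", lake_id, k), anchor = a,
             onshore_normal_deg = vec_to_bearing(nx, nyv),
             lake_id = lake_id)
  })
}

#' @export
print.synthetic_lake <- function(x, ...) {
  cat(sprintf("<synthetic_lake> %s: %s, %s profile, z_max %.1f m, %d transects\n",
              x$geometry$lake_id, x$spec$shape, x$spec$profile,
              x$geometry$z_max, length(x$transects)))
  invisible(x)
}
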