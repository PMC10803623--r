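# Internal planar geometry primitives.
#
# All coordinates are planar metric (metres). Bearings follow the compass
# convention: 0 deg = +y (north), 90 deg = +x (east), clockwise positive.
# Polygons are n x 2 matrices of vertices; rings are treated as closed
# whether or not the first vertex is repeated.

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

#' @noRd
bearing_to_vec <- function(bearing_deg) {
  b <- .deg2rad(bearing_deg)
  cbind(sin(b), cos(b))
}

#' @noRd
vec_to_bearing <- function(dx, dy) {
  (atan2(dx, dy) * 180 / pi) %% 360
}

# drop a repeated closing vertex
.ring_open <- function(poly) {
  n <- nrow(poly)
  if (n > 1L && all(abs(poly[1L, ] - poly[n, ]) < 1e-12)) poly[-n, , drop = FALSE] else poly
}

.ring_close <- function(poly) {
  poly <- .ring_open(poly)
  rbind(poly, poly[1L, , drop = FALSE])
}

#' @noRd
polygon_area <- function(poly) {
  p <- .ring_open(poly)
  x <- p[, 1L]; y <- p[, 2L]
  abs(sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y)) / 2
}

#' @noRd
polyline_length <- function(coords, closed = FALSE) {
  p <- if (closed) .ring_close(coords) else coords
  sum(sqrt(rowSums(diff(p)^2)))
}

# Even-odd point-in-polygon test, vectorised over points.
#' @noRd
point_in_ring <- function(px, py, ring) {
  ring <- .ring_open(ring)
  n <- nrow(ring)
  xs <- ring[, 1L]; ys <- ring[, 2L]
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- xs[i]; yi <- ys[i]; xj <- xs[j]; yj <- ys[j]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Inside the shoreline and outside every island ring.
#' @noRd
point_in_lake <- function(px, py, geometry) {
  inside <- point_in_ring(px, py, geometry$shoreline)
  for (isl in geometry$islands) {
    inside <- inside & !point_in_ring(px, py, isl)
  }
  inside
}

# Minimum distance from each point to a polyline (sequence of segments).
# Vectorised over points, looped over segments.
#' @noRd
dist_to_polyline <- function(px, py, coords, closed = FALSE) {
  p <- if (closed) .ring_close(coords) else coords
  n <- nrow(p)
  dmin <- rep(Inf, length(px))
  for (i in seq_len(n - 1L)) {
    x1 <- p[i, 1L]; y1 <- p[i, 2L]
    ex <- p[i + 1L, 1L] - x1; ey <- p[i + 1L, 2L] - y1
    len2 <- ex * ex + ey * ey
    if (len2 < 1e-24) {
      d2 <- (px - x1)^2 + (py - y1)^2
    } else {
      t <- ((px - x1) * ex + (py - y1) * ey) / len2
      t <- pmin(1, pmax(0, t))
      d2 <- (px - (x1 + t * ex))^2 + (py - (y1 + t * ey))^2
    }
    dmin <- pmin(dmin, d2)
  }
  sqrt(dmin)
}

# First transversal intersection of the ray (ax,ay) + t*(dx,dy), t > tol,
# with a set of rings. Returns t (distance in metres) or Inf.
#' @noRd
ray_first_hit <- function(ax, ay, dx, dy, rings, tol = 1e-9) {
  tbest <- Inf
  for (ring in rings) {
    p <- .ring_close(ring)
    x1 <- p[-nrow(p), 1L]; y1 <- p[-nrow(p), 2L]
    sx <- diff(p[, 1L]); sy <- diff(p[, 2L])
    denom <- dx * sy - dy * sx
    ok <- abs(denom) > 1e-15
    t <- ((x1 - ax) * sy - (y1 - ay) * sx) / denom
    u <- ((x1 - ax) * dy - (y1 - ay) * dx) / denom
    hit <- ok & t > tol & u >= 0 & u <= 1
    if (any(hit)) tbest <- min(tbest, t[hit])
  }
  tbest
}

# Resample a ring to m points evenly spaced by arc length.
#' @noRd
resample_ring <- function(ring, m) {
  p <- .ring_close(ring)
  seg <- sqrt(rowSums(diff(p)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  target <- seq(0, total, length.out = m + 1L)[-(m + 1L)]
  idx <- findInterval(target, s, rightmost.closed = TRUE)
  idx[idx >= length(s)] <- length(s) - 1L
  frac <- (target - s[idx]) / pmax(seg[idx], 1e-24)
  cbind(p[idx, 1L] + frac * (p[idx + 1L, 1L] - p[idx, 1L]),
        p[idx, 2L] + frac * (p[idx + 1L, 2L] - p[idx, 2L]))
}

# Smallest signed angular difference a - b in (-180, 180].
#' @noRd
angle_diff <- function(a, b) {
  d <- (a - b) %% 360
  d[d > 180] <- d[d > 180] - 360
  d
}

# Round half away from zero (printed-value convention).
#' @noRd
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}
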