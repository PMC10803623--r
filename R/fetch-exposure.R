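# Five-ray effective fetch and the wind-exposure index E.

#' Cast the five fetch rays of a transect
#'
#' From the transect anchor, rays are cast at bearings offset by -45, -22.5,
#' 0, +22.5 and +45 degrees from the inward normal (the extreme lines
#' subtend 90 degrees). Each ray length is the distance to the first
#' transversal intersection with the shoreline or an island boundary,
#' excluding the origin. A ray that leaves the lake immediately (concave
#' anchor) gets length 0 with a warning.
#'
#' @param transect a [transect()].
#' @param geometry a [lake_geometry()].
#' @return numeric length-5 vector of ray lengths in km, ordered from
#'   -45 to +45 degrees.
#' @export
cast_fetch_rays <- function(transect, geometry) {
  stopifnot(inherits(transect, "transect"),
            inherits(geometry, "lake_geometry"))
  offsets <- c(-45, -22.5, 0, 22.5, 45)
  rings <- c(list(geometry$shoreline), geometry$islands)
  a <- transect$anchor
  out <- vapply(offsets, function(off) {
    v <- bearing_to_vec(transect$onshore_normal_deg + off)[1L, ]
    probe <- a + 1e-6 * v
    if (!point_in_lake(probe[1L], probe[2L], geometry)) {
      warning(sprintf("transect %s: ray at %+.1f deg leaves the lake immediately",
                      transect$transect_id, off))
      return(0)
    }
    t <- ray_first_hit(a[1L], a[2L], v[1L], v[2L], rings, tol = 1e-9)
    if (!is.finite(t)) {
      # ray passing exactly through a vertex can slip between segments;
      # a sub-arcsecond jitter resolves the degeneracy
      for (jit in c(1e-6, -1e-6, 1e-5, -1e-5)) {
        vj <- bearing_to_vec(transect$onshore_normal_deg + off + jit)[1L, ]
        t <- ray_first_hit(a[1L], a[2L], vj[1L], vj[2L], rings, tol = 1e-9)
        if (is.finite(t)) break
      }
    }
    if (!is.finite(t)) {
      warning(sprintf("transect %s: ray at %+.1f deg found no shoreline hit",
                      transect$transect_id, off))
      return(0)
    }
    t / 1000
  }, numeric(1))
  names(out) <- c("-45", "-22.5", "0", "+22.5", "+45")
  out
}

#' Cosine-weighted effective fetch
#'
#' Weighted mean of the five ray lengths with the cosine of the angle to
#' the middle line as weight: 1 for the middle line, cos(22.5 deg) =
#' 0.92388 for the 22.5-degree lines and cos(45 deg) = 0.70711 for the
#' 45-degree lines (weight sum 4.26198).
#'
#' @param ray_lengths numeric length-5, km, ordered -45 ... +45 deg.
#' @return effective fetch f in km.
#' @export
effective_fetch <- function(ray_lengths) {
  if (length(ray_lengths) != 5L || any(ray_lengths < 0) ||
      anyNA(ray_lengths))
    stop("effective fetch needs five non-negative ray lengths")
  w <- fetch_weights()
  sum(w * ray_lengths) / sum(w)
}

#' The five cosine fetch weights
#'
#' @return numeric length-5: cos(45), cos(22.5), 1, cos(22.5), cos(45).
#' @export
fetch_weights <- function() {
  cos(.deg2rad(c(45, 22.5, 0, 22.5, 45)))
}

#' Linear Directional Mean of a set of directions
#'
#' Circular mean via \eqn{LDM = \arctan(\sum \sin\theta_i / \sum
#' \cos\theta_i)} with the four-branch quadrant correction: for sin-sum
#' \eqn{\ge 0} the result is |LDM| (cos-sum > 0) or 180 - |LDM| (cos-sum
#' < 0); for sin-sum < 0 it is 360 - |LDM| (cos-sum > 0) or 180 + |LDM|
#' (cos-sum < 0).
#'
#' @param directions_deg directions in degrees.
#' @return mean direction in \eqn{[0, 360)} degrees. Errors when the
#'   resultant vector has (near-)zero length, i.e. the mean is undefined.
#' @export
linear_directional_mean <- function(directions_deg) {
  if (!length(directions_deg) || anyNA(directions_deg))
    stop("need at least one non-missing direction")
  th <- .deg2rad(directions_deg)
  S <- sum(sin(th)); C <- sum(cos(th))
  if (sqrt(S^2 + C^2) / length(th) < 1e-12)
    stop("mean direction undefined: resultant vector has length ~0")
  .ldm_from_sums(S, C)
}

#' Daily wind summaries from an hourly series
#'
#' Hourly records are collapsed to one record per calendar day: direction
#' via the Linear Directional Mean, speed via the arithmetic mean. Days
#' whose resultant direction is undefined are dropped with a message.
#'
#' @param series a [make_wind()] `wind_series`, or a data frame with
#'   `timestamp`, `dir_deg`, `speed_ms`.
#' @return data frame: `date`, `dir_deg`, `speed_ms`, `n_obs`.
#' @export
daily_wind_summary <- function(series) {
  rec <- if (inherits(series, "wind_series")) series$records else series
  if (!nrow(rec)) stop("empty wind series")
  day <- format(rec$timestamp, "%Y-%m-%d", tz = "UTC")
  th <- .deg2rad(rec$dir_deg)
  S <- rowsum(sin(th), day)
  C <- rowsum(cos(th), day)
  n <- as.vector(rowsum(rep(1, nrow(rec)), day))
  sp <- as.vector(rowsum(rec$speed_ms, day)) / n
  ok <- sqrt(S^2 + C^2) / n >= 1e-12
  if (any(!ok))
    message(sprintf("dropped %d day(s) with undefined mean direction",
                    sum(!ok)))
  dir <- mapply(.ldm_from_sums, S[ok], C[ok])
  data.frame(date = as.Date(rownames(S)[ok]), dir_deg = dir,
             speed_ms = sp[ok], n_obs = n[ok])
}

#' @noRd
.ldm_from_sums <- function(S, C) {
  if (C == 0) return(if (S >= 0) 90 else 270)
  raw <- abs(.rad2deg(atan(S / C)))
  out <- if (S >= 0 && C > 0) raw
    else if (S >= 0 && C < 0) 180 - raw
    else if (S < 0 && C > 0) 360 - raw
    else 180 + raw
  out %% 360
}

#' Share of days with wind blowing towards a transect
#'
#' A day counts as blowing towards the site when its daily mean wind
#' direction falls within `half_angle` degrees of the transect's inward
#' (open-water) normal - the same 90-degree sector spanned by the fetch
#' rays. With the meteorological convention (`"from"`, the default) wind
#' travelling from open water onto the shore comes *from* the open-water
#' side, so the daily FROM-direction is compared to the inward normal
#' directly; with `convention = "to"` daily directions are travel
#' directions and are flipped by 180 degrees first.
#'
#' @param daily data frame from [daily_wind_summary()].
#' @param transect a [transect()], or a bearing in degrees.
#' @param half_angle sector half-width, degrees (default 45).
#' @param convention `"from"` (meteorological) or `"to"` (vector travel).
#' @return w, the fraction of days in \eqn{[0, 1]}.
#' @export
toward_share <- function(daily, transect, half_angle = 45,
                         convention = c("from", "to")) {
  convention <- match.arg(convention)
  if (!nrow(daily)) stop("no valid daily wind summaries")
  bearing <- if (inherits(transect, "transect"))
    transect$onshore_normal_deg else as.numeric(transect)
  dir <- daily$dir_deg
  if (convention == "to") dir <- (dir + 180) %% 360
  mean(abs(angle_diff(dir, bearing)) <= half_angle)
}

#' Wind-exposure index E
#'
#' \eqn{E = \log(1 + f w h / d^2)} with f the effective fetch (km), w the
#' share of days with wind towards the site, h the mean wind speed (m/s)
#' and d the site depth (m): 1 m for helophyte analyses, the maximum
#' colonisation depth for hydrophytes. The logarithm base is natural by
#' default and exposed because the index is used on a relative scale.
#'
#' @param f effective fetch, km.
#' @param w share of toward-days in \eqn{[0, 1]}.
#' @param h mean wind speed, m/s.
#' @param d site depth, m (> 0).
#' @param log_base logarithm base, default `exp(1)`.
#' @return exposure E (unitless, >= 0; 0 iff `f * w * h == 0`).
#' @examples
#' exposure(1, 0.5, 4, 1)  # log(3)
#' @export
exposure <- function(f, w, h, d, log_base = exp(1)) {
  if (any(d <= 0)) stop("site depth d must be positive")
  if (any(f < 0) || any(w < 0) || any(w > 1) || any(h < 0))
    stop("need f >= 0, 0 <= w <= 1, h >= 0")
  log1p(f * w * h / d^2) / log(log_base)
}

#' Per-transect exposure for both depth conventions
#'
#' Runs rays, effective fetch, daily summaries, toward-share and the
#' exposure formula for each transect, with d = 1 m (`exp_1m`) and
#' d = C_max of the transect (`exp_cmax`).
#'
#' @param transects list of [transect()] with `c_max_tr` set.
#' @param geometry a [lake_geometry()].
#' @param wind a `wind_series` or precomputed daily summary data frame.
#' @param half_angle,convention,log_base see [toward_share()] and
#'   [exposure()].
#' @return data frame: `transect_id`, `fetch_km`, `w`, `h_ms`, `exp_1m`,
#'   `exp_cmax`.
#' @export
transect_exposure <- function(transects, geometry, wind, half_angle = 45,
                              convention = "from", log_base = exp(1)) {
  daily <- if (is.data.frame(wind)) wind else daily_wind_summary(wind)
  h <- mean(daily$speed_ms)
  rows <- lapply(transects, function(tr) {
    f <- effective_fetch(cast_fetch_rays(tr, geometry))
    w <- toward_share(daily, tr, half_angle = half_angle,
                      convention = convention)
    d_cmax <- if (is.na(tr$c_max_tr)) NA_real_ else tr$c_max_tr
    data.frame(transect_id = tr$transect_id, lake_id = tr$lake_id,
               fetch_km = f, w = w, h_ms = h,
               exp_1m = exposure(f, w, h, 1, log_base = log_base),
               exp_cmax = if (is.na(d_cmax)) NA_real_ else
                 exposure(f, w, h, d_cmax, log_base = log_base))
  })
  do.call(rbind, rows)
}
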