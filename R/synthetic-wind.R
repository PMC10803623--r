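# Synthetic hourly wind records with a known circular direction law.

#' Specification of a synthetic wind climate
#'
#' Directions are drawn from a von Mises distribution (any unimodal circular
#' family would do; the concentration parameter is exposed). `concentration
#' = 0` gives uniform directions, `Inf` a point mass at the mean direction.
#' Speeds are Weibull with shape 2 scaled to the requested mean.
#'
#' @param mean_direction_deg mean direction the wind blows from, degrees
#'   \eqn{[0, 360)} (meteorological convention).
#' @param concentration von Mises concentration (kappa), non-negative.
#' @param mean_speed_ms mean wind speed, m/s.
#' @param years length of the record; surveys use the 6-year window
#'   preceding sampling.
#' @param start first timestamp (UTC), default `"2010-01-01"`.
#' @param seed integer seed.
#' @return object of class `wind_spec`.
#' @export
wind_spec <- function(mean_direction_deg = 270, concentration = 1.5,
                      mean_speed_ms = 4, years = 6L,
                      start = "2010-01-01", seed = 1L) {
  stopifnot(mean_direction_deg >= 0, mean_direction_deg < 360,
            concentration >= 0, mean_speed_ms > 0, years >= 1)
  structure(list(mean_direction_deg = mean_direction_deg,
                 concentration = concentration,
                 mean_speed_ms = mean_speed_ms, years = as.integer(years),
                 start = start, seed = as.integer(seed)),
            class = "wind_spec")
}

# von Mises sampler (Best & Fisher rejection scheme), degrees out.
#' @noRd
rvonmises_deg <- function(n, mu_deg, kappa) {
  if (n == 0L) return(numeric(0))
  if (!is.finite(kappa)) return(rep(mu_deg %% 360, n))
  if (kappa < 1e-10) return(runif(n, 0, 360))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(n - length(out), 64L)
    u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    keep <- (c_ * (2 - c_) - u2 > 0) | (log(c_ / u2) + 1 - c_ >= 0)
    th <- sign(u3[keep] - 0.5) * acos(f[keep])
    out <- c(out, th)
  }
  (mu_deg + .rad2deg(out[seq_len(n)])) %% 360
}

#' Generate an hourly wind series
#'
#' @param spec a [wind_spec()].
#' @param station_id identifier, default `"SYN"`.
#' @return object of class `wind_series`: `records` (data frame with
#'   `timestamp` POSIXct UTC, `dir_deg`, `speed_ms`), `station_id`,
#'   `window` (first/last timestamp).
#' @export
make_wind <- function(spec, station_id = "SYN") {
  stopifnot(inherits(spec, "wind_spec"))
  n <- spec$years * 365L * 24L
  t0 <- as.POSIXct(spec$start, tz = "UTC")
  ts <- t0 + 3600 * (seq_len(n) - 1L)
  rec <- .with_seed(spec$seed, {
    dir <- rvonmises_deg(n, spec$mean_direction_deg, spec$concentration)
    scale <- spec$mean_speed_ms / gamma(1.5)
    speed <- stats::rweibull(n, shape = 2, scale = scale)
    data.frame(timestamp = ts, dir_deg = dir, speed_ms = speed)
  })
  structure(list(records = rec, station_id = station_id,
                 window = range(ts)),
            class = "wind_series")
}

#' @export
print.wind_series <- function(x, ...) {
  cat(sprintf("<wind_series> %s: %d hourly records, %s to %s\n",
              x$station_id, nrow(x$records),
              format(x$window[1L], "%Y-%m-%d"),
              format(x$window[2L], "%Y-%m-%d")))
  invisible(x)
}
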