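# Effective fetch, Linear Directional Mean, toward-share, exposure index.

test_that("fetch rays on a circular lake follow the chord formula", {
  geom <- lake_geometry(circle_ring(500, n = 1024), z_max = 10)
  tr <- transect("T1", c(500, 0), 270)  # inward normal through the centre
  rays <- cast_fetch_rays(tr, geom)
  chord <- function(a) 2 * 0.5 * cos(a * pi / 180)
  expect_equal(unname(rays),
               c(chord(45), chord(22.5), 1, chord(22.5), chord(45)),
               tolerance = 2e-3)
})

test_that("middle ray across a square lake equals the side length", {
  geom <- lake_geometry(square_ring(1000), z_max = 5)
  tr <- transect("T1", c(-500, 0), 90)
  rays <- cast_fetch_rays(tr, geom)
  expect_equal(unname(rays[3L]), 1, tolerance = 1e-9)
})

test_that("an island truncates the ray at the first hit", {
  geom <- lake_geometry(circle_ring(500, n = 720),
                        islands = list(circle_ring(50, n = 180,
                                                   centre = c(150, 0))),
                        z_max = 10)
  tr <- transect("T1", c(500, 0), 270)
  rays <- cast_fetch_rays(tr, geom)
  expect_equal(unname(rays[3L]), 0.3, tolerance = 2e-3)
})

test_that("effective fetch is the published cosine-weighted mean", {
  expect_equal(effective_fetch(rep(1, 5)), 1, tolerance = 1e-12)
  expect_lt(abs(effective_fetch(c(0, 0, 1, 0, 0)) - 0.23463), 1e-5)
  r <- c(0.70711, 0.92388, 1, 0.92388, 0.70711)
  expect_lt(abs(effective_fetch(r) - 0.86981), 1e-5)
  expect_error(effective_fetch(c(1, 2, 3)), "five")
  # symmetric under left/right ray exchange; bounded by the extremes
  set.seed(1)
  for (k in 1:50) {
    r <- runif(5, 0, 3)
    expect_equal(effective_fetch(r), effective_fetch(rev(r)))
    expect_gte(effective_fetch(r), min(r))
    expect_lte(effective_fetch(r), max(r))
  }
})

test_that("LDM reproduces the quadrant-branch hand traces", {
  expect_equal(linear_directional_mean(c(10, 350)), 0)
  expect_equal(linear_directional_mean(c(90, 180)), 135)
  expect_equal(linear_directional_mean(c(200, 340)), 270)
  expect_equal(linear_directional_mean(c(45)), 45)
  expect_error(linear_directional_mean(c(0, 180)), "undefined")
})

test_that("LDM agrees with the resultant-vector arctangent oracle", {
  set.seed(7)
  for (k in 1:500) {
    d <- runif(sample(1:48, 1), 0, 360)
    got <- tryCatch(linear_directional_mean(d), error = function(e) NA)
    if (is.na(got)) next
    delta <- abs(got - ldm_oracle(d)) %% 360
    expect_lt(min(delta, 360 - delta), 1e-9)
  }
})

test_that("daily summaries average speeds arithmetically and directions circularly", {
  ts <- as.POSIXct("2015-06-01 00:00:00", tz = "UTC") + 3600 * 0:23
  rec <- data.frame(timestamp = ts, dir_deg = rep(90, 24),
                    speed_ms = rep(5, 24))
  d <- daily_wind_summary(rec)
  expect_equal(nrow(d), 1L)
  expect_equal(d$dir_deg, 90)
  expect_equal(d$speed_ms, 5)
  rec2 <- data.frame(timestamp = ts[1:2], dir_deg = c(10, 350),
                     speed_ms = c(2, 4))
  d2 <- daily_wind_summary(rec2)
  expect_equal(d2$dir_deg, 0)
  expect_equal(d2$speed_ms, 3)
})

test_that("toward-share counts the onshore sector under both conventions", {
  daily <- data.frame(date = as.Date("2015-01-01") + 0:3,
                      dir_deg = c(90, 90, 270, 270),
                      speed_ms = 4)
  # FROM-convention: days blowing from the open-water side count
  expect_equal(toward_share(daily, 90), 0.5)
  expect_equal(toward_share(daily, transect("T", c(0, 0), 90)), 0.5)
  # all days exactly onshore / offshore
  on <- data.frame(date = 1:5, dir_deg = rep(45, 5), speed_ms = 1)
  expect_equal(toward_share(on, 45), 1)
  expect_equal(toward_share(on, 225), 0)
  # travel-direction convention flips by 180
  expect_equal(toward_share(on, 225, convention = "to"), 1)
})

test_that("exposure follows E = ln(1 + f w h / d^2) with its monotonicities", {
  expect_equal(exposure(1, 0.5, 4, 1), log(3), tolerance = 1e-12)
  expect_equal(exposure(1, 0.5, 4, 2), log(1.5), tolerance = 1e-12)
  expect_equal(exposure(2, 0, 5, 1), 0)
  expect_error(exposure(1, 0.5, 4, 0), "positive")
  expect_equal(exposure(1, 0.5, 4, 1, log_base = 10), log10(3))
  set.seed(3)
  for (k in 1:40) {
    f <- runif(1, 0.05, 3); w <- runif(1, 0.05, 1)
    h <- runif(1, 0.5, 12); d <- runif(1, 0.5, 8); eps <- 0.1
    E <- exposure(f, w, h, d)
    expect_gt(exposure(f + eps, w, h, d), E)
    expect_gt(exposure(f, min(w + 0.01, 1), h, d), E)
    expect_gt(exposure(f, w, h + eps, d), E)
    expect_lt(exposure(f, w, h, d + eps), E)
  }
})

test_that("fetch is rotation-symmetric on a circular lake", {
  lk <- make_lake(lake_spec("circle", radius_m = 400, max_depth_m = 8,
                            n_transects = 8, seed = 2), cell_size = 10)
  f <- vapply(lk$transects, function(tr)
    effective_fetch(cast_fetch_rays(tr, lk$geometry)), numeric(1))
  expect_lt(diff(range(f)), 1e-9)
})
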