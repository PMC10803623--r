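# Generators: lakes, wind, survey tables.

test_that("conic circle lake has the analytic cone gradient everywhere off-centre", {
  lk <- make_lake(lake_spec("circle", radius_m = 500, max_depth_m = 10,
                            n_transects = 8, seed = 1), cell_size = 5)
  sl <- slope_raster(lk$grid)
  ax <- grid_axes(lk$grid)
  r <- sqrt(outer(ax$y^2, ax$x^2, `+`))
  # Horn on a cone is exact up to curvature error ~ (cell/r)^2
  v <- sl$values[!is.na(sl$values) & r > 100 & r < 450]
  expect_equal(unname(range(v)), rep(atan(10 / 500) * 180 / pi, 2),
               tolerance = 0.01)
})

test_that("planar-shelf profile gives depth = grade * shore distance", {
  lk <- make_lake(lake_spec("circle", radius_m = 300, max_depth_m = 50,
                            profile = "planar-shelf", shelf_slope = 0.1,
                            n_transects = 8, seed = 1), cell_size = 4)
  expect_equal(depth_at(lk$grid, 250, 0), 5, tolerance = 1e-6)
  sl <- slope_raster(lk$grid)
  mid <- sl$values[nrow(sl$values) %/% 2, ncol(sl$values) %/% 4]
  expect_equal(mid, atan(0.1) * 180 / pi, tolerance = 0.01)
})

test_that("transect anchors are evenly spaced on a circle with inward normals", {
  lk <- make_lake(lake_spec("circle", radius_m = 500, max_depth_m = 10,
                            n_transects = 8, seed = 1), cell_size = 10)
  anchors <- t(vapply(lk$transects, function(t) t$anchor, numeric(2)))
  ang <- sort(atan2(anchors[, 2L], anchors[, 1L]))
  expect_equal(diff(ang) * 500, rep(2 * pi * 500 / 8, 7), tolerance = 1e-6)
  # inward normal of an anchor on a circle points at the centre
  for (tr in lk$transects) {
    expected <- (atan2(-tr$anchor[1L], -tr$anchor[2L]) * 180 / pi) %% 360
    expect_equal(tr$onshore_normal_deg, expected, tolerance = 0.5)
  }
})

test_that("identical seeds give bit-identical lakes, wind and surveys", {
  a <- make_lake(lake_spec("irregular", radius_m = 300, n_transects = 8,
                           seed = 9), cell_size = 10)
  b <- make_lake(lake_spec("irregular", radius_m = 300, n_transects = 8,
                           seed = 9), cell_size = 10)
  expect_identical(a$geometry$shoreline, b$geometry$shoreline)
  expect_identical(a$grid$values, b$grid$values)
  w1 <- make_wind(wind_spec(years = 1, seed = 4))
  w2 <- make_wind(wind_spec(years = 1, seed = 4))
  expect_identical(w1$records, w2$records)
  tr <- lapply(1:8, function(i) transect(paste0("T", i), c(0, 0), 0))
  s1 <- make_survey(spec = community_spec(seed = 3), transects = tr)
  s2 <- make_survey(spec = community_spec(seed = 3), transects = tr)
  expect_identical(s1$data, s2$data)
})

test_that("degenerate self-intersecting shorelines are rejected", {
  bow <- rbind(c(0, 0), c(10, 10), c(10, 0), c(0, 10))
  expect_error(lake_geometry(bow), "self-intersect")
})

test_that("wind directions follow the requested circular law", {
  # point mass: LDM is the planted direction exactly
  wp <- make_wind(wind_spec(mean_direction_deg = 90, concentration = Inf,
                            years = 1, seed = 2))
  expect_equal(linear_directional_mean(wp$records$dir_deg), 90)
  # two equal opposite-of-north masses average to north
  expect_equal(linear_directional_mean(c(10, 350)), 0)
  # uniform directions put ~25% of days in any fixed 90-degree sector
  wu <- make_wind(wind_spec(concentration = 0, years = 6, seed = 5))
  daily <- daily_wind_summary(wu)
  expect_equal(nrow(daily), 6 * 365)
  for (bearing in c(0, 90, 217)) {
    expect_lt(abs(toward_share(daily, bearing) - 0.25), 0.035)
  }
  expect_true(all(wu$records$speed_ms > 0))
})

test_that("hourly records cover the requested multi-year window", {
  w <- make_wind(wind_spec(years = 2, seed = 1))
  expect_equal(nrow(w$records), 2 * 365 * 24)
  expect_true(!is.unsorted(w$records$timestamp, strictly = TRUE))
})

test_that("relative covers are normalised and C_max stays in range", {
  tr <- lapply(1:40, function(i) transect(sprintf("T%02d", i), c(0, 0), 0))
  sv <- make_survey(spec = community_spec(seed = 6), transects = tr)
  sums <- tapply(sv$data$rel_cover_pct, sv$data$transect_id, sum)
  expect_equal(as.numeric(sums), rep(100, 40), tolerance = 1e-9)
  expect_true(all(sv$transect_info$c_max_tr >= 2 &
                  sv$transect_info$c_max_tr <= 8.5))
})

test_that("trophic effect on charophyte cover is recovered from 260 transects", {
  tr <- lapply(1:260, function(i) transect(sprintf("T%03d", i), c(0, 0), 0))
  pn_ch_of <- function(sv) {
    vapply(sv$transect_info$transect_id, function(t) {
      d <- sv$data[sv$data$transect_id == t, ]
      sum(d$rel_cover_pct[d$group == "charophyte"])
    }, numeric(1))
  }
  # strong negative effect: significant negative Spearman rho
  sv <- make_survey(spec = community_spec(trophic_effect = -3, seed = 7),
                    transects = tr)
  ct <- suppressWarnings(cor.test(sv$transect_info$tp_mgL, pn_ch_of(sv),
                                  method = "spearman", exact = FALSE))
  expect_lt(unname(ct$estimate), 0)
  expect_lt(ct$p.value, 0.001)
  # null effect: no signal
  sv0 <- make_survey(spec = community_spec(trophic_effect = 0, seed = 7),
                     transects = tr)
  ct0 <- suppressWarnings(cor.test(sv0$transect_info$tp_mgL, pn_ch_of(sv0),
                                   method = "spearman", exact = FALSE))
  expect_gt(ct0$p.value, 0.05)
})
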