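# Depth interpolation, Horn slope, zonal statistics, unit conversion.

test_that("depth interpolates linearly between shoreline and a single isobath", {
  g <- lake_geometry(circle_ring(500),
                     isobaths = list(list(depth = 5,
                                          coords = circle_ring(250),
                                          closed = TRUE)),
                     z_max = 10)
  grid <- interpolate_depth(g, cell_size = 5)
  expect_equal(depth_at(grid, 375, 0), 2.5, tolerance = 0.1)
  # shoreline cells sit at depth ~0
  expect_lt(abs(depth_at(grid, 497.4, 0)), 0.1)
  # the isobath itself is honoured
  expect_equal(depth_at(grid, 0, 250), 5, tolerance = 0.1)
})

test_that("flat lake with a depth tag fills all wet cells with the constant", {
  g <- lake_geometry(square_ring(200), flat_depth = 2)
  grid <- interpolate_depth(g, cell_size = 10)
  wet <- grid$values[!is.na(grid$values)]
  expect_true(all(wet == 2))
})

test_that("crossing or out-of-range isobaths are rejected with the depth named", {
  off <- list(list(depth = 5, coords = circle_ring(400, centre = c(350, 0)),
                   closed = TRUE))
  g <- expect_error(
    interpolate_depth(lake_geometry(circle_ring(500), isobaths = off,
                                    z_max = 10), cell_size = 10),
    "5.00 m")
  expect_error(lake_geometry(circle_ring(500),
                             isobaths = list(list(depth = 12,
                                                  coords = circle_ring(100),
                                                  closed = TRUE)),
                             z_max = 10),
               "deeper than z_max")
})

test_that("Horn slope of affine depth planes is exact away from edges", {
  s1 <- slope_raster(plane_grid(0.1, 0))
  inner <- s1$values[2:20, 2:20]
  expect_equal(unname(inner), matrix(atan(0.1) * 180 / pi, 19, 19),
               tolerance = 1e-10)
  s2 <- slope_raster(plane_grid(1, 1))
  expect_equal(s2$values[10, 10], atan(sqrt(2)) * 180 / pi,
               tolerance = 1e-10)
  s0 <- slope_raster(plane_grid(0, 0, c = 3))
  expect_true(all(s0$values == 0))
})

test_that("slope raster rejects degenerate grids", {
  expect_error(slope_raster(depth_grid(c(0, 0), 1,
                                       matrix(NA_real_, 5, 5))),
               "3 x 3")
})

test_that("zonal mean is the arithmetic mean, invariant to cell order", {
  sl <- structure(list(origin = c(0, 0), cell_size = 1,
                       values = rbind(c(2, 4), c(4, 2))),
                  class = c("slope_raster", "depth_grid"))
  cells <- data.frame(row = c(1, 1, 2), col = c(1, 2, 1))
  expect_equal(zonal_slope(cells, sl), mean(c(2, 4, 4)))
  expect_equal(zonal_slope(cells[3:1, ], sl), zonal_slope(cells, sl))
  expect_error(zonal_slope(cells[0, ], sl), "empty")
})

test_that("transect zone truncates at the target depth on a conic lake", {
  lk <- make_lake(lake_spec("circle", radius_m = 500, max_depth_m = 10,
                            n_transects = 8, seed = 1), cell_size = 2)
  z <- transect_zone(lk$transects[[1]], lk$geometry, lk$grid,
                     max_depth = 1)
  # cone: depth 1 m is reached 500 * 1/10 = 50 m from shore
  expect_equal(z$length_m, 50, tolerance = 2)
  expect_true(z$truncated)
  # rectangle: area = length x 30 m, within a couple of cell rows
  area <- nrow(z$cells) * lk$grid$cell_size^2
  expect_lt(abs(area - z$length_m * 30), 2 * 30 * lk$grid$cell_size)
})

test_that("zone warns and runs on when the target depth is never reached", {
  lk <- make_lake(lake_spec("circle", radius_m = 200, max_depth_m = 3,
                            n_transects = 8, seed = 1), cell_size = 4)
  expect_warning(z <- transect_zone(lk$transects[[1]], lk$geometry,
                                    lk$grid, max_depth = 5),
                 "never reached")
  expect_false(z$truncated)
})

test_that("anchors off the shoreline are a precondition error", {
  lk <- make_lake(lake_spec("circle", radius_m = 200, max_depth_m = 5,
                            n_transects = 8, seed = 1), cell_size = 4)
  bad <- transect("bad", c(0, 0), 0)
  expect_error(transect_zone(bad, lk$geometry, lk$grid, 1), "shoreline")
})

test_that("degree to percent conversion reproduces the printed dual units", {
  expect_equal(deg_to_pct(15.93, report = TRUE), 28.5)
  expect_equal(deg_to_pct(14.23, report = TRUE), 25.4)
  expect_equal(deg_to_pct(0), 0)
  expect_error(deg_to_pct(90), "\\[0, 90\\)")
  # strict monotonicity
  a <- seq(0, 89, by = 0.5)
  expect_true(all(diff(deg_to_pct(a)) > 0))
})

test_that("slope classes use strict thresholds with dual-unit consistency", {
  expect_equal(as.character(classify_slope(c(1.0, 5.0, 10))),
               c("gentle", "moderate", "steep"))
  # the printed boundaries themselves are moderate (strict inequalities)
  expect_equal(as.character(classify_slope(c(1.32, 8.42))),
               c("moderate", "moderate"))
  # both threshold angles match their printed percent twins
  expect_equal(deg_to_pct(1.32, report = TRUE), 2.3)
  expect_equal(deg_to_pct(8.42, report = TRUE), 14.8)
})

test_that("the full interpolate-Horn-zonal pipeline recovers a known slope", {
  true_deg <- 5.711  # arctan(0.1)
  sp <- lake_spec("circle", radius_m = 250, max_depth_m = 40,
                  profile = "planar-shelf", shelf_slope = 0.1,
                  n_transects = 8, n_vertices = 720, seed = 3)
  lk <- make_lake(sp, cell_size = 2.5,
                  isobath_depths = seq(0.5, 22, by = 2.5))
  gi <- interpolate_depth(lk$geometry, cell_size = 2.5)
  sl <- slope_raster(gi)
  z <- transect_zone(lk$transects[[2]], lk$geometry, gi, max_depth = 2)
  expect_lt(abs(zonal_slope(z, sl) - true_deg), 0.1)
})
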