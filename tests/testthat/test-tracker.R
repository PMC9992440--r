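# particle advection, turbulence, backtracking, forward dispersal

test_that("velocity perturbation follows its closed form", {
  # zero speed kills the perturbation entirely
  expect_equal(perturb_velocity(0, 0, 0.5), list(u = 0, v = 0))
  # zero coefficient is the identity
  expect_equal(perturb_velocity(1.3, -0.4, 0), list(u = 1.3, v = -0.4))
})

test_that("a backward Euler step in uniform flow matches the closed form", {
  g <- uniform_velocity_grid(-0.5145, 0)
  cfg <- track_config(n_particles = 1, turbulence = 0, windage = 0)
  p <- advect_step(c(0, 0), g, NULL, 100, cfg)
  dlon_expected <- 0.5145 * 21600 / (6371000 * pi / 180)
  expect_equal(unname(p[1, 1]), dlon_expected, tolerance = 1e-12)
  expect_equal(unname(p[1, 2]), 0)
})

test_that("windage of 0.5% acts like a current of 0.5% of the wind", {
  ocean <- uniform_velocity_grid(0, 0)
  wind <- uniform_velocity_grid(10, 0)
  equiv <- uniform_velocity_grid(0.05, 0)
  cfg <- track_config(n_particles = 1, turbulence = 0, windage = 0.005,
                      direction = "forward")
  p_wind <- advect_step(c(0, 0), ocean, wind, 0, cfg)
  cfg0 <- track_config(n_particles = 1, turbulence = 0, windage = 0,
                       direction = "forward")
  p_curr <- advect_step(c(0, 0), equiv, NULL, 0, cfg0)
  expect_equal(p_wind[1, ], p_curr[1, ], tolerance = 1e-12)
})

test_that("a particle stepping onto land stalls in place and is flagged", {
  lon <- seq(-5, 0, by = 1); lat <- seq(0, 5, by = 1)
  land <- matrix(FALSE, 6, 6); land[1:2, ] <- TRUE    # western strip
  g <- velocity_grid(lon, lat, array(0.5, c(6, 6, 1)),
                     array(0, c(6, 6, 1)), land = land)
  cfg <- track_config(n_particles = 1, turbulence = 0, windage = 0)
  # backward advection of +u moves west, into the land strip
  p <- advect_step(c(-3.6, 2), g, NULL, 0, cfg)
  expect_equal(unname(p[1, ]), c(-3.6, 2))
  expect_true(attr(p, "grounded"))
})

test_that("zero turbulence collapses the ensemble onto the analytic track", {
  g <- uniform_velocity_grid(-0.3, 0.1)
  cfg <- track_config(n_particles = 20, horizon_days = 30, turbulence = 0,
                      windage = 0, seed = 5)
  r <- backtrack_sample(-100, 0, 50, g, NULL, cfg)
  expect_equal(max(dist(r$endpoints)), 0)
  expect_equal(unname(r$center_of_mass), unname(r$endpoints[1, ]))
  # distance accumulates monotonically and bounds the net displacement
  expect_true(all(r$cum_dist_km >=
                    haversine_km(r$launch[1], r$launch[2],
                                 r$endpoints[, 1], r$endpoints[, 2]) - 1e-9))
})

test_that("a 365-day backtrack in steady uniform flow matches the closed form", {
  g <- uniform_velocity_grid(-0.5145, 0)
  cfg <- track_config(n_particles = 2, turbulence = 0, windage = 0)
  r <- backtrack_sample(-150, 0, 0, g, NULL, cfg)
  dlon <- 1460 * 0.5145 * 21600 / (6371000 * pi / 180)
  expect_equal(unname(r$endpoints[1, 1]), -150 + dlon, tolerance = 1e-6)
  expect_equal(unname(r$cum_dist_km[1]),
               1460 * 0.5145 * 21.6, tolerance = 1e-6)
})

test_that("backtracking is deterministic for a fixed seed", {
  g <- steady_regime_grid(300)
  cfg <- track_config(n_particles = 10, horizon_days = 20, seed = 11)
  r1 <- backtrack_sample(-59.56, 13.27, 300, g, NULL, cfg)
  r2 <- backtrack_sample(-59.56, 13.27, 300, g, NULL, cfg)
  expect_identical(r1$endpoints, r2$endpoints)
  expect_identical(r1$cum_dist_km, r2$cum_dist_km)
})

test_that("ensemble centre of mass converges on the deterministic endpoint", {
  g <- uniform_velocity_grid(-0.4, 0.2)
  cfg0 <- track_config(n_particles = 1, horizon_days = 60, turbulence = 0,
                       windage = 0)
  det <- backtrack_sample(-100, 0, 0, g, NULL, cfg0)$endpoints[1, ]
  cfg <- track_config(n_particles = 100, horizon_days = 60, turbulence = 0.1,
                      windage = 0, seed = 2)
  com <- backtrack_sample(-100, 0, 0, g, NULL, cfg)$center_of_mass
  # random-walk scale of the ensemble mean: coeff * s * sqrt(T dt) / sqrt(n)
  s <- sqrt(0.4^2 + 0.2^2)
  tol_m <- 3 * 0.1 * s * sqrt(60 * 86400 * 21600) / sqrt(100)
  expect_lt(haversine_km(com[1], com[2], det[1], det[2]), tol_m / 1000)
})

test_that("launch points snap to the nearest ocean cell within two cells", {
  cfg <- small_field_config()
  f <- generate_current_field(cfg)
  g <- f$currents
  # a point just inside the synthetic coastline
  land_j <- which(g$land[20, ])
  lat_land <- g$lat[max(land_j)]
  tc <- track_config(n_particles = 2, horizon_days = 1, turbulence = 0)
  r <- backtrack_sample(g$lon[20], lat_land, 100, g, NULL, tc)
  expect_false(is_land(g, r$launch[1], r$launch[2]))
  # far inside land: beyond the snap radius
  expect_error(backtrack_sample(g$lon[20], g$lat[1], 100, g, NULL, tc),
               "ocean")
})

test_that("retention is total when the box is the whole (closed) domain", {
  g <- uniform_velocity_grid(-0.5, 0, lon_range = c(-10, 0),
                             lat_range = c(0, 10), res = 1)
  cfg <- track_config(seed = 3, turbulence = 0)
  ret <- forward_dispersal(c(-10, 0, 0, 10), 50, 20, g, NULL, cfg)
  expect_true(all(ret$fraction == 1))
})

test_that("a uniform jet empties a box at the analytic transit time", {
  # 0.5 m/s westward across a 4.32-degree-wide box at the equator:
  # crossing time = box width / speed = 11.12 days for the farthest particle
  g <- uniform_velocity_grid(-0.5, 0, lon_range = c(-60, 0),
                             lat_range = c(-5, 5), res = 1)
  width_deg <- 4.32
  cfg <- track_config(seed = 8, turbulence = 0)
  ret <- forward_dispersal(c(-30, -30 + width_deg, -2, 2), 100, 20, g,
                           NULL, cfg)
  expect_true(all(diff(ret$fraction) <= 1e-12))    # non-increasing
  expect_true(all(ret$fraction >= 0 & ret$fraction <= 1))
  transit_days <- width_deg * (6371000 * pi / 180) / 0.5 / 86400
  expect_equal(ret$fraction[ret$day > ceiling(transit_days)][1], 0)
  expect_gt(ret$fraction[floor(transit_days) - 1], 0)
  expect_false(is.na(attr(ret, "day90")))
})

test_that("a box entirely on land is rejected", {
  lon <- seq(-5, 0, by = 1); lat <- seq(0, 5, by = 1)
  land <- matrix(FALSE, 6, 6); land[, 1:2] <- TRUE
  g <- velocity_grid(lon, lat, array(0, c(6, 6, 1)), array(0, c(6, 6, 1)),
                     land = land)
  expect_error(forward_dispersal(c(-5, 0, 0, 1), 10, 5, g), "no ocean")
})
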