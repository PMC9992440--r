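# environmental box averages and the two-factor PERMANOVA

make_env_grid <- function(fill_sst = NULL, fill_chl = 0.2, res = 0.25,
                          lon_range = c(-50, -30), lat_range = c(0, 20)) {
  lon <- seq(lon_range[1], lon_range[2], by = res)
  lat <- seq(lat_range[1], lat_range[2], by = res)
  sst <- array(NA_real_, c(length(lon), length(lat), 46))
  chl <- array(fill_chl, c(length(lon), length(lat), 46))
  for (k in 1:46) {
    sst[, , k] <- if (is.null(fill_sst))
      matrix(30 - 0.5 * lat, length(lon), length(lat), byrow = TRUE)
    else fill_sst
  }
  structure(list(lon = lon, lat = lat,
                 composite_yearday = 8 * (0:45) + 3.5,
                 sst = sst, chl = chl,
                 land = matrix(FALSE, length(lon), length(lat)),
                 dlon = res, dlat = res),
            class = "env_grid")
}

test_that("box averages: constants pass through, linear fields hit the centre", {
  g <- make_env_grid(fill_sst = 27)
  ba <- box_average(g, c(-40, 10), 93500, yearday = 100)
  expect_equal(unname(ba["sst_mean"]), 27)
  expect_equal(unname(ba["chl_mean"]), 0.2)
  # 93,500 km^2 -> side 305.78 km -> 2.747 degrees of latitude
  expect_equal(sqrt(93500) / 111.32, 2.7468, tolerance = 1e-3)
  # meridionally linear field, symmetric box: mean equals the centre value
  g2 <- make_env_grid()
  ba2 <- box_average(g2, c(-40, 10), 93500, yearday = 10)
  expect_equal(unname(ba2["sst_mean"]), 30 - 0.5 * 10, tolerance = 1e-6)
  expect_error(box_average(g2, c(-40, 10), 0), "area")
  expect_error(box_average(g2, c(100, 50)), "outside")
})

test_that("box averaging converges under grid refinement for smooth fields", {
  v_coarse <- box_average(make_env_grid(res = 1), c(-40, 10), 93500, 10)
  v_fine <- box_average(make_env_grid(res = 0.125), c(-40, 10), 93500, 10)
  expect_equal(unname(v_coarse["sst_mean"]), unname(v_fine["sst_mean"]),
               tolerance = 0.02)
})

synthetic_results <- function(dates, lat_a = 3, lat_b = 15) {
  cal <- default_regime_calendar()
  lapply(dates, function(d) {
    yd <- date_to_yearday(d)
    lat <- if (regime_of_yearday(cal, yd) == "A") lat_a else lat_b
    n_steps <- 1460
    structure(list(
      endpoints = cbind(lon = rep(-40, 2), lat = rep(lat, 2)),
      center_of_mass = c(lon = -40, lat = lat),
      cum_dist_km = c(1, 1), yearday = yd, date = d,
      lon_traj = matrix(-45, n_steps + 1, 2),
      lat_traj = matrix(lat + 1, n_steps + 1, 2),
      config = track_config(n_particles = 2)),
      class = "backtrack_result")
  })
}

test_that("24 simulations yield 48 records with correct periods and labels", {
  dates <- default_collection_dates()
  res <- synthetic_results(dates)
  names(res) <- as.character(dates)
  lab <- setNames(regime_of_yearday(default_regime_calendar(),
                                    date_to_yearday(dates)),
                  as.character(dates))
  g <- make_env_grid(lon_range = c(-50, -30), lat_range = c(0, 20))
  rec <- extract_env_records(res, lab, g)
  expect_equal(nrow(rec), 48)
  expect_equal(sum(rec$period == "origin"), 24)
  expect_equal(sum(rec$period == "midpoint"), 24)
  expect_true(all(rec$suborigin %in% c("A", "B")))
  # constant-chl grid: all chlorophyll records identical
  expect_equal(unique(rec$chl_mean), 0.2)
  # planted SST gradient: pathway-A records (low latitude) are warmer
  expect_gt(mean(rec$sst_mean[rec$suborigin == "A"]),
            mean(rec$sst_mean[rec$suborigin == "B"]))
})

simulate_env_records <- function(n_per_cell = 12, sst_shift = 0,
                                 seed = 1) {
  set.seed(seed)
  cells <- expand.grid(period = c("origin", "midpoint"),
                       suborigin = c("A", "B"))
  do.call(rbind, lapply(seq_len(nrow(cells)), function(k) {
    shift <- if (cells$suborigin[k] == "A") sst_shift else 0
    data.frame(period = cells$period[k], suborigin = cells$suborigin[k],
               sst_mean = rnorm(n_per_cell, 27 + shift, 1),
               chl_mean = rlnorm(n_per_cell, log(0.2), 0.3))
  }))
}

test_that("two-factor partition agrees with the reference sequential PERMANOVA", {
  rec <- simulate_env_records(sst_shift = 1.5, seed = 3)
  ours <- env_permanova(rec, n_perm = 499, seed = 5)
  Y <- scale(cbind(rec$sst_mean, sqrt(rec$chl_mean)))
  veg <- vegan::adonis2(dist(Y) ~ period * suborigin, data = rec,
                        permutations = 499, by = "terms")
  expect_equal(ours$aov_tab$F.Model[1:3], veg$F[1:3], tolerance = 1e-8)
  expect_equal(ours$aov_tab$SumOfSqs[1:4], veg$SumOfSqs[1:4], tolerance = 1e-8)
})

test_that("interaction-only structure loads the interaction term", {
  rec <- simulate_env_records(seed = 7)
  # plant a pure interaction: sign flips across the 2x2 cells
  sgn <- ifelse((rec$period == "origin") == (rec$suborigin == "A"), 1, -1)
  rec$sst_mean <- 27 + 2 * sgn + rnorm(nrow(rec), 0, 0.3)
  res <- env_permanova(rec, n_perm = 199, seed = 2)
  ss <- res$aov_tab$SumOfSqs
  expect_gt(ss[3], 5 * (ss[1] + ss[2]))
  expect_lt(res$aov_tab$p[3], 0.05)
})

test_that("a planted sub-origin SST shift is detected with high power", {
  hits <- vapply(1:40, function(r) {
    rec <- simulate_env_records(sst_shift = 3, seed = 100 + r)
    env_permanova(rec, n_perm = 199, seed = r)$aov_tab$p[2] < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("null data keep the type-I error near nominal for every term", {
  ps <- t(vapply(1:500, function(r) {
    rec <- simulate_env_records(n_per_cell = 8, seed = 500 + r)
    env_permanova(rec, n_perm = 199, seed = r)$aov_tab$p[1:3]
  }, numeric(3)))
  rates <- colMeans(ps < 0.05)
  expect_true(all(rates > 0.03 & rates < 0.07))
})

test_that("an empty design cell is a design error", {
  rec <- simulate_env_records()
  rec <- rec[!(rec$period == "origin" & rec$suborigin == "A"), ]
  expect_error(env_permanova(rec, n_perm = 9), "design")
})

test_that("missing records are dropped with a warning, not fatal", {
  rec <- simulate_env_records()
  rec$sst_mean[1] <- NA
  expect_warning(res <- env_permanova(rec, n_perm = 49, seed = 1), "dropped")
  expect_equal(res$aov_tab$Df[4], nrow(rec) - 1 - 3 - 1 + 1 - 1)
})
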