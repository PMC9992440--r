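# shared fixtures, built in code

# coarse field configuration for fast module tests
small_field_config <- function(...) {
  field_config(res = 0.5, ...)
}

# time-constant grid holding one regime's field (steady-flow oracle)
steady_regime_grid <- function(yearday, config = small_field_config()) {
  f <- generate_current_field(config)
  g <- f$currents
  k <- yearday + 1
  velocity_grid(g$lon, g$lat, g$u[, , k, drop = FALSE],
                g$v[, , k, drop = FALSE], land = g$land)
}

# analytic planar velocity field sampled on cell centres as drifter fixes
planar_fixes <- function(a = 0.1, b = 0.02, c = -0.01, res = 0.5,
                         lon_range = c(-10, -5), lat_range = c(0, 5),
                         days = seq(1, 365, by = 5), noise_sd = 0,
                         seed = 1) {
  set.seed(seed)
  lon <- seq(lon_range[1] + res / 2, lon_range[2], by = res)
  lat <- seq(lat_range[1] + res / 2, lat_range[2], by = res)
  g <- expand.grid(lon = lon, lat = lat, day = days)
  u <- a + b * g$lon + c * g$lat
  v <- -a + c * g$lon + b * g$lat
  data.frame(year = 2020L, day = as.integer(g$day), hour = 0L,
             lon = g$lon, lat = g$lat,
             u = u + stats::rnorm(nrow(g), 0, noise_sd),
             v = v + stats::rnorm(nrow(g), 0, noise_sd),
             drogue = TRUE)
}

# independent pseudo-F oracle computed from coordinates (not distances):
# classic between/within partition of the response matrix
oracle_pseudo_f <- function(z, groups) {
  z <- as.matrix(z)
  groups <- factor(groups)
  n <- nrow(z)
  a <- nlevels(groups)
  grand <- colMeans(z)
  ssw <- 0
  ssb <- 0
  for (g in levels(groups)) {
    zg <- z[groups == g, , drop = FALSE]
    m <- colMeans(zg)
    ssw <- ssw + sum(sweep(zg, 2, m)^2)
    ssb <- ssb + nrow(zg) * sum((m - grand)^2)
  }
  if (ssb < 1e-12) return(0)
  (ssb / (a - 1)) / (ssw / (n - a))
}
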