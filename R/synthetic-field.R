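# synthetic two-pathway current/wind and environmental fields
#
# The generator plants the seasonal structure the downstream pipeline is
# supposed to recover: on pathway-A year-days a meandering jet routes water
# from a low-latitude eastern source along a synthetic coastline to the
# target (Barbados-like launch point); on pathway-B year-days a direct
# near-zonal jet runs from a higher-latitude eastern source to the same
# target. Purely kinematic -- no dynamical consistency is claimed.

#' Seasonal regime calendar
#'
#' Partition of the 365-day year into pathway regimes A and B. The default
#' places regime A (southern meandering pathway) on year-days 60--218
#' (approx. 1 March -- early August) and regime B on the remainder,
#' mirroring the seasonal split of stranding pathways.
#'
#' @param start,end Integer vectors of 0-based year-days (inclusive bounds).
#' @param regime Character vector of "A"/"B" labels, one per interval.
#' @return A `regime_calendar` data frame.
#' @export
regime_calendar <- function(start, end, regime) {
  stopifnot(length(start) == length(end), length(start) == length(regime),
            all(regime %in% c("A", "B")),
            all(start >= 0 & start <= 364), all(end >= 0 & end <= 364),
            all(start <= end))
  cover <- integer(365)
  for (k in seq_along(start)) cover[(start[k]:end[k]) + 1] <- cover[(start[k]:end[k]) + 1] + 1L
  if (any(cover != 1L))
    stop("regime_calendar: intervals must cover all 365 year-days exactly once")
  if (!all(c("A", "B") %in% regime))
    stop("regime_calendar: need at least one interval per regime")
  structure(data.frame(start = as.integer(start), end = as.integer(end),
                       regime = as.character(regime)),
            class = c("regime_calendar", "data.frame"))
}

#' @rdname regime_calendar
#' @export
default_regime_calendar <- function() {
  regime_calendar(start = c(0, 60, 219), end = c(59, 218, 364),
                  regime = c("B", "A", "B"))
}

#' Regime of given year-days
#'
#' @param calendar A `regime_calendar`.
#' @param yearday Integer/real 0-based year-days.
#' @return Character vector of "A"/"B".
#' @export
regime_of_yearday <- function(calendar, yearday) {
  yd <- floor(yearday %% 365)
  out <- rep(NA_character_, length(yd))
  for (k in seq_len(nrow(calendar)))
    out[yd >= calendar$start[k] & yd <= calendar$end[k]] <- calendar$regime[k]
  if (anyNA(out)) stop("regime lookup failed for some year-days")
  out
}

# smooth regime-A weight for each of the 365 year-days: the 0/1 indicator
# circularly convolved with a Hann window of `blend` days, so fields switch
# regimes without velocity discontinuities
regime_weights <- function(calendar, blend = 10) {
  ind <- as.numeric(regime_of_yearday(calendar, 0:364) == "A")
  if (blend <= 0) return(ind)
  h <- floor(blend / 2)
  k <- -h:h
  w <- 0.5 * (1 + cos(pi * k / (h + 1)))
  w <- w / sum(w)
  sapply(0:364, function(d) sum(w * ind[((d + k) %% 365) + 1]))
}

#' Synthetic field configuration
#'
#' Domain, resolution, target location and jet parameters for the synthetic
#' two-pathway current field. Defaults give a 1/4-degree tropical-Atlantic
#' style domain (62W--30W, 5S--22N) with a Barbados-like target.
#'
#' Jet speeds are free parameters of the emulation (no observed speeds are
#' imposed); they specify the net along-axis drift speed of floating
#' material (see `windage_assumed`) and default to 0.80 m/s on the fast
#' coastal/meandering pathway A (Guiana-current-like) and 0.20 m/s on the
#' direct zonal pathway B, chosen by transit-time arithmetic so a 365-day
#' backtrack under the default regime calendar traverses most of each
#' pathway.
#'
#' @param lon_range,lat_range Domain bounds (degrees).
#' @param res Grid resolution (degrees).
#' @param target `(lon, lat)` of the stranding/launch point.
#' @param jet_speed_a,jet_speed_b Peak jet speeds (m/s).
#' @param jet_width Gaussian cross-jet half-width (degrees).
#' @param meander_amp,meander_wavelength Meander amplitude / wavelength of
#'   pathway A's equatorial segment (degrees).
#' @param turn_lon Longitude where pathway A turns from its equatorial
#'   segment onto the coastal segment toward the target.
#' @param src_lat_a,src_lat_b Latitudes of the eastern source regions.
#' @param background Weak uniform westward background current (m/s).
#' @param wind_u,wind_v Constant 10-m trade wind components (m/s).
#' @param windage_assumed Windage fraction assumed when compensating the
#'   ambient drift inside the jet cores: jet speeds specify the net
#'   along-axis drift speed of floating material, so the stored current
#'   field cancels the background current and the assumed windage
#'   contribution where the jet weight is 1.
#' @param coast_margin Ocean margin between pathway A's coastal axis and the
#'   synthetic coastline (degrees).
#' @param noise Amplitude of smooth random velocity perturbations, as a
#'   fraction of `jet_speed_a` (0 disables).
#' @param blend Regime cross-fade width at calendar boundaries (days).
#' @param seed Integer seed for the (optional) noise field.
#' @return A `field_config` list.
#' @export
field_config <- function(lon_range = c(-62, -30), lat_range = c(-5, 22),
                         res = 0.25,
                         target = c(-59.56345, 13.26802),
                         jet_speed_a = 0.80, jet_speed_b = 0.20,
                         jet_width = 1.0,
                         meander_amp = 2, meander_wavelength = 8,
                         turn_lon = -52, src_lat_a = 3, src_lat_b = 17,
                         background = 0.02, wind_u = -5, wind_v = 0,
                         windage_assumed = 0.005,
                         coast_margin = 2, noise = 0, blend = 10,
                         seed = 1L) {
  cfg <- list(lon_range = lon_range, lat_range = lat_range, res = res,
              target = target, jet_speed_a = jet_speed_a,
              jet_speed_b = jet_speed_b, jet_width = jet_width,
              meander_amp = meander_amp,
              meander_wavelength = meander_wavelength, turn_lon = turn_lon,
              src_lat_a = src_lat_a, src_lat_b = src_lat_b,
              background = background, wind_u = wind_u, wind_v = wind_v,
              windage_assumed = windage_assumed,
              coast_margin = coast_margin, noise = noise, blend = blend,
              seed = as.integer(seed))
  validate_field_config(cfg)
  cfg
}

validate_field_config <- function(cfg) {
  with(cfg, {
    if (res <= 0) stop("field_config: res must be > 0")
    if (lon_range[1] >= lon_range[2] || lat_range[1] >= lat_range[2])
      stop("field_config: bounds must be ordered")
    if (jet_speed_a <= 0 || jet_speed_b <= 0)
      stop("field_config: jet speeds must be > 0")
    if (target[1] < lon_range[1] || target[1] > lon_range[2] ||
        target[2] < lat_range[1] || target[2] > lat_range[2])
      stop("field_config: target outside domain")
    if (src_lat_a < lat_range[1] || src_lat_a > lat_range[2] ||
        src_lat_b < lat_range[1] || src_lat_b > lat_range[2] ||
        turn_lon <= lon_range[1] || turn_lon >= lon_range[2])
      stop("field_config: domain too small to contain both jets")
  })
  invisible(cfg)
}

# pathway-A axis latitude and slope dlat/dlon as functions of longitude:
# meandering equatorial segment east of turn_lon, linear coastal segment
# rising to the target west of it
axis_a <- function(lon, cfg) {
  k <- 2 * pi / cfg$meander_wavelength
  lat_turn <- cfg$src_lat_a +
    cfg$meander_amp * sin(k * (cfg$turn_lon - cfg$lon_range[2]))
  m_coast <- (cfg$target[2] - lat_turn) / (cfg$target[1] - cfg$turn_lon)
  east <- lon >= cfg$turn_lon
  lat <- ifelse(east,
                cfg$src_lat_a + cfg$meander_amp * sin(k * (lon - cfg$lon_range[2])),
                lat_turn + m_coast * (lon - cfg$turn_lon))
  slope <- ifelse(east,
                  cfg$meander_amp * k * cos(k * (lon - cfg$lon_range[2])),
                  m_coast)
  list(lat = lat, slope = slope)
}

# pathway-B axis: square-root rise from the target toward the eastern
# source, so the two jet corridors separate quickly near the target
axis_b <- function(lon, cfg) {
  span <- cfg$lon_range[2] - cfg$target[1]
  x <- pmax(lon - cfg$target[1], 0)
  f <- sqrt(x / span)
  lat <- cfg$target[2] + (cfg$src_lat_b - cfg$target[2]) * f
  slope <- ifelse(x > 0,
                  (cfg$src_lat_b - cfg$target[2]) / (2 * sqrt(x * span)),
                  0)
  list(lat = lat, slope = pmin(slope, 3))
}

# synthetic coastline: land lies coast_margin degrees south of pathway A's
# axis envelope (a NE-South-America-like wedge in the south-west)
coast_lat <- function(lon, cfg) {
  k <- 2 * pi / cfg$meander_wavelength
  lat_turn <- cfg$src_lat_a +
    cfg$meander_amp * sin(k * (cfg$turn_lon - cfg$lon_range[2]))
  m_coast <- (cfg$target[2] - lat_turn) / (cfg$target[1] - cfg$turn_lon)
  env <- ifelse(lon >= cfg$turn_lon,
                cfg$src_lat_a - cfg$meander_amp,
                lat_turn - cfg$meander_amp + m_coast * (lon - cfg$turn_lon))
  env - cfg$coast_margin
}

# velocity of one jet on the (lon, lat) mesh: along-axis flow toward the
# target (westward), Gaussian decay across the axis. The meridional
# component carries a 1/cos(lat) factor so that particle motion follows
# the axis slope in lon/lat degree space (advection divides zonal motion
# by cos(lat)); a particle offset from the axis then keeps a constant
# offset instead of drifting off the jet.
jet_field <- function(lon_m, lat_m, axis, speed, width) {
  w <- exp(-(lat_m - axis$lat)^2 / (2 * width^2))
  nrm <- sqrt(1 + axis$slope^2)
  list(u = speed * (-1 / nrm) * w,
       v = speed * (-axis$slope / nrm) * w / cos(lat_m * pi / 180))
}

#' Generate the synthetic two-pathway current and wind fields
#'
#' Builds a 365-year-day `velocity_grid` in which regime-A year-days carry
#' the southern meandering coastal jet and regime-B year-days the direct
#' northern jet, cross-faded over `cfg$blend` days at calendar boundaries,
#' plus a weak westward background everywhere. The wind grid is a constant
#' trade-wind field. Deterministic for a fixed config (and seed, when
#' `noise > 0`).
#'
#' @param config A [field_config()].
#' @param calendar A [regime_calendar()].
#' @return List with elements `currents` (`velocity_grid`) and `wind`
#'   (`velocity_grid`, time-constant).
#' @export
generate_current_field <- function(config = field_config(),
                                   calendar = default_regime_calendar()) {
  validate_field_config(config)
  lon <- seq(config$lon_range[1], config$lon_range[2], by = config$res)
  lat <- seq(config$lat_range[1], config$lat_range[2], by = config$res)
  nlon <- length(lon); nlat <- length(lat)
  lon_m <- matrix(lon, nlon, nlat)
  lat_m <- matrix(lat, nlon, nlat, byrow = TRUE)

  land <- lat_m < coast_lat(lon_m, config)

  ax_a <- axis_a(lon, config)
  ax_b <- axis_b(lon, config)
  expand <- function(ax) list(lat = matrix(ax$lat, nlon, nlat),
                              slope = matrix(ax$slope, nlon, nlat))
  a <- jet_field(lon_m, lat_m, expand(ax_a), config$jet_speed_a, config$jet_width)
  b <- jet_field(lon_m, lat_m, expand(ax_b), config$jet_speed_b, config$jet_width)

  # inside a jet core the ambient westward drift (background current plus
  # the windage floating material feels) is cancelled, so the jet speed is
  # the net along-axis drift speed of tracked material
  drift_comp <- config$background +
    config$windage_assumed * sqrt(config$wind_u^2 + config$wind_v^2)
  wgt_a <- exp(-(lat_m - expand(ax_a)$lat)^2 / (2 * config$jet_width^2))
  wgt_b <- exp(-(lat_m - expand(ax_b)$lat)^2 / (2 * config$jet_width^2))
  a$u <- a$u + drift_comp * wgt_a
  b$u <- b$u + drift_comp * wgt_b

  bg_u <- -config$background

  if (config$noise > 0) {
    set.seed(config$seed)
    nz_u <- smooth_noise(nlon, nlat) * config$noise * config$jet_speed_a
    nz_v <- smooth_noise(nlon, nlat) * config$noise * config$jet_speed_a
  } else {
    nz_u <- 0; nz_v <- 0
  }

  wA <- regime_weights(calendar, config$blend)
  u <- array(0, c(nlon, nlat, 365L))
  v <- array(0, c(nlon, nlat, 365L))
  for (d in 1:365) {
    u[, , d] <- wA[d] * a$u + (1 - wA[d]) * b$u + bg_u + nz_u
    v[, , d] <- wA[d] * a$v + (1 - wA[d]) * b$v + nz_v
  }
  currents <- velocity_grid(lon, lat, u, v, land = land)
  wind <- velocity_grid(lon, lat,
                        array(config$wind_u, c(nlon, nlat, 1L)),
                        array(config$wind_v, c(nlon, nlat, 1L)),
                        land = land)
  list(currents = currents, wind = wind)
}

# smooth random surface: coarse white noise bilinearly upsampled
smooth_noise <- function(nlon, nlat, factor = 8) {
  nc <- max(2, ceiling(nlon / factor) + 1)
  nr <- max(2, ceiling(nlat / factor) + 1)
  coarse <- matrix(stats::rnorm(nc * nr), nc, nr)
  xi <- seq(1, nc, length.out = nlon)
  yi <- seq(1, nr, length.out = nlat)
  i0 <- pmin(floor(xi), nc - 1); wx <- xi - i0
  j0 <- pmin(floor(yi), nr - 1); wy <- yi - j0
  out <- matrix(0, nlon, nlat)
  for (j in seq_len(nlat)) {
    c0 <- coarse[, j0[j]] * (1 - wy[j]) + coarse[, j0[j] + 1] * wy[j]
    out[, j] <- c0[i0] * (1 - wx) + c0[i0 + 1] * wx
  }
  out
}

#' Generate synthetic 8-day composite SST and chlorophyll fields
#'
#' SST decreases monotonically poleward (warmer toward the equator) with a
#' mild seasonal cycle and smooth spatial noise; chlorophyll-a is highest
#' near the synthetic coast with multiplicative lognormal noise. 46
#' composites cover the 365-day year. Land cells are `NA`.
#'
#' @param config A [field_config()] (domain and coastline are shared with
#'   the current field).
#' @param seed Integer seed.
#' @param sst_equator SST at latitude 0 (deg C).
#' @param sst_gradient Meridional SST decrease (deg C per degree latitude).
#' @param sst_seasonal Seasonal half-amplitude (deg C).
#' @param noise_sd Spatial noise sd: additive deg C for SST, log-scale for
#'   chlorophyll.
#' @return An `env_grid` with arrays `sst` and `chl` of dim
#'   `[lon, lat, 46]` and composite-centre year-days (0-based).
#' @export
generate_env_fields <- function(config = field_config(), seed = 1L,
                                sst_equator = 29, sst_gradient = 0.22,
                                sst_seasonal = 0.7, noise_sd = 0.3) {
  validate_field_config(config)
  set.seed(as.integer(seed))
  lon <- seq(config$lon_range[1], config$lon_range[2], by = config$res)
  lat <- seq(config$lat_range[1], config$lat_range[2], by = config$res)
  nlon <- length(lon); nlat <- length(lat)
  lat_m <- matrix(lat, nlon, nlat, byrow = TRUE)
  lon_m <- matrix(lon, nlon, nlat)
  land <- lat_m < coast_lat(lon_m, config)
  centres <- 8 * (seq_len(46) - 1) + 3.5   # 0-based composite centres
  coast_dist <- pmax(lat_m - coast_lat(lon_m, config), 0)
  sst <- array(NA_real_, c(nlon, nlat, 46L))
  chl <- array(NA_real_, c(nlon, nlat, 46L))
  for (k in seq_len(46)) {
    season <- sst_seasonal * sin(2 * pi * (centres[k] - 120) / 365)
    s <- sst_equator - sst_gradient * abs(lat_m) + season +
      noise_sd * smooth_noise(nlon, nlat)
    c0 <- exp(log(0.1) + log(1 + 6 * exp(-coast_dist / 1.5)) +
                noise_sd * smooth_noise(nlon, nlat))
    s[land] <- NA; c0[land] <- NA
    sst[, , k] <- s
    chl[, , k] <- c0
  }
  structure(list(lon = lon, lat = lat, composite_yearday = centres,
                 sst = sst, chl = chl, land = land,
                 dlon = lon[2] - lon[1], dlat = lat[2] - lat[1]),
            class = "env_grid")
}

#' @export
print.env_grid <- function(x, ...) {
  cat(sprintf("env_grid: %d x %d cells, %d 8-day composites, SST %.1f--%.1f degC\n",
              length(x$lon), length(x$lat), length(x$composite_yearday),
              min(x$sst, na.rm = TRUE), max(x$sst, na.rm = TRUE)))
  invisible(x)
}
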