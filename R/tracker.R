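# Lagrangian particle tracking: backward/forward advection with windage and
# a Lagrangian stochastic turbulence model

#' Tracking configuration
#'
#' Defaults follow the reference backtracking setup: 100 particles, 365-day
#' horizon, 6-h explicit Euler steps, 0.5% windage and turbulence
#' coefficient 0.1.
#'
#' @param n_particles Ensemble size (>= 1).
#' @param horizon_days Integration horizon (days).
#' @param dt Step (seconds); `horizon_days * 86400` must be a multiple.
#' @param windage Fraction of the 10-m wind added to the (unperturbed)
#'   current velocity.
#' @param turbulence Turbulence coefficient multiplying current speed in
#'   the stochastic perturbation.
#' @param seed Integer seed for the ensemble's random draws.
#' @param direction `"backward"` or `"forward"`.
#' @return A `track_config` list.
#' @export
track_config <- function(n_particles = 100, horizon_days = 365, dt = 21600,
                         windage = 0.005, turbulence = 0.1, seed = 1L,
                         direction = c("backward", "forward")) {
  direction <- match.arg(direction)
  stopifnot(n_particles >= 1, dt > 0, windage >= 0, turbulence >= 0,
            horizon_days > 0)
  if (abs((horizon_days * 86400) %% dt) > 1e-9)
    stop("track_config: horizon must be an integer number of steps")
  list(n_particles = as.integer(n_particles), horizon_days = horizon_days,
       dt = dt, windage = windage, turbulence = turbulence,
       seed = as.integer(seed), direction = direction)
}

#' Stochastic velocity perturbation
#'
#' Adds sub-grid turbulence to each velocity component:
#' `u' = u + coeff * s * Z_u`, `v' = v + coeff * s * Z_v` with
#' `s = sqrt(u^2 + v^2)` the current speed and `Z` independent standard
#' normal draws. With `coeff = 0` (or zero speed) the velocity is returned
#' unchanged.
#'
#' @param u,v Velocity components (m/s, vectorized).
#' @param coeff Turbulence coefficient (dimensionless).
#' @return List with perturbed components `u` and `v`.
#' @export
perturb_velocity <- function(u, v, coeff = 0.1) {
  if (coeff == 0) return(list(u = u, v = v))
  s <- sqrt(u^2 + v^2)
  n <- length(u)
  list(u = u + coeff * s * stats::rnorm(n),
       v = v + coeff * s * stats::rnorm(n))
}

# one advection step over positions (lon, lat); returns new positions and
# updated grounded/exited flags. Frozen particles are not moved.
.advect <- function(lon, lat, currents, wind, t, cfg, sgn, frozen) {
  act <- which(!frozen)
  if (length(act) == 0) return(list(lon = lon, lat = lat,
                                    grounded = logical(length(lon)),
                                    exited = logical(length(lon))))
  uv <- .sample_uv(currents, lon[act], lat[act], t)
  uv <- perturb_velocity(uv$u, uv$v, cfg$turbulence)
  if (!is.null(wind) && cfg$windage > 0) {
    wv <- .sample_uv(wind, lon[act], lat[act], t)
    uv$u <- uv$u + cfg$windage * wv$u
    uv$v <- uv$v + cfg$windage * wv$v
  }
  new_lon <- lon[act] + sgn * uv$u * cfg$dt / (M_PER_DEG * cos(lat[act] * pi / 180))
  new_lat <- lat[act] + sgn * uv$v * cfg$dt / M_PER_DEG
  exited <- !in_grid_domain(currents, new_lon, new_lat)
  grounded <- logical(length(act))
  chk <- !exited
  grounded[chk] <- is_land(currents, new_lon[chk], new_lat[chk])
  move <- !exited & !grounded
  out_g <- logical(length(lon)); out_e <- logical(length(lon))
  out_g[act[grounded]] <- TRUE
  out_e[act[exited]] <- TRUE
  lon[act[move]] <- new_lon[move]
  lat[act[move]] <- new_lat[move]
  list(lon = lon, lat = lat, grounded = out_g, exited = out_e)
}

#' Single advection step
#'
#' Advances positions one step of length `cfg$dt`: total velocity is the
#' turbulence-perturbed current plus `windage x wind`, converted to degrees
#' on a sphere of radius 6371 km; the sign is reversed for backward
#' tracking. A particle whose destination cell is land stays in place and
#' is flagged grounded; one leaving the domain stays in place and is
#' flagged exited.
#'
#' @param pos Matrix `n x 2` of (lon, lat), or a length-2 vector.
#' @param currents,wind `velocity_grid`s (wind may be `NULL`).
#' @param yearday Real year-day at the step start (0-based).
#' @param cfg A [track_config()].
#' @return Matrix `n x 2` of new positions, with logical attributes
#'   `grounded` and `exited`.
#' @export
advect_step <- function(pos, currents, wind = NULL, yearday = 0,
                        cfg = track_config()) {
  if (is.null(dim(pos))) pos <- matrix(pos, ncol = 2)
  sgn <- if (cfg$direction == "backward") -1 else 1
  st <- .advect(pos[, 1], pos[, 2], currents, wind, yearday, cfg, sgn,
                frozen = logical(nrow(pos)))
  out <- cbind(lon = st$lon, lat = st$lat)
  attr(out, "grounded") <- st$grounded
  attr(out, "exited") <- st$exited
  out
}

# snap a (possibly coastal) launch point to the nearest ocean cell centre
# within max_cells; error beyond that
snap_to_ocean <- function(grid, lon, lat, max_cells = 2) {
  if (!in_grid_domain(grid, lon, lat)) stop("launch point outside domain")
  if (!is_land(grid, lon, lat)) return(c(lon, lat))
  i0 <- round((lon - grid$lon[1]) / grid$dlon) + 1
  j0 <- round((lat - grid$lat[1]) / grid$dlat) + 1
  best <- NULL; best_d <- Inf
  for (di in -max_cells:max_cells) for (dj in -max_cells:max_cells) {
    i <- i0 + di; j <- j0 + dj
    if (i < 1 || i > length(grid$lon) || j < 1 || j > length(grid$lat)) next
    if (grid$land[i, j]) next
    d <- haversine_km(lon, lat, grid$lon[i], grid$lat[j])
    if (d < best_d) { best_d <- d; best <- c(grid$lon[i], grid$lat[j]) }
  }
  if (is.null(best))
    stop("launch point more than ", max_cells, " cells from any ocean cell")
  best
}

#' Backtrack an ensemble from a collection point
#'
#' Launches `cfg$n_particles` particles simultaneously from the collection
#' location and integrates them backward (or forward) for the configured
#' horizon through the year-day climatology, each with independent
#' turbulent perturbations. Per-particle cumulative great-circle distance,
#' endpoints and the ensemble centre of mass (arithmetic mean of endpoint
#' lon and lat; grounded particles included) are recorded. Deterministic
#' for a fixed `cfg$seed`.
#'
#' @param launch_lon,launch_lat Launch coordinates (snapped to the nearest
#'   ocean cell if on land; error if more than 2 cells away).
#' @param collection_date `Date` (or 0-based numeric year-day) of
#'   collection; sets the climatological clock.
#' @param currents,wind `velocity_grid`s (`wind = NULL` disables windage).
#' @param cfg A [track_config()].
#' @param store_trajectories Keep full position histories (needed for
#'   midpoint extraction and plotting).
#' @return A `backtrack_result`: launch/date, endpoints (`n x 2`),
#'   `center_of_mass`, `cum_dist_km`, grounded/exited flags,
#'   `grounding_step`, optional `lon_traj`/`lat_traj` matrices
#'   (`steps+1 x n`), and the config.
#' @export
backtrack_sample <- function(launch_lon, launch_lat, collection_date,
                             currents, wind = NULL, cfg = track_config(),
                             store_trajectories = TRUE) {
  yd0 <- if (inherits(collection_date, "Date"))
    date_to_yearday(collection_date) else as.numeric(collection_date)
  launch <- snap_to_ocean(currents, launch_lon, launch_lat)
  sgn <- if (cfg$direction == "backward") -1 else 1
  n <- cfg$n_particles
  n_steps <- as.integer(round(cfg$horizon_days * 86400 / cfg$dt))
  dt_days <- cfg$dt / 86400

  set.seed(cfg$seed)
  lon <- rep(launch[1], n); lat <- rep(launch[2], n)
  frozen <- logical(n)
  grounded <- logical(n); exited <- logical(n)
  grounding_step <- rep(NA_integer_, n)
  cum <- numeric(n)
  if (store_trajectories) {
    lon_traj <- matrix(NA_real_, n_steps + 1, n)
    lat_traj <- matrix(NA_real_, n_steps + 1, n)
    lon_traj[1, ] <- lon; lat_traj[1, ] <- lat
  }
  for (k in seq_len(n_steps)) {
    t <- (yd0 + sgn * (k - 1) * dt_days) %% 365
    old_lon <- lon; old_lat <- lat
    st <- .advect(lon, lat, currents, wind, t, cfg, sgn, frozen)
    lon <- st$lon; lat <- st$lat
    moved <- lon != old_lon | lat != old_lat
    if (any(moved))
      cum[moved] <- cum[moved] +
        haversine_km(old_lon[moved], old_lat[moved], lon[moved], lat[moved])
    newly <- (st$grounded | st$exited) & !frozen
    grounding_step[newly & st$grounded] <- k
    grounded <- grounded | st$grounded
    exited <- exited | st$exited
    frozen <- frozen | newly
    if (store_trajectories) {
      lon_traj[k + 1, ] <- lon; lat_traj[k + 1, ] <- lat
    }
  }
  stopifnot(diff(range(lon)) < 180)  # centre-of-mass lon mean needs a
                                     # domain away from the antimeridian
  res <- list(
    launch = c(lon = launch[1], lat = launch[2]),
    launch_requested = c(lon = launch_lon, lat = launch_lat),
    date = if (inherits(collection_date, "Date")) collection_date else NULL,
    yearday = yd0,
    endpoints = cbind(lon = lon, lat = lat),
    center_of_mass = c(lon = mean(lon), lat = mean(lat)),
    cum_dist_km = cum,
    grounded = grounded, exited = exited, grounding_step = grounding_step,
    config = cfg)
  if (store_trajectories) {
    res$lon_traj <- lon_traj
    res$lat_traj <- lat_traj
  }
  structure(res, class = "backtrack_result")
}

#' @export
print.backtrack_result <- function(x, ...) {
  cat(sprintf(
    "backtrack_result: %d particles, %g days %s from (%.3f, %.3f)%s\n",
    nrow(x$endpoints),
    x$config$horizon_days, x$config$direction,
    x$launch["lon"], x$launch["lat"],
    if (!is.null(x$date)) paste0(" on ", x$date) else ""))
  cat(sprintf("  centre of mass (%.3f, %.3f); mean distance %.0f km; %d grounded, %d exited\n",
              x$center_of_mass["lon"], x$center_of_mass["lat"],
              mean(x$cum_dist_km), sum(x$grounded), sum(x$exited)))
  invisible(x)
}

#' Ensemble mean position a given number of days along the track
#'
#' @param result A `backtrack_result` with stored trajectories.
#' @param days_along Days along the track (e.g. 183 for the midpoint of a
#'   365-day backtrack).
#' @return Named vector `(lon, lat)`.
#' @export
ensemble_position <- function(result, days_along) {
  if (is.null(result$lon_traj))
    stop("trajectories were not stored; rerun with store_trajectories = TRUE")
  k <- round(days_along * 86400 / result$config$dt) + 1
  k <- min(max(k, 1), nrow(result$lon_traj))
  c(lon = mean(result$lon_traj[k, ]), lat = mean(result$lat_traj[k, ]))
}

#' Forward dispersal / retention experiment
#'
#' Seeds particles uniformly at random over the ocean cells of a lon/lat
#' box, advects them forward, and reports the fraction still inside the box
#' at each day, together with the first day at which the fraction drops to
#' 0.1 or below (the "90% dispersed" horizon).
#'
#' @param box `c(lon_min, lon_max, lat_min, lat_max)`.
#' @param n_particles Number of particles.
#' @param horizon_days Integration horizon (days).
#' @param currents,wind `velocity_grid`s.
#' @param cfg A [track_config()]; `n_particles`, `horizon_days` and
#'   direction are overridden.
#' @param start_yearday Seeding year-day (0-based).
#' @return A `dispersal_curve`: data frame `day`, `fraction`, plus
#'   attributes `day90` (first day fraction <= 0.1, `NA` if never) and the
#'   seeded positions.
#' @export
forward_dispersal <- function(box, n_particles, horizon_days, currents,
                              wind = NULL, cfg = track_config(),
                              start_yearday = 0) {
  stopifnot(length(box) == 4, box[1] < box[2], box[3] < box[4])
  cfg$n_particles <- as.integer(n_particles)
  cfg$horizon_days <- horizon_days
  cfg$direction <- "forward"
  in_box_cells <- which(
    outer(currents$lon >= box[1] & currents$lon <= box[2],
          currents$lat >= box[3] & currents$lat <= box[4], "&") &
      !currents$land)
  if (length(in_box_cells) == 0) stop("box contains no ocean cells")
  set.seed(cfg$seed)
  nlon <- length(currents$lon)
  cells <- sample(in_box_cells, n_particles, replace = TRUE)
  i <- (cells - 1L) %% nlon + 1L
  j <- (cells - 1L) %/% nlon + 1L
  lon <- currents$lon[i] + (stats::runif(n_particles) - 0.5) * currents$dlon
  lat <- currents$lat[j] + (stats::runif(n_particles) - 0.5) * currents$dlat
  lon <- pmin(pmax(lon, box[1]), box[2])
  lat <- pmin(pmax(lat, box[3]), box[4])

  steps_per_day <- as.integer(round(86400 / cfg$dt))
  n_steps <- as.integer(horizon_days * steps_per_day)
  dt_days <- cfg$dt / 86400
  frozen <- logical(n_particles)
  frac <- numeric(horizon_days + 1)
  in_box <- function(lon, lat)
    lon >= box[1] & lon <= box[2] & lat >= box[3] & lat <= box[4]
  frac[1] <- mean(in_box(lon, lat))
  for (k in seq_len(n_steps)) {
    t <- (start_yearday + (k - 1) * dt_days) %% 365
    st <- .advect(lon, lat, currents, wind, t, cfg, 1, frozen)
    lon <- st$lon; lat <- st$lat
    frozen <- frozen | st$grounded | st$exited
    if (k %% steps_per_day == 0)
      frac[k / steps_per_day + 1] <- mean(in_box(lon, lat))
  }
  out <- data.frame(day = 0:horizon_days, fraction = frac)
  hit <- which(frac <= 0.1)
  attr(out, "day90") <- if (length(hit)) out$day[hit[1]] else NA_integer_
  attr(out, "n_particles") <- n_particles
  class(out) <- c("dispersal_curve", "data.frame")
  out
}
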