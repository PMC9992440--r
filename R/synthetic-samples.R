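# synthetic drifter fixes and beach morphotype samples

#' Simulate drifter fix records from a velocity grid
#'
#' Emulates mixed-layer drifter records: drifters are seeded uniformly over
#' ocean cells, advected forward with the grid velocity at a 6-h step, and a
#' fix (year, day, hour, lon, lat, u, v, drogue flag) is recorded every 6 h.
#' Reported velocities are the grid velocities sampled at the fix position
#' plus optional Gaussian observation noise. Drifters drawn on land are
#' rejected and re-seeded (count in attribute `n_reseeded`).
#'
#' @param grid A `velocity_grid`.
#' @param n_drifters Number of drifters (>= 1).
#' @param duration_days Record length per drifter (days, >= 1).
#' @param seed Integer seed.
#' @param noise_sd Observation noise sd on reported velocities (m/s);
#'   default 0.02, use 0 for exact grid values.
#' @param year Nominal deployment year written to the records.
#' @param drogue_prob Probability a drifter keeps its drogue for the whole
#'   record (flag is constant per drifter).
#' @return A `drifter_fixes` data frame with columns
#'   `year, day, hour, lon, lat, u, v, drogue` (`day` is the 1-based
#'   year-day, `hour` in \{0, 6, 12, 18\}).
#' @export
generate_drifter_fixes <- function(grid, n_drifters, duration_days, seed = 1L,
                                   noise_sd = 0.02, year = 2020L,
                                   drogue_prob = 0.7) {
  stopifnot(n_drifters >= 1, duration_days >= 1)
  set.seed(as.integer(seed))
  nlon <- length(grid$lon); nlat <- length(grid$lat)
  ocean <- which(!grid$land)
  if (length(ocean) == 0) stop("grid has no ocean cells")

  n_reseeded <- 0L
  draw_start <- function(n) {
    cells <- sample(seq_len(nlon * nlat), n, replace = TRUE)
    bad <- grid$land[cells]
    n_reseeded <<- n_reseeded + sum(bad)
    while (any(bad)) {
      cells[bad] <- sample(seq_len(nlon * nlat), sum(bad), replace = TRUE)
      bad <- grid$land[cells]
      n_reseeded <<- n_reseeded + sum(bad)
    }
    i <- (cells - 1L) %% nlon + 1L
    j <- (cells - 1L) %/% nlon + 1L
    cbind(pmin(pmax(grid$lon[i] + (stats::runif(n) - 0.5) * grid$dlon,
                    grid$lon[1]), grid$lon[nlon]),
          pmin(pmax(grid$lat[j] + (stats::runif(n) - 0.5) * grid$dlat,
                    grid$lat[1]), grid$lat[nlat]))
  }
  pos <- draw_start(n_drifters)
  start_day <- sample.int(365, n_drifters, replace = TRUE) - 1L  # 0-based
  drogue <- stats::runif(n_drifters) < drogue_prob

  n_steps <- as.integer(duration_days * 4)  # fixes at 0,6,12,18 h each day
  recs <- vector("list", n_steps)
  lon <- pos[, 1]; lat <- pos[, 2]
  for (k in seq_len(n_steps)) {
    t <- (start_day + (k - 1) * 0.25) %% 365
    uv <- sample_velocity(grid, lon, lat, t, out_of_domain = "zero")
    recs[[k]] <- data.frame(
      id = seq_len(n_drifters),
      step = k,
      year = year,
      day = as.integer(floor(t)) + 1L,
      hour = as.integer(((k - 1) %% 4) * 6),
      lon = lon, lat = lat,
      u = uv$u + if (noise_sd > 0) stats::rnorm(n_drifters, 0, noise_sd) else 0,
      v = uv$v + if (noise_sd > 0) stats::rnorm(n_drifters, 0, noise_sd) else 0,
      drogue = drogue
    )
    # forward advection at the grid velocity; drifters leaving the domain
    # or running aground are frozen (their later fixes stay in place)
    dt <- 21600
    dlon_d <- uv$u * dt / (M_PER_DEG * cos(lat * pi / 180))
    dlat_d <- uv$v * dt / M_PER_DEG
    cand_lon <- lon + dlon_d
    cand_lat <- lat + dlat_d
    ok <- in_grid_domain(grid, cand_lon, cand_lat)
    ok[ok] <- !is_land(grid, cand_lon[ok], cand_lat[ok])
    lon[ok] <- cand_lon[ok]
    lat[ok] <- cand_lat[ok]
  }
  out <- do.call(rbind, recs)
  out <- out[order(out$id, out$step), ]
  out$step <- NULL
  rownames(out) <- NULL
  structure(out, class = c("drifter_fixes", "data.frame"),
            n_reseeded = n_reseeded)
}

#' Read / write drifter fixes as CSV
#'
#' Column layout follows the compiled drifter record format: year, day
#' (1-based year-day), hour, longitude, latitude, east and north current
#' components (m/s), drogue flag.
#'
#' @param fixes A `drifter_fixes` data frame.
#' @param path File path.
#' @export
write_drifter_csv <- function(fixes, path) {
  utils::write.csv(
    fixes[, c("year", "day", "hour", "lon", "lat", "u", "v", "drogue")],
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_drifter_csv
#' @export
read_drifter_csv <- function(path) {
  df <- utils::read.csv(path)
  names(df) <- tolower(names(df))
  needed <- c("year", "day", "hour", "lon", "lat", "u", "v", "drogue")
  if (!all(needed %in% names(df)))
    stop("drifter CSV must have columns: ", paste(needed, collapse = ", "))
  df$drogue <- as.logical(df$drogue)
  df$lon <- ((df$lon + 180) %% 360) - 180
  stopifnot(all(abs(df$lat) <= 90), all(df$hour %in% c(0L, 6L, 12L, 18L)),
            all(df$day >= 1 & df$day <= 365))
  structure(df, class = c("drifter_fixes", "data.frame"))
}

#' Morphotype composition parameters
#'
#' Per-regime Dirichlet parameters for three-part morphotype compositions
#' in the order (S. natans I, S. natans VIII, S. fluitans III). The default
#' means plant the seasonal contrast seen in strandings: pathway A
#' dominated by S. fluitans III, pathway B with elevated S. natans VIII.
#'
#' @param mean_a,mean_b Strictly positive mean vectors summing to 1.
#' @param concentration Dirichlet concentration (> 0); larger is less
#'   variable.
#' @param clumps_per_date Beach clumps collected per sampling date.
#' @param volume_ml Mean total displacement volume per clump (mL).
#' @return A `composition_params` list.
#' @export
composition_params <- function(mean_a = c(sni = 0.10, snviii = 0.15, sfiii = 0.75),
                               mean_b = c(sni = 0.08, snviii = 0.55, sfiii = 0.37),
                               concentration = 30,
                               clumps_per_date = 3,
                               volume_ml = 250) {
  for (m in list(mean_a, mean_b)) {
    if (length(m) != 3 || any(m <= 0) || abs(sum(m) - 1) > 1e-8)
      stop("composition_params: mean vectors must be 3 strictly positive parts summing to 1")
  }
  if (concentration <= 0) stop("composition_params: concentration must be > 0")
  list(mean_a = mean_a, mean_b = mean_b, concentration = concentration,
       clumps_per_date = clumps_per_date, volume_ml = volume_ml)
}

#' Dirichlet random compositions
#'
#' Gamma-representation sampler: rows are draws from
#' Dirichlet(concentration * mean).
#'
#' @param n Number of draws.
#' @param mean Mean vector (positive, sums to 1).
#' @param concentration Concentration parameter.
#' @return Matrix `n x length(mean)` of compositions.
#' @export
rdirichlet_mean <- function(n, mean, concentration) {
  alpha <- mean * concentration
  g <- matrix(stats::rgamma(n * length(alpha), shape = rep(alpha, each = n)),
              nrow = n)
  g / rowSums(g)
}

#' Generate synthetic beach morphotype samples
#'
#' For each collection date, draws `clumps_per_date` clump compositions
#' from the Dirichlet distribution of the date's regime (per the calendar)
#' and converts them to displacement volumes: volumes = clump total volume
#' x composition. Duplicate dates are allowed (multiple collections).
#'
#' @param dates Vector of collection dates (`Date` or coercible).
#' @param calendar A [regime_calendar()].
#' @param params A [composition_params()].
#' @param seed Integer seed.
#' @return A data frame with columns `date, clump_id, regime,
#'   vol_sni_ml, vol_snviii_ml, vol_sfiii_ml`.
#' @export
generate_morphotype_samples <- function(dates,
                                        calendar = default_regime_calendar(),
                                        params = composition_params(),
                                        seed = 1L) {
  if (length(dates) == 0) stop("dates must be non-empty")
  dates <- as.Date(dates)
  set.seed(as.integer(seed))
  regimes <- regime_of_yearday(calendar, date_to_yearday(dates))
  rows <- vector("list", length(dates))
  for (k in seq_along(dates)) {
    m <- if (regimes[k] == "A") params$mean_a else params$mean_b
    comp <- rdirichlet_mean(params$clumps_per_date, m, params$concentration)
    total <- stats::rgamma(params$clumps_per_date, shape = 25,
                           rate = 25 / params$volume_ml)
    vols <- comp * total
    rows[[k]] <- data.frame(
      date = dates[k],
      clump_id = seq_len(params$clumps_per_date),
      regime = regimes[k],
      vol_sni_ml = vols[, 1], vol_snviii_ml = vols[, 2],
      vol_sfiii_ml = vols[, 3])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read / write morphotype samples as CSV
#'
#' @param samples Sample data frame as produced by
#'   [generate_morphotype_samples()].
#' @param path File path.
#' @export
write_samples_csv <- function(samples, path) {
  utils::write.csv(samples, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_samples_csv
#' @export
read_samples_csv <- function(path) {
  df <- utils::read.csv(path)
  df$date <- as.Date(df$date)
  needed <- c("date", "clump_id", "vol_sni_ml", "vol_snviii_ml", "vol_sfiii_ml")
  if (!all(needed %in% names(df)))
    stop("sample CSV must have columns: ", paste(needed, collapse = ", "))
  df
}
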