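# environmental extraction at origins and trajectory midpoints

#' Box-average SST and chlorophyll around a point
#'
#' Averages the 8-day composite nearest the requested date over a square
#' box of the given area centred on the point. The square side in degrees
#' is `sqrt(area) / 111.32` of latitude and the same length of longitude
#' divided by `cos(lat)`. Only non-missing ocean cells contribute.
#'
#' @param grid An `env_grid` from [generate_env_fields()].
#' @param center `(lon, lat)` of the box centre.
#' @param area_km2 Box area; the default 93,500 km^2 gives a side of
#'   305.78 km (about 2.75 degrees of latitude).
#' @param yearday Target date as 0-based year-day (or a `Date`).
#' @return Named vector `c(sst_mean, chl_mean)`; `NA`s if the box holds no
#'   data (fully outside the grid is an error).
#' @export
box_average <- function(grid, center, area_km2 = 93500, yearday = 0) {
  stopifnot(area_km2 > 0, length(center) == 2)
  if (inherits(yearday, "Date")) yearday <- date_to_yearday(yearday)
  side_km <- sqrt(area_km2)
  half_lat <- side_km / 111.32 / 2
  half_lon <- side_km / (111.32 * cos(center[2] * pi / 180)) / 2
  i <- which(grid$lon >= center[1] - half_lon & grid$lon <= center[1] + half_lon)
  j <- which(grid$lat >= center[2] - half_lat & grid$lat <= center[2] + half_lat)
  if (length(i) == 0 || length(j) == 0)
    stop("box falls entirely outside the environmental grid")
  k <- which.min(abs(yearday_diff(grid$composite_yearday, yearday %% 365)))
  sst <- grid$sst[i, j, k]
  chl <- grid$chl[i, j, k]
  if (all(is.na(sst)) && all(is.na(chl)))
    return(c(sst_mean = NA_real_, chl_mean = NA_real_))
  c(sst_mean = mean(sst, na.rm = TRUE), chl_mean = mean(chl, na.rm = TRUE))
}

#' Environmental records at origin and midpoint of each simulation
#'
#' For every backtrack simulation, evaluates [box_average()] at (1) the
#' centre-of-mass origin, at the collection date minus 365 days, and
#' (2) the ensemble mean position 183 backtracked days along the track, at
#' the collection date minus 183 days. Simulations whose box holds no data
#' yield `NA` records (with a warning) rather than failing.
#'
#' @param results List of `backtrack_result`s (with stored trajectories).
#' @param labels A labelled `suborigin_assignment` (from
#'   [label_suborigins()]), or a named "A"/"B" vector per simulation id.
#' @param grid An `env_grid`.
#' @param area_km2 Box area passed to [box_average()].
#' @return Data frame with one row per (simulation, period): `id, date,
#'   period, suborigin, lon, lat, sst_mean, chl_mean`.
#' @export
extract_env_records <- function(results, labels, grid, area_km2 = 93500) {
  lab <- if (inherits(labels, "suborigin_assignment")) labels$label else labels
  rows <- vector("list", 2 * length(results))
  ids <- names(results) %||% as.character(seq_along(results))
  for (k in seq_along(results)) {
    r <- results[[k]]
    yd0 <- r$yearday
    spots <- list(
      origin = list(pos = r$center_of_mass, yd = (yd0 - 365) %% 365),
      midpoint = list(pos = ensemble_position(r, 183), yd = (yd0 - 183) %% 365))
    for (pn in names(spots)) {
      s <- spots[[pn]]
      ba <- box_average(grid, s$pos, area_km2, s$yd)
      rows[[2 * (k - 1) + match(pn, names(spots))]] <- data.frame(
        id = ids[k],
        date = if (!is.null(r$date)) r$date else as.Date(NA),
        period = pn,
        suborigin = unname(lab[ids[k]]),
        lon = unname(s$pos["lon"]), lat = unname(s$pos["lat"]),
        sst_mean = unname(ba["sst_mean"]), chl_mean = unname(ba["chl_mean"]))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  n_miss <- sum(!stats::complete.cases(out[, c("sst_mean", "chl_mean")]))
  if (n_miss > 0)
    warning(n_miss, " environmental record(s) have no data in their box")
  out
}
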