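# gridded year-day velocity climatologies: container, interpolation, text I/O

#' Construct a year-day velocity grid
#'
#' The substrate the particle tracker advects through: u/v surface velocity
#' components on a regular lon/lat grid with either 365 year-day slices or a
#' single time-constant slice, plus a land mask. Land cells carry zero
#' velocity by definition.
#'
#' @param lon,lat Strictly increasing, uniformly spaced axes of cell centres
#'   (degrees; longitudes in \[-180, 180)).
#' @param u,v Numeric arrays `[lon, lat, yearday]` in m/s. A third dimension
#'   of length 1 denotes a time-constant field.
#' @param land Logical matrix `[lon, lat]`; `TRUE` marks land. Default all
#'   ocean.
#' @param n_obs Optional observation-count array (filled by
#'   [build_climatology()]).
#' @return An object of class `velocity_grid`.
#' @export
velocity_grid <- function(lon, lat, u, v, land = NULL, n_obs = NULL) {
  u <- as_grid_array(u, length(lon), length(lat))
  v <- as_grid_array(v, length(lon), length(lat))
  stopifnot(
    length(lon) >= 2, length(lat) >= 2,
    all(diff(lon) > 0), all(diff(lat) > 0),
    identical(dim(u), dim(v)),
    dim(u)[1] == length(lon), dim(u)[2] == length(lat),
    dim(u)[3] %in% c(1L, 365L)
  )
  if (is.null(land)) land <- matrix(FALSE, length(lon), length(lat))
  stopifnot(identical(dim(land), c(length(lon), length(lat))))
  if (any(land)) {
    for (k in seq_len(dim(u)[3])) {
      uk <- u[, , k]; uk[land] <- 0; u[, , k] <- uk
      vk <- v[, , k]; vk[land] <- 0; v[, , k] <- vk
    }
  }
  structure(list(
    lon = lon, lat = lat, u = u, v = v, land = land, n_obs = n_obs,
    dlon = lon[2] - lon[1], dlat = lat[2] - lat[1], nt = dim(u)[3]
  ), class = "velocity_grid")
}

as_grid_array <- function(x, nlon, nlat) {
  if (length(dim(x)) == 2) dim(x) <- c(dim(x), 1L)
  if (is.null(dim(x)) && length(x) == 1) x <- array(x, c(nlon, nlat, 1L))
  x
}

#' Spatially uniform velocity grid
#'
#' Convenience constructor for analytic test fields: constant (u, v)
#' everywhere, time-invariant.
#'
#' @param u,v Velocity components (m/s).
#' @param lon_range,lat_range Domain bounds (degrees).
#' @param res Grid resolution (degrees).
#' @return A `velocity_grid`.
#' @export
uniform_velocity_grid <- function(u, v, lon_range = c(-170, 170),
                                  lat_range = c(-60, 60), res = 5) {
  lon <- seq(lon_range[1], lon_range[2], by = res)
  lat <- seq(lat_range[1], lat_range[2], by = res)
  velocity_grid(lon, lat,
                array(u, c(length(lon), length(lat), 1L)),
                array(v, c(length(lon), length(lat), 1L)))
}

#' @export
print.velocity_grid <- function(x, ...) {
  cat(sprintf(
    "velocity_grid: %d x %d cells at %.4g deg, %s, lon [%.2f, %.2f], lat [%.2f, %.2f], %d land cells\n",
    length(x$lon), length(x$lat), x$dlon,
    if (x$nt == 1) "time-constant" else "365 year-days",
    min(x$lon), max(x$lon), min(x$lat), max(x$lat), sum(x$land)))
  invisible(x)
}

in_grid_domain <- function(grid, lon, lat) {
  lon >= grid$lon[1] & lon <= grid$lon[length(grid$lon)] &
    lat >= grid$lat[1] & lat <= grid$lat[length(grid$lat)]
}

#' Is a point on land?
#'
#' Nearest-cell lookup of the grid's land mask.
#'
#' @param grid A `velocity_grid`.
#' @param lon,lat Point coordinates (vectorized).
#' @return Logical vector; points outside the domain return `NA`.
#' @export
is_land <- function(grid, lon, lat) {
  ok <- in_grid_domain(grid, lon, lat)
  i <- pmin(pmax(round((lon - grid$lon[1]) / grid$dlon) + 1, 1), length(grid$lon))
  j <- pmin(pmax(round((lat - grid$lat[1]) / grid$dlat) + 1, 1), length(grid$lat))
  out <- grid$land[cbind(i, j)]
  out[!ok] <- NA
  out
}

#' Interpolate grid velocity at points
#'
#' Bilinear interpolation in lon/lat and circular linear interpolation in
#' year-day (day 364 wraps to day 0). Land cells hold zero velocity, so the
#' interpolant decays to (0, 0) toward and over land; a point surrounded by
#' land returns exactly (0, 0).
#'
#' @param grid A `velocity_grid` (or wind grid with the same structure).
#' @param lon,lat Query points (degrees, vectorized).
#' @param yearday Real year-day in \[0, 365); scalar or vector. 0-based:
#'   0 = Jan 1. Ignored for time-constant grids.
#' @param out_of_domain `"error"` (default) or `"zero"` for points outside
#'   the grid bounds.
#' @return List with numeric vectors `u` and `v` (m/s).
#' @export
sample_velocity <- function(grid, lon, lat, yearday = 0,
                            out_of_domain = c("error", "zero")) {
  out_of_domain <- match.arg(out_of_domain)
  inside <- in_grid_domain(grid, lon, lat)
  if (!all(inside)) {
    if (out_of_domain == "error")
      stop("sample_velocity: point(s) outside grid domain")
    lon <- pmin(pmax(lon, grid$lon[1]), grid$lon[length(grid$lon)])
    lat <- pmin(pmax(lat, grid$lat[1]), grid$lat[length(grid$lat)])
  }
  uv <- .sample_uv(grid, lon, lat, yearday)
  if (!all(inside) && out_of_domain == "zero") {
    uv$u[!inside] <- 0
    uv$v[!inside] <- 0
  }
  uv
}

# hot path: no validation, callers guarantee points in domain
.sample_uv <- function(grid, lon, lat, yearday) {
  nlon <- length(grid$lon); nlat <- length(grid$lat)
  fi <- (lon - grid$lon[1]) / grid$dlon
  fj <- (lat - grid$lat[1]) / grid$dlat
  i0 <- pmin(pmax(floor(fi), 0), nlon - 2)
  j0 <- pmin(pmax(floor(fj), 0), nlat - 2)
  wx <- fi - i0
  wy <- fj - j0
  i0 <- as.integer(i0); j0 <- as.integer(j0)
  if (grid$nt == 1L) {
    s0 <- 1L; s1 <- 1L; wt <- 0
  } else {
    t <- yearday %% 365
    d0 <- floor(t)
    wt <- t - d0
    s0 <- as.integer(d0) + 1L
    s1 <- (as.integer(d0) + 1L) %% 365L + 1L
  }
  base00 <- i0 + 1L + j0 * nlon
  plane <- nlon * nlat
  bl <- function(f, s) {
    off <- (s - 1L) * plane
    (1 - wx) * (1 - wy) * f[base00 + off] +
      wx * (1 - wy) * f[base00 + 1L + off] +
      (1 - wx) * wy * f[base00 + nlon + off] +
      wx * wy * f[base00 + nlon + 1L + off]
  }
  if (grid$nt == 1L || all(wt == 0)) {
    list(u = bl(grid$u, s0), v = bl(grid$v, s0))
  } else {
    list(u = (1 - wt) * bl(grid$u, s0) + wt * bl(grid$u, s1),
         v = (1 - wt) * bl(grid$v, s0) + wt * bl(grid$v, s1))
  }
}

#' Write / read a velocity grid as long-format CSV
#'
#' Plain-text interchange format: one row per (lon, lat, yearday) cell with
#' u, v, land flag and observation count. Intended for small grids;
#' synthetic grids are normally regenerated from code.
#'
#' @param grid A `velocity_grid`.
#' @param path File path.
#' @return `read_velocity_grid_csv` returns a `velocity_grid`;
#'   `write_velocity_grid_csv` returns `path` invisibly.
#' @export
write_velocity_grid_csv <- function(grid, path) {
  nt <- grid$nt
  df <- data.frame(
    lon = rep(grid$lon, times = length(grid$lat) * nt),
    lat = rep(rep(grid$lat, each = length(grid$lon)), times = nt),
    yearday = rep(seq_len(nt) - 1L, each = length(grid$lon) * length(grid$lat)),
    u = as.vector(grid$u), v = as.vector(grid$v),
    land = rep(as.integer(grid$land), times = nt),
    n_obs = if (is.null(grid$n_obs)) NA_integer_ else as.vector(grid$n_obs)
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_velocity_grid_csv
#' @export
read_velocity_grid_csv <- function(path) {
  df <- utils::read.csv(path)
  lon <- sort(unique(df$lon)); lat <- sort(unique(df$lat))
  nt <- length(unique(df$yearday))
  ord <- order(df$yearday, match(df$lat, lat), match(df$lon, lon))
  df <- df[ord, ]
  dims <- c(length(lon), length(lat), nt)
  land <- matrix(df$land[seq_len(prod(dims[1:2]))] > 0, dims[1], dims[2])
  n_obs <- if (all(is.na(df$n_obs))) NULL else array(df$n_obs, dims)
  velocity_grid(lon, lat, array(df$u, dims), array(df$v, dims),
                land = land, n_obs = n_obs)
}
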