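# drifter-fix gridding into a year-day velocity climatology

#' Build a year-day velocity climatology from drifter fixes
#'
#' Cell-mean binning: each grid cell / year-day holds the mean of all fix
#' velocities that fall in the cell within a circular +/- `temporal_window`
#' year-days of that day. Cells left empty after binning are filled by
#' iterative nearest-neighbour averaging up to `fill_radius` cells; cells
#' still empty are set to zero velocity. The per-cell observation count is
#' recorded in `n_obs` (filled/zero cells count 0).
#'
#' @param fixes A `drifter_fixes` data frame (see [read_drifter_csv()]).
#' @param resolution Grid resolution (degrees, > 0).
#' @param temporal_window Half-width of the circular year-day window (days).
#' @param drogue_only If `TRUE`, use only drogue-on fixes.
#' @param lon_range,lat_range Optional domain bounds; default snaps to the
#'   fix extent.
#' @param land Optional logical land-mask matrix for the output grid.
#' @param fill_radius Maximum nearest-neighbour fill distance (cells).
#' @return A `velocity_grid` with `n_obs` set.
#' @export
build_climatology <- function(fixes, resolution, temporal_window = 7,
                              drogue_only = FALSE,
                              lon_range = NULL, lat_range = NULL,
                              land = NULL, fill_radius = 3) {
  stopifnot(resolution > 0, nrow(fixes) > 0, temporal_window >= 0)
  if (drogue_only) fixes <- fixes[fixes$drogue, , drop = FALSE]
  if (nrow(fixes) == 0) stop("no fixes left after drogue filtering")

  lon_range <- lon_range %||%
    (c(floor(min(fixes$lon) / resolution), ceiling(max(fixes$lon) / resolution)) * resolution)
  lat_range <- lat_range %||%
    (c(floor(min(fixes$lat) / resolution), ceiling(max(fixes$lat) / resolution)) * resolution)
  lon <- seq(lon_range[1] + resolution / 2, lon_range[2], by = resolution)
  lat <- seq(lat_range[1] + resolution / 2, lat_range[2], by = resolution)
  nlon <- length(lon); nlat <- length(lat)

  ii <- floor((fixes$lon - lon_range[1]) / resolution) + 1L
  jj <- floor((fixes$lat - lat_range[1]) / resolution) + 1L
  keep <- ii >= 1 & ii <= nlon & jj >= 1 & jj <= nlat
  if (!any(keep)) stop("all fixes fall outside the grid domain")
  ii <- ii[keep]; jj <- jj[keep]
  u <- fixes$u[keep]; v <- fixes$v[keep]
  yd <- as.integer(fixes$day[keep]) - 1L          # 0-based
  cell <- ii + (jj - 1L) * nlon

  offs <- -temporal_window:temporal_window
  nfix <- length(cell)
  big_cell <- rep(cell, times = length(offs))
  big_day <- (rep(yd, times = length(offs)) +
                rep(offs, each = nfix)) %% 365L
  id <- big_cell + as.numeric(big_day) * (nlon * nlat)

  su <- rowsum(rep(u, length(offs)), id)
  sv <- rowsum(rep(v, length(offs)), id)
  cnt <- rowsum(rep(1, length(id)), id)
  ids <- as.numeric(rownames(su))

  dims <- c(nlon, nlat, 365L)
  u_arr <- array(NA_real_, dims)
  v_arr <- array(NA_real_, dims)
  n_arr <- array(0L, dims)
  day_idx <- floor((ids - 1) / (nlon * nlat))
  cell_idx <- ids - day_idx * (nlon * nlat)
  lin <- cell_idx + day_idx * (nlon * nlat)
  u_arr[lin] <- su / cnt
  v_arr[lin] <- sv / cnt
  n_arr[lin] <- as.integer(cnt)

  if (is.null(land)) land <- matrix(FALSE, nlon, nlat)
  land_arr <- array(rep(land, 365L), dims)
  u_arr[land_arr] <- 0; v_arr[land_arr] <- 0

  # nearest-neighbour fill: up to fill_radius dilation passes over the
  # 8-neighbourhood; only genuinely empty ocean cells are filled
  for (pass in seq_len(fill_radius)) {
    empty <- is.na(u_arr)
    if (!any(empty)) break
    acc_u <- array(0, dims); acc_v <- array(0, dims); acc_n <- array(0, dims)
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      sh_u <- shift2d(u_arr, di, dj)
      sh_v <- shift2d(v_arr, di, dj)
      has <- !is.na(sh_u)
      acc_u[has] <- acc_u[has] + sh_u[has]
      acc_v[has] <- acc_v[has] + sh_v[has]
      acc_n <- acc_n + has
    }
    fill <- empty & acc_n > 0 & !land_arr
    u_arr[fill] <- acc_u[fill] / acc_n[fill]
    v_arr[fill] <- acc_v[fill] / acc_n[fill]
  }
  still <- is.na(u_arr)
  u_arr[still] <- 0; v_arr[still] <- 0

  velocity_grid(lon, lat, u_arr, v_arr, land = land, n_obs = n_arr)
}

# shift a [lon, lat, t] array by (di, dj) cells with NA padding
shift2d <- function(a, di, dj) {
  d <- dim(a)
  out <- array(NA_real_, d)
  si <- seq_len(d[1]); sj <- seq_len(d[2])
  from_i <- si - di; from_j <- sj - dj
  ok_i <- from_i >= 1 & from_i <= d[1]
  ok_j <- from_j >= 1 & from_j <= d[2]
  out[si[ok_i], sj[ok_j], ] <- a[from_i[ok_i], from_j[ok_j], , drop = FALSE]
  out
}
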