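# shared constants and small helpers

# Earth radius convention used throughout the tracker (km)
EARTH_RADIUS_KM <- 6371
# metres per degree of latitude under that convention
M_PER_DEG <- EARTH_RADIUS_KM * 1000 * pi / 180

#' Great-circle distance between points (km)
#'
#' Haversine distance on a sphere of radius 6371 km, the convention used by
#' the particle tracker for cumulative track lengths.
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees (vectorized).
#' @return Numeric vector of distances in kilometres.
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = EARTH_RADIUS_KM * 1000) / 1000
}

#' Convert dates to 0-based year-days on a 365-day year
#'
#' Leap days are stripped so every date maps into 0..364: in leap years
#' Feb 29 maps to the year-day of Mar 1 and all later days shift back by one.
#'
#' @param date A `Date` vector (or something coercible).
#' @return Integer vector of year-days in 0..364.
#' @export
date_to_yearday <- function(date) {
  date <- as.Date(date)
  yd <- as.integer(strftime(date, "%j"))
  yr <- as.integer(strftime(date, "%Y"))
  leap <- (yr %% 4 == 0 & yr %% 100 != 0) | yr %% 400 == 0
  yd <- ifelse(leap & yd > 60L, yd - 1L, yd)
  as.integer(pmin(yd, 365L) - 1L)
}

#' Derive a reproducible sub-seed from a master seed and a key
#'
#' Stable string hash (polynomial rolling hash mod 2^31 - 1) combined with
#' the master seed, so per-simulation seeds do not depend on evaluation
#' order.
#'
#' @param seed Master integer seed.
#' @param key Character scalar (e.g. a date string).
#' @return Integer seed in 0 .. 2^31-2.
#' @export
derive_seed <- function(seed, key) {
  m <- 2147483647
  h <- 0
  for (c in utf8ToInt(as.character(key))) h <- (h * 31 + c) %% m
  as.integer((h + (as.numeric(seed) %% m) * 2654435) %% m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# circular difference of year-days, result in [-182.5, 182.5]
yearday_diff <- function(a, b) {
  d <- (a - b) %% 365
  ifelse(d > 365 / 2, d - 365, d)
}
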