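#' Solar geometry (NOAA equations)
#'
#' Sunrise, solar noon and sunset in UTC for a date and position, computed
#' from the NOAA low-precision solar equations (fractional-year Fourier
#' expansions of the equation of time and solar declination, sunrise/sunset
#' at a zenith of 90.833 degrees to account for refraction and the solar
#' disc). Accuracy is a few minutes, ample for windowing dives by daylight
#' and extracting the midday (solar noon +/- 1 h) light window.
#'
#' @param date a `Date` (or something coercible to one).
#' @param lat latitude, degrees north. Must satisfy `abs(lat) < 66`: polar
#'   day/night is outside the supported domain.
#' @param lon longitude, degrees east (0-360 or -180..180 accepted).
#' @return a list with POSIXct (UTC) elements `sunrise`, `solar_noon`,
#'   `sunset`.
#' @examples
#' ev <- solar_events(as.Date("2004-03-20"), lat = 0, lon = 0)
#' format(ev$solar_noon, "%H:%M")
#' @export
solar_events <- function(date, lat, lon) {
  date <- as.Date(date)
  stopifnot(length(date) == 1L, length(lat) == 1L, length(lon) == 1L)
  if (!is.finite(lat) || abs(lat) >= 66)
    stop("latitude ", lat, " outside supported range (|lat| < 66 deg)")
  lon <- normalize_lon180(lon)
  doy <- as.integer(format(date, "%j"))
  sc <- .solar_coeffs(doy, hour = 12)
  phi <- lat * pi / 180
  # hour angle at sunrise/sunset, zenith 90.833 deg
  cos_ha <- cos(90.833 * pi / 180) / (cos(phi) * cos(sc$decl)) -
    tan(phi) * tan(sc$decl)
  if (!is.finite(cos_ha) || abs(cos_ha) > 1)
    stop("no sunrise/sunset at lat ", lat, " on ", format(date),
         " (polar day or night)")
  ha_deg <- acos(cos_ha) * 180 / pi
  # minutes are deliberately NOT wrapped into [0, 1440): for far-west
  # longitudes the local day spans UTC midnight, and sunrise < noon <
  # sunset must hold as instants. `date` is the LOCAL solar date.
  noon_min <- 720 - 4 * lon - sc$eqtime
  sunrise_min <- noon_min - 4 * ha_deg
  sunset_min <- noon_min + 4 * ha_deg
  day0 <- as.POSIXct(paste0(format(date), " 00:00:00"), tz = "UTC")
  ev <- day0 + 60 * c(sunrise_min, noon_min, sunset_min)
  list(sunrise = ev[1L], solar_noon = ev[2L], sunset = ev[3L])
}

#' Local solar date of a UTC instant
#'
#' The calendar date at the local mean solar time (`UTC + lon/15` hours).
#' All per-day grouping in the pipeline (daily MLD, dive dates, midday
#' windows, daily positions) uses the local solar date, so a local day is
#' never split across a UTC midnight.
#'
#' @param time POSIXct UTC (vectorized).
#' @param lon longitude, deg E.
#' @return a `Date` vector.
#' @export
solar_date <- function(time, lon) {
  as.Date(format(time + normalize_lon180(lon) / 15 * 3600,
                 "%Y-%m-%d", tz = "UTC"))
}

#' Solar elevation angle
#'
#' @param time POSIXct (UTC), vectorized.
#' @param lat,lon position in degrees (north / east).
#' @return elevation above the horizon in degrees (negative at night).
#' @export
solar_elevation <- function(time, lat, lon) {
  lon <- normalize_lon180(lon)
  doy <- as.integer(format(time, "%j", tz = "UTC"))
  hr <- as.numeric(format(time, "%H", tz = "UTC")) +
    as.numeric(format(time, "%M", tz = "UTC")) / 60 +
    as.numeric(format(time, "%S", tz = "UTC")) / 3600
  sc <- .solar_coeffs(doy, hr)
  tst <- (hr * 60 + sc$eqtime + 4 * lon) %% 1440
  ha <- (tst / 4 - 180) * pi / 180
  phi <- lat * pi / 180
  cos_zen <- sin(phi) * sin(sc$decl) + cos(phi) * cos(sc$decl) * cos(ha)
  90 - acos(pmin(1, pmax(-1, cos_zen))) * 180 / pi
}

# NOAA fractional-year expansion: equation of time (minutes) and solar
# declination (radians).
.solar_coeffs <- function(doy, hour) {
  g <- 2 * pi / 365 * (doy - 1 + (hour - 12) / 24)
  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
    0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  list(eqtime = eqtime, decl = decl)
}

#' @keywords internal
normalize_lon180 <- function(lon) {
  lon <- lon %% 360
  ifelse(lon > 180, lon - 360, lon)
}

#' @keywords internal
normalize_lon360 <- function(lon) lon %% 360

#' Local solar hour-of-day from a UTC time and longitude
#'
#' Longitude-only conversion (`UTC + lon/15`), the convention used for diel
#' compositing and for the diel schedule of migrating scattering layers.
#'
#' @inheritParams solar_elevation
#' @return fractional hour in [0, 24).
#' @export
local_solar_hour <- function(time, lon) {
  hr <- as.numeric(format(time, "%H", tz = "UTC")) +
    as.numeric(format(time, "%M", tz = "UTC")) / 60 +
    as.numeric(format(time, "%S", tz = "UTC")) / 3600
  (hr + normalize_lon180(lon) / 15) %% 24
}
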