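#' Construct an ocean scenario (synthetic ground truth)
#'
#' An `ocean_scenario` is the stated physical world against which the whole
#' pipeline is tested: a two-layer temperature profile with a tanh
#' thermocline, a diel half-sine surface log-irradiance cycle driven by NOAA
#' solar geometry at the scenario position, and a diffuse attenuation field
#' K(z, t) that is the sum of a constant background, an optional deep
#' chlorophyll maximum (DCM) Gaussian, and scattering-layer Gaussians whose
#' centers may migrate between a midnight (shallow) and noon (deep) depth.
#'
#' @param surface_temp,deep_temp mixed-layer and abyssal temperature, deg C
#'   (`surface_temp >= deep_temp`).
#' @param mld true mixed layer depth, m (thermocline center).
#' @param thermocline_width tanh half-width of the thermocline, m.
#' @param latitude,longitude scenario position (deg N, deg E).
#' @param k0 background diffuse attenuation coefficient, m^-1 (> 0).
#' @param components list of [attenuation_component()] objects (DCM and
#'   scattering layers).
#' @param surface_light_max peak ln-irradiance at local solar noon
#'   (arbitrary ln units above the sensor floor).
#' @param light_floor sensor floor, ln units (night / full-dark reading).
#' @return an object of class `ocean_scenario`.
#' @examples
#' sc <- build_scenario(k0 = 0.041, mld = 29, surface_temp = 15.5,
#'                      deep_temp = 7.4, latitude = 45, longitude = 230)
#' scenario_attenuation(sc, depth = c(0, 100, 300), hour = 12)
#' @export
build_scenario <- function(surface_temp = 16, deep_temp = 8,
                           mld = 40, thermocline_width = 15,
                           latitude = 35, longitude = 215,
                           k0 = 0.04, components = list(),
                           surface_light_max = 18, light_floor = 0) {
  if (!is.finite(k0) || k0 <= 0) stop("invalid parameter 'k0': must be > 0")
  if (!is.finite(mld) || mld <= 0) stop("invalid parameter 'mld': must be > 0")
  if (!is.finite(thermocline_width) || thermocline_width <= 0)
    stop("invalid parameter 'thermocline_width': must be > 0")
  if (surface_temp < deep_temp)
    stop("invalid parameter 'surface_temp': must be >= deep_temp")
  if (abs(latitude) >= 66)
    stop("invalid parameter 'latitude': |lat| must be < 66")
  if (surface_light_max <= light_floor)
    stop("invalid parameter 'surface_light_max': must exceed light_floor")
  components <- lapply(components, function(cmp) {
    if (!inherits(cmp, "attenuation_component"))
      stop("invalid parameter 'components': use attenuation_component()")
    cmp
  })
  structure(list(
    surface_temp = surface_temp, deep_temp = deep_temp, mld = mld,
    thermocline_width = thermocline_width, latitude = latitude,
    longitude = normalize_lon360(longitude), k0 = k0,
    components = components, surface_light_max = surface_light_max,
    light_floor = light_floor
  ), class = "ocean_scenario")
}

#' Attenuation field component (DCM or scattering layer)
#'
#' A Gaussian-in-depth addition to the background attenuation. Scattering
#' layers may be migrant: their center depth follows a sinusoid over the
#' local diel cycle, shallowest (`midnight_depth`) at local midnight and
#' deepest (`noon_depth`) at local noon.
#'
#' @param kind `"dcm"` or `"scattering_layer"`.
#' @param peak_k added attenuation at the component center, m^-1 (> 0).
#' @param width Gaussian standard deviation, m (> 0).
#' @param center_depth fixed center depth, m (non-migrant components).
#' @param noon_depth,midnight_depth diel extremes of the center depth, m,
#'   with `noon_depth >= midnight_depth` (daytime is deeper). If supplied the
#'   component is migrant and `center_depth` is ignored.
#' @return an `attenuation_component` object.
#' @export
attenuation_component <- function(kind = c("dcm", "scattering_layer"),
                                  peak_k, width, center_depth = NULL,
                                  noon_depth = NULL, midnight_depth = NULL) {
  kind <- match.arg(kind)
  if (!is.finite(peak_k) || peak_k <= 0)
    stop("invalid parameter 'peak_k': must be > 0")
  if (!is.finite(width) || width <= 0)
    stop("invalid parameter 'width': must be > 0")
  migrant <- !is.null(noon_depth) || !is.null(midnight_depth)
  if (migrant) {
    if (is.null(noon_depth) || is.null(midnight_depth))
      stop("invalid parameter 'noon_depth'/'midnight_depth': both required")
    if (noon_depth < midnight_depth)
      stop("invalid parameter 'noon_depth': must be >= midnight_depth")
  } else if (is.null(center_depth)) {
    stop("invalid parameter 'center_depth': required for non-migrant components")
  }
  structure(list(kind = kind, peak_k = peak_k, width = width,
                 center_depth = center_depth, migrant = migrant,
                 noon_depth = noon_depth, midnight_depth = midnight_depth),
            class = "attenuation_component")
}

#' Center depth of an attenuation component at a local solar hour
#'
#' Migrant layers interpolate sinusoidally: `midnight_depth` at hour 0,
#' `noon_depth` at hour 12.
#'
#' @param component an [attenuation_component()].
#' @param hour local solar hour in [0, 24), vectorized.
#' @return center depth in m.
#' @export
component_center <- function(component, hour) {
  if (!component$migrant) return(rep(component$center_depth, length(hour)))
  component$midnight_depth +
    (component$noon_depth - component$midnight_depth) *
      (1 - cos(2 * pi * hour / 24)) / 2
}

#' Evaluate the scenario attenuation field K(z, t)
#'
#' @param scenario an `ocean_scenario`.
#' @param depth depth in m (vectorized).
#' @param hour local solar hour (scalar).
#' @return diffuse attenuation, m^-1.
#' @export
scenario_attenuation <- function(scenario, depth, hour = 12) {
  k <- rep(scenario$k0, length(depth))
  for (cmp in scenario$components) {
    ctr <- component_center(cmp, hour)
    k <- k + cmp$peak_k * exp(-(depth - ctr)^2 / (2 * cmp$width^2))
  }
  k
}

#' Optical depth: the attenuation field integrated from the surface
#'
#' Closed-form integral of K(z, t) from 0 to `depth` (Gaussian components
#' integrate to scaled normal CDFs), used to propagate surface irradiance to
#' depth via Beer-Lambert decay.
#'
#' @inheritParams scenario_attenuation
#' @return dimensionless optical depth (ln-units of attenuation).
#' @export
scenario_optical_depth <- function(scenario, depth, hour = 12) {
  od <- scenario$k0 * depth
  for (cmp in scenario$components) {
    ctr <- component_center(cmp, hour)
    od <- od + cmp$peak_k * cmp$width * sqrt(2 * pi) *
      (stats::pnorm((depth - ctr) / cmp$width) - stats::pnorm(-ctr / cmp$width))
  }
  od
}

#' Scenario temperature profile
#'
#' Two-layer tanh thermocline: `deep_temp + (surface_temp - deep_temp) *
#' (1 - tanh((z - mld)/w)) / 2`. Monotonically non-increasing with depth and
#' bounded by `[deep_temp, surface_temp]`.
#'
#' @param scenario an `ocean_scenario`.
#' @param depth depth in m (vectorized).
#' @return temperature, deg C.
#' @export
scenario_temperature <- function(scenario, depth) {
  scenario$deep_temp + (scenario$surface_temp - scenario$deep_temp) *
    (1 - tanh((depth - scenario$mld) / scenario$thermocline_width)) / 2
}

#' Surface ln-irradiance at a UTC time
#'
#' Diel half-sine between sunrise and sunset (NOAA solar events at the
#' scenario position); the sensor floor at night.
#'
#' @param scenario an `ocean_scenario`.
#' @param time POSIXct UTC (vectorized within one date).
#' @return ln-irradiance, arbitrary units.
#' @export
scenario_surface_light <- function(scenario, time) {
  dates <- solar_date(time, scenario$longitude)
  out <- rep(scenario$light_floor, length(time))
  for (d in unique(dates)) {
    idx <- which(dates == d)
    ev <- solar_events(as.Date(d, origin = "1970-01-01"),
                       scenario$latitude, scenario$longitude)
    frac <- as.numeric(difftime(time[idx], ev$sunrise, units = "secs")) /
      as.numeric(difftime(ev$sunset, ev$sunrise, units = "secs"))
    day <- frac > 0 & frac < 1
    out[idx[day]] <- scenario$light_floor +
      (scenario$surface_light_max - scenario$light_floor) * sin(pi * frac[day])
  }
  out
}

#' Noiseless tag light model: ln-irradiance at depth and time
#'
#' Beer-Lambert: surface ln-irradiance minus optical depth at the local
#' solar hour, clamped at the sensor floor.
#'
#' @param scenario an `ocean_scenario`.
#' @param depth depth, m (vectorized; recycled against `time`).
#' @param time POSIXct UTC.
#' @return ln-irradiance.
#' @export
scenario_light <- function(scenario, depth, time) {
  surf <- scenario_surface_light(scenario, time)
  hr <- local_solar_hour(time, scenario$longitude)
  od <- scenario$k0 * depth
  for (cmp in scenario$components) {
    ctr <- component_center(cmp, hr)
    od <- od + cmp$peak_k * cmp$width * sqrt(2 * pi) *
      (stats::pnorm((depth - ctr) / cmp$width) - stats::pnorm(-ctr / cmp$width))
  }
  pmax(surf - od, scenario$light_floor)
}

#' @export
print.ocean_scenario <- function(x, ...) {
  cat("<ocean_scenario>\n")
  cat(sprintf("  position: %.1f N, %.1f E\n", x$latitude, x$longitude))
  cat(sprintf("  temperature: %.1f -> %.1f C, MLD %.0f m (width %.0f m)\n",
              x$surface_temp, x$deep_temp, x$mld, x$thermocline_width))
  cat(sprintf("  background k0: %.3f m^-1; %d component(s)\n",
              x$k0, length(x$components)))
  invisible(x)
}
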