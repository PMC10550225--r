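#' Behavior configuration for the tag simulator
#'
#' Describes how the simulated fish uses the water column: daytime U-shaped
#' (sustained foraging: descend, hold a bottom phase at a target layer,
#' ascend) and V-shaped (prey searching: descend and immediately ascend)
#' dives below the mixed layer, with mixed-layer occupation in between, and
#' sensor noise. Dives are scheduled only between sunrise and sunset.
#'
#' `dives_per_day` are deterministic integer counts (not Poisson draws):
#' recoverability of the schedule by the dive-extraction stage is part of
#' what the simulator is for.
#'
#' @param n_days number of simulated days.
#' @param dives_per_day named vector `c(U = , V = )` of daily dive counts.
#' @param u_target_layer index into the scenario's `components` of the
#'   scattering layer U dives target, or `NULL` to use `u_target_depth`.
#' @param u_target_depth `c(mean, sd)` fallback U-dive target depth, m.
#' @param u_bottom_duration_min `c(mean, sd)` U-dive bottom duration, min.
#' @param v_apex_depth `c(mean, sd)` V-dive apex depth, m.
#' @param descent_rate,ascent_rate `c(mean, sd)` vertical rates, m s^-1.
#' @param surface_depth `c(mean, sd)` inter-dive mixed-layer depth, m.
#' @param sampling_interval_s tag sampling interval, 30 or 60 s.
#' @param noise named vector `c(depth_sd = , temp_sd = , light_sd = )`
#'   additive Gaussian sensor noise (m, deg C, ln-units).
#' @param seed integer seed; identical config + seed gives bit-identical
#'   output.
#' @return a `behavior_config` object.
#' @export
behavior_config <- function(n_days = 5,
                            dives_per_day = c(U = 6, V = 8),
                            u_target_layer = NULL,
                            u_target_depth = c(250, 10),
                            u_bottom_duration_min = c(12, 3),
                            v_apex_depth = c(200, 20),
                            descent_rate = c(0.85, 0.08),
                            ascent_rate = c(0.85, 0.08),
                            surface_depth = c(5, 2),
                            sampling_interval_s = 30,
                            noise = c(depth_sd = 0.5, temp_sd = 0.1,
                                      light_sd = 0.02),
                            seed = 1L) {
  if (!sampling_interval_s %in% c(30, 60))
    stop("invalid parameter 'sampling_interval_s': must be 30 or 60")
  if (descent_rate[1] <= 0 || ascent_rate[1] <= 0)
    stop("invalid parameter 'descent_rate'/'ascent_rate': must be > 0")
  if (any(dives_per_day < 0) ||
      !all(c("U", "V") %in% names(dives_per_day)))
    stop("invalid parameter 'dives_per_day': need non-negative U and V counts")
  noise <- noise[c("depth_sd", "temp_sd", "light_sd")]
  if (anyNA(noise) || any(noise < 0))
    stop("invalid parameter 'noise': need non-negative depth_sd, temp_sd, light_sd")
  structure(list(
    n_days = as.integer(n_days), dives_per_day = dives_per_day,
    u_target_layer = u_target_layer, u_target_depth = u_target_depth,
    u_bottom_duration_min = u_bottom_duration_min,
    v_apex_depth = v_apex_depth, descent_rate = descent_rate,
    ascent_rate = ascent_rate, surface_depth = surface_depth,
    sampling_interval_s = sampling_interval_s, noise = noise,
    seed = as.integer(seed)
  ), class = "behavior_config")
}

#' Simulate an archival tag record
#'
#' Generates a `tag_series`: depth, ambient temperature and ln-irradiance at
#' the configured sampling interval, plus daily positions, with the
#' ground-truth dive schedule attached (`$schedule`) so downstream stages
#' can be scored against what was actually simulated.
#'
#' A dive that cannot complete before sunset is truncated at sunset and
#' flagged in the schedule (`truncated = TRUE`), never silently dropped.
#'
#' @param scenario an [build_scenario()] `ocean_scenario`.
#' @param behavior a [behavior_config()].
#' @param start_date first simulated date.
#' @param fish_length fish fork length, m (for body-lengths-per-second
#'   swimming speeds downstream).
#' @param drift `c(dlat, dlon)` degrees of linear position drift per day.
#' @return a `tag_series` object: list with `records` (data.frame:
#'   `timestamp`, `depth_m`, `temp_c`, `light`), `positions` (`date`, `lat`,
#'   `lon`), `fish_length`, `interval_s`, `light_channel` (`"log"`), and
#'   `schedule` (the ground truth).
#' @export
simulate_tag_series <- function(scenario, behavior,
                                start_date = as.Date("2004-06-15"),
                                fish_length = 0.8, drift = c(0, 0)) {
  stopifnot(inherits(scenario, "ocean_scenario"),
            inherits(behavior, "behavior_config"))
  set.seed(behavior$seed)
  dt <- behavior$sampling_interval_s
  start_date <- as.Date(start_date)
  n <- behavior$n_days * 86400L %/% dt
  # grid starts at LOCAL solar midnight so every simulated day contains its
  # full daylight period (local days are the pipeline's grouping unit)
  t0 <- as.POSIXct(paste(format(start_date), "00:00:00"), tz = "UTC") -
    round(normalize_lon180(scenario$longitude) / 15 * 3600)
  tgrid <- t0 + dt * (seq_len(n) - 1L)
  tsec <- as.numeric(tgrid) # absolute seconds for interval arithmetic

  dates <- start_date + seq_len(behavior$n_days) - 1L
  positions <- data.frame(
    date = dates,
    lat = scenario$latitude + drift[1] * (seq_along(dates) - 1L),
    lon = normalize_lon360(scenario$longitude + drift[2] *
                             (seq_along(dates) - 1L))
  )

  rpos <- function(m, s) max(m + s * stats::rnorm(1), m * 0.2, 1e-3)
  depth <- numeric(n)
  sched <- list()
  for (d in seq_len(behavior$n_days)) {
    ev <- solar_events(dates[d], positions$lat[d], positions$lon[d])
    sr <- as.numeric(ev$sunrise)
    ss <- as.numeric(ev$sunset)
    base_depth <- rpos(behavior$surface_depth[1], behavior$surface_depth[2])
    day_idx <- which(tsec >= as.numeric(t0) + (d - 1) * 86400 &
                       tsec < as.numeric(t0) + d * 86400)
    depth[day_idx] <- base_depth

    n_u <- as.integer(round(behavior$dives_per_day[["U"]]))
    n_v <- as.integer(round(behavior$dives_per_day[["V"]]))
    n_dives <- n_u + n_v
    if (n_dives == 0L) next
    # interleave U dives evenly among the slots
    # U (foraging) dives form a midday bout -- deep daytime foraging peaks
    # around local noon -- while V (searching) dives fill the remaining
    # daylight slots
    types <- rep("V", n_dives)
    if (n_u > 0L) {
      center <- (n_dives + 1) / 2
      types[order(abs(seq_len(n_dives) - center))[seq_len(n_u)]] <- "U"
    }
    win0 <- sr + 900
    slot <- (ss - win0) / n_dives
    prev_end <- -Inf
    for (i in seq_len(n_dives)) {
      rd <- rpos(behavior$descent_rate[1], behavior$descent_rate[2])
      ra <- rpos(behavior$ascent_rate[1], behavior$ascent_rate[2])
      if (types[i] == "U") {
        if (!is.null(behavior$u_target_layer)) {
          cmp <- scenario$components[[behavior$u_target_layer]]
          mid_hr <- local_solar_hour(
            as.POSIXct(win0 + (i - 0.5) * slot, origin = "1970-01-01",
                       tz = "UTC"), positions$lon[d])
          target <- component_center(cmp, mid_hr)
        } else {
          target <- rpos(behavior$u_target_depth[1], behavior$u_target_depth[2])
        }
        bott <- 60 * rpos(behavior$u_bottom_duration_min[1],
                          behavior$u_bottom_duration_min[2])
      } else {
        target <- rpos(behavior$v_apex_depth[1], behavior$v_apex_depth[2])
        bott <- 0
      }
      tdesc <- (target - base_depth) / rd
      tasc <- (target - base_depth) / ra
      # center the dive in its slot (a lone dive sits on local noon)
      t_start <- max(win0 + (i - 0.5) * slot - (tdesc + bott + tasc) / 2,
                     win0, prev_end + 120)
      t_end <- t_start + tdesc + bott + tasc
      truncated <- FALSE
      if (t_start >= ss) break
      if (t_end > ss) {
        t_end <- ss
        truncated <- TRUE
      }
      prev_end <- t_end
      idx <- which(tsec >= t_start & tsec <= t_end)
      if (length(idx) == 0L) next
      tt <- tsec[idx] - t_start
      z <- ifelse(tt <= tdesc, base_depth + rd * tt,
             ifelse(tt <= tdesc + bott,
                    target + 3 * sin(2 * pi * (tt - tdesc) / 300),
                    pmax(base_depth, target - ra * (tt - tdesc - bott))))
      depth[idx] <- z
      sched[[length(sched) + 1L]] <- data.frame(
        day = d, date = dates[d], type = types[i],
        t_start = as.POSIXct(t_start, origin = "1970-01-01", tz = "UTC"),
        t_end = as.POSIXct(t_end, origin = "1970-01-01", tz = "UTC"),
        target_depth = target, bottom_duration_min = bott / 60,
        descent_rate = rd, ascent_rate = ra, truncated = truncated
      )
    }
  }

  noise <- behavior$noise
  depth <- pmax(depth + stats::rnorm(n, 0, noise[["depth_sd"]]), 0)
  temp <- scenario_temperature(scenario, depth) +
    stats::rnorm(n, 0, noise[["temp_sd"]])
  light <- pmax(scenario_light(scenario, depth, tgrid) +
                  stats::rnorm(n, 0, noise[["light_sd"]]),
                scenario$light_floor)

  schedule <- if (length(sched)) do.call(rbind, sched) else
    data.frame(day = integer(), date = as.Date(character()),
               type = character(), t_start = as.POSIXct(character()),
               t_end = as.POSIXct(character()), target_depth = numeric(),
               bottom_duration_min = numeric(), descent_rate = numeric(),
               ascent_rate = numeric(), truncated = logical())
  schedule$dive <- seq_len(nrow(schedule))

  structure(list(
    records = data.frame(timestamp = tgrid, depth_m = depth,
                         temp_c = temp, light = light),
    positions = positions, fish_length = fish_length,
    interval_s = dt, light_channel = "log", schedule = schedule
  ), class = "tag_series")
}

#' @export
print.tag_series <- function(x, ...) {
  cat(sprintf("<tag_series> %d records at %d s over %d day(s), %d scheduled dive(s)\n",
              nrow(x$records), x$interval_s, nrow(x$positions),
              if (is.null(x$schedule)) NA_integer_ else nrow(x$schedule)))
  invisible(x)
}

#' Simulate gridded shipboard backscatter
#'
#' Volume backscatter profiles (dB) on an hour-of-day by depth grid:
#' Gaussian layers in depth whose centers follow each scattering-layer
#' component's diel schedule, over a constant noise floor, one profile per
#' simulated hour per day.
#'
#' @param scenario an `ocean_scenario`; its `scattering_layer` components
#'   define the layers.
#' @param n_days number of simulated cruise days.
#' @param seed integer seed.
#' @param depth_max,bin_width depth grid, m (must cover 0-600 m).
#' @param base_db noise-floor mean volume backscatter, dB.
#' @param layer_db added backscatter at a layer center, dB.
#' @param noise_db Gaussian noise SD, dB.
#' @return data.frame `timestamp` (UTC), `depth_m` (bin centers), `sv_db`,
#'   `lat`, `lon`.
#' @export
simulate_backscatter <- function(scenario, n_days = 3, seed = 1L,
                                 depth_max = 600, bin_width = 10,
                                 base_db = -85, layer_db = 15,
                                 noise_db = 1.5) {
  stopifnot(inherits(scenario, "ocean_scenario"))
  if (depth_max < 600) stop("depth grid must cover 0-600 m")
  set.seed(as.integer(seed))
  zc <- seq(bin_width / 2, depth_max - bin_width / 2, by = bin_width)
  layers <- Filter(function(c) c$kind == "scattering_layer",
                   scenario$components)
  t0 <- as.POSIXct("2004-06-15 00:00:00", tz = "UTC")
  out <- vector("list", n_days * 24L)
  i <- 0L
  for (d in seq_len(n_days)) for (h in 0:23) {
    ts <- t0 + ((d - 1) * 24 + h) * 3600
    lhr <- local_solar_hour(ts, scenario$longitude)
    sv <- rep(base_db, length(zc))
    for (ly in layers) {
      ctr <- component_center(ly, lhr)
      sv <- sv + layer_db * exp(-(zc - ctr)^2 / (2 * ly$width^2))
    }
    sv <- sv + stats::rnorm(length(zc), 0, noise_db)
    i <- i + 1L
    out[[i]] <- data.frame(timestamp = ts, depth_m = zc, sv_db = sv,
                           lat = scenario$latitude, lon = scenario$longitude)
  }
  do.call(rbind, out)
}
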