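# Shared scenario/behavior fixtures (the two-biome stated world) and
# brute-force oracles used by the module and acceptance tests.

# cold-at-depth coastal upwelling biome (California Current-like):
# shallow cold mixed layer, high attenuation, migrant layer at ~210 m noon
cold_scenario <- function(layer = TRUE) {
  comps <- list(attenuation_component("dcm", peak_k = 0.03, width = 15,
                                      center_depth = 70))
  if (layer)
    comps <- c(comps, list(attenuation_component(
      "scattering_layer", peak_k = 0.02, width = 30,
      noon_depth = 210, midnight_depth = 80)))
  build_scenario(surface_temp = 15.5, deep_temp = 7.4, mld = 29,
                 thermocline_width = 10, latitude = 45, longitude = 230,
                 k0 = 0.041, components = comps)
}

# warm-at-depth oligotrophic gyre biome: deep warm mixed layer, clear
# water, shallow scattering layer at ~250 m noon
warm_scenario <- function(layer = TRUE) {
  comps <- list(attenuation_component("dcm", peak_k = 0.02, width = 20,
                                      center_depth = 120))
  if (layer)
    comps <- c(comps, list(attenuation_component(
      "scattering_layer", peak_k = 0.02, width = 30,
      noon_depth = 250, midnight_depth = 120)))
  build_scenario(surface_temp = 17, deep_temp = 10.5, mld = 55,
                 thermocline_width = 40, latitude = 30, longitude = 210,
                 k0 = 0.035, components = comps)
}

cold_behavior <- function(seed, n_days = 1, ...) {
  behavior_config(n_days = n_days, dives_per_day = c(U = 6, V = 24),
                  u_target_layer = 2, v_apex_depth = c(200, 20),
                  descent_rate = c(1.0, 0.08), ascent_rate = c(1.0, 0.08),
                  seed = seed, ...)
}

warm_behavior <- function(seed, n_days = 1, layer = TRUE, ...) {
  behavior_config(n_days = n_days, dives_per_day = c(U = 6, V = 24),
                  u_target_layer = if (layer) 2 else NULL,
                  u_target_depth = c(250, 10),
                  v_apex_depth = c(200, 20),
                  descent_rate = c(0.7, 0.07), ascent_rate = c(0.7, 0.07),
                  seed = seed, ...)
}

# hand-built tag_series: timestamps centered on the local solar noon of
# `date` at (lat, lon), one record per `interval` seconds
make_series <- function(depth, temp = rep(10, length(depth)),
                        light = rep(5, length(depth)),
                        lat = 45, lon = 230,
                        date = as.Date("2004-06-15"), interval = 30,
                        fish_length = 0.8) {
  n <- length(depth)
  noon <- solar_events(date, lat, lon)$solar_noon
  ts <- noon + interval * (seq_len(n) - ceiling(n / 2))
  structure(list(
    records = data.frame(timestamp = ts, depth_m = depth, temp_c = temp,
                         light = light),
    positions = data.frame(date = date, lat = lat, lon = lon),
    fish_length = fish_length, interval_s = interval,
    light_channel = "log", schedule = NULL
  ), class = "tag_series")
}

# attenuation_profile object built directly from a k(z) table
make_profile <- function(depth_m, k_per_m, lat = 30, bin_width = 10,
                         dcm_cutoff = 165, qc_pass = NA) {
  structure(list(
    fish_id = "fx", date = as.Date("2004-06-15"), lat = lat, lon = 210,
    bin_width = bin_width,
    bins = data.frame(depth_m = depth_m, k_per_m = k_per_m,
                      n_obs = rep(5L, length(depth_m)),
                      gap_m = rep(bin_width, length(depth_m))),
    epipelagic_mean_k = mean(k_per_m[depth_m >= 20 & depth_m <= 150]),
    dcm_cutoff = dcm_cutoff,
    extends_below_cutoff = max(depth_m) >= dcm_cutoff,
    qc_pass = qc_pass, qc_fail = character(0)
  ), class = "attenuation_profile")
}

# match extracted dives to the simulator's ground-truth schedule by
# maximal time overlap; returns the scheduled type per dive (NA if none)
match_schedule <- function(dives, schedule) {
  vapply(seq_len(nrow(dives)), function(i) {
    ov <- pmin(as.numeric(dives$end_time[i]),
               as.numeric(schedule$t_end)) -
      pmax(as.numeric(dives$start_time[i]), as.numeric(schedule$t_start))
    if (all(ov <= 0)) NA_character_ else schedule$type[which.max(ov)]
  }, character(1))
}

## ---- brute-force oracles ----

# exhaustive scan segmentation: first/last sample at >= frac * max
oracle_segment <- function(depths, frac = 0.75) {
  thr <- frac * max(depths)
  bs <- NA_integer_; be <- NA_integer_
  for (i in seq_along(depths)) {
    if (depths[i] >= thr) {
      if (is.na(bs)) bs <- i
      be <- i
    }
  }
  c(bottom_start = bs, bottom_end = be)
}

# exhaustive run-length scan for threshold excursions
oracle_extract <- function(depths, thr) {
  runs <- list()
  inrun <- FALSE
  for (i in seq_along(depths)) {
    if (depths[i] > thr && !inrun) {
      s <- i; inrun <- TRUE
    }
    if (inrun && (depths[i] <= thr || i == length(depths))) {
      e <- if (depths[i] <= thr) i - 1L else i
      runs[[length(runs) + 1L]] <- c(start = s, end = e)
      inrun <- FALSE
    }
  }
  runs
}

# naive double-loop IDW with great-circle distances
oracle_idw <- function(samples, grid, power = 2) {
  out <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    num <- 0; den <- 0; exact <- NA
    for (j in seq_len(nrow(samples))) {
      d <- great_circle_km(grid$lat[i], grid$lon[i],
                           samples$lat[j], samples$lon[j])
      if (d == 0) { exact <- samples$value[j]; break }
      w <- d^(-power)
      num <- num + w * samples$value[j]
      den <- den + w
    }
    out[i] <- if (!is.na(exact)) exact else num / den
  }
  out
}

# naive group-by mean over (local hour, depth bin)
oracle_composite <- function(profiles, bin_width) {
  hour <- round(local_solar_hour(profiles$timestamp, profiles$lon)) %% 24
  zb <- floor(profiles$depth_m / bin_width) * bin_width + bin_width / 2
  keys <- unique(data.frame(hour = hour, depth_m = zb))
  keys$mean_sv <- NA_real_
  for (i in seq_len(nrow(keys))) {
    sel <- hour == keys$hour[i] & zb == keys$depth_m[i]
    keys$mean_sv[i] <- mean(profiles$sv_db[sel])
  }
  keys
}

# sort-based type-7 quantile
oracle_quantile7 <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
}

# bisection solve of the cost-equivalent bottom duration on the
# travel-cost integrator (independent of the closed form)
oracle_bisect_bottom <- function(observed_cost, hyp_travel,
                                 hyp_rate_per_min, hi = 1e4) {
  f <- function(b) hyp_travel + hyp_rate_per_min * b - observed_cost
  if (f(0) > 0) return(NA_real_)
  lo <- 0
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}
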