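#' Local solar dates of a series' records
#'
#' Per-day grouping uses the local solar date at the track's median
#' longitude, so a day's daylight is never split across UTC midnight.
#'
#' @param series a `tag_series`.
#' @return `Date` vector, one element per record.
#' @export
series_dates <- function(series) {
  solar_date(series$records$timestamp, stats::median(series$positions$lon))
}

#' Estimate mixed layer depth from one day of tag records
#'
#' Temperature-threshold method on the tag's own vertical excursions: depths
#' are binned (default 5 m), a median temperature is computed per bin, and
#' the MLD is the shallowest bin center at which the binned temperature
#' falls more than `delta_t_threshold` below the 0-10 m reference
#' temperature. If no bin qualifies (e.g. an isothermal day) the deepest
#' binned depth is returned with `method_tag = "no-crossing"`.
#'
#' @param day_records data.frame with `depth_m` and `temp_c` for one day.
#' @param delta_t_threshold temperature offset from the surface reference,
#'   deg C.
#' @param bin_width depth bin width, m.
#' @param ref_depth upper reference layer bound, m (reference temperature is
#'   the median over 0-`ref_depth` m).
#' @param min_samples,min_span_m data floor: at least `min_samples` records
#'   spanning at least `min_span_m` of depth.
#' @return list with `mld` (m), `method_tag` (`"threshold"` or
#'   `"no-crossing"`), `n_samples_used`.
#' @export
estimate_mld <- function(day_records, delta_t_threshold = 0.5,
                         bin_width = 5, ref_depth = 10,
                         min_samples = 20, min_span_m = 30) {
  z <- day_records$depth_m
  tmp <- day_records$temp_c
  ok <- is.finite(z) & is.finite(tmp)
  z <- z[ok]; tmp <- tmp[ok]
  if (length(z) < min_samples || diff(range(z)) < min_span_m)
    stop("insufficient data for MLD estimation: need >= ", min_samples,
         " samples spanning >= ", min_span_m, " m")
  bin <- floor(z / bin_width)
  med <- tapply(tmp, bin, stats::median)
  centers <- (as.numeric(names(med)) + 0.5) * bin_width
  ord <- order(centers)
  med <- med[ord]; centers <- centers[ord]
  ref <- stats::median(tmp[z <= ref_depth])
  if (!is.finite(ref)) ref <- med[1L] # no near-surface samples: use shallowest bin
  hit <- which(med < ref - delta_t_threshold)
  if (length(hit) == 0L) {
    list(mld = centers[length(centers)], method_tag = "no-crossing",
         n_samples_used = length(z))
  } else {
    list(mld = centers[min(hit)], method_tag = "threshold",
         n_samples_used = length(z))
  }
}

#' Daily mixed layer depth estimates for a tag series
#'
#' Applies [estimate_mld()] per calendar date; days failing the data floor
#' are dropped with a warning.
#'
#' @param series a `tag_series`.
#' @inheritParams estimate_mld
#' @return data.frame `date`, `mld`, `method_tag`, `n_samples_used`.
#' @export
estimate_mld_daily <- function(series, delta_t_threshold = 0.5,
                               bin_width = 5, ref_depth = 10,
                               min_samples = 20, min_span_m = 30) {
  recs <- series$records
  dates <- series_dates(series)
  out <- lapply(unique(dates), function(d) {
    est <- tryCatch(
      estimate_mld(recs[dates == d, , drop = FALSE], delta_t_threshold,
                   bin_width, ref_depth, min_samples, min_span_m),
      error = function(e) {
        warning("skipping ", format(d), ": ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
    if (is.null(est)) return(NULL)
    data.frame(date = d, mld = est$mld, method_tag = est$method_tag,
               n_samples_used = est$n_samples_used)
  })
  do.call(rbind, out)
}

#' Extract candidate dives from a tag series
#'
#' A candidate dive is a maximal contiguous run of samples deeper than the
#' day's mixed layer depth plus `offset` (default 10 m below the MLD).
#' Candidates shorter than `min_duration_min` are dropped. Days without an
#' MLD estimate are skipped with a warning.
#'
#' @param series a `tag_series`.
#' @param mld_by_day data.frame from [estimate_mld_daily()] (`date`, `mld`).
#' @param offset depth offset below the MLD defining the dive boundary, m.
#' @param min_duration_min minimum candidate duration, min.
#' @return data.frame, one row per candidate: `dive_id`, `date`,
#'   `start_idx`, `end_idx`, `start_time`, `end_time`, `max_depth`,
#'   `n_samples`, `total_duration_min`, `threshold_depth`.
#' @export
extract_dives <- function(series, mld_by_day, offset = 10,
                          min_duration_min = 5) {
  recs <- series$records
  dt <- series$interval_s
  dates <- series_dates(series)
  thr <- mld_by_day$mld[match(dates, mld_by_day$date)] + offset
  if (anyNA(thr)) {
    miss <- unique(dates[is.na(thr)])
    warning("no MLD estimate for ", paste(format(miss), collapse = ", "),
            "; day(s) skipped", call. = FALSE)
  }
  below <- !is.na(thr) & recs$depth_m > thr
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  out <- lapply(keep, function(j) {
    s <- starts[j]; e <- ends[j]
    data.frame(
      date = dates[s], start_idx = s, end_idx = e,
      start_time = recs$timestamp[s], end_time = recs$timestamp[e],
      max_depth = max(recs$depth_m[s:e]), n_samples = e - s + 1L,
      total_duration_min = (e - s + 1L) * dt / 60,
      threshold_depth = thr[s]
    )
  })
  dives <- if (length(out)) do.call(rbind, out) else
    data.frame(date = as.Date(character()), start_idx = integer(),
               end_idx = integer(), start_time = as.POSIXct(character()),
               end_time = as.POSIXct(character()), max_depth = numeric(),
               n_samples = integer(), total_duration_min = numeric(),
               threshold_depth = numeric())
  dives <- dives[dives$total_duration_min >= min_duration_min, , drop = FALSE]
  if (nrow(dives)) dives$dive_id <- seq_len(nrow(dives))
  else dives$dive_id <- integer()
  rownames(dives) <- NULL
  dives[, c("dive_id", setdiff(names(dives), "dive_id"))]
}

#' Segment a depth vector into descent, bottom, and ascent phases
#'
#' The bottom phase spans the first to the last sample with depth at or
#' above 75 percent of the dive's maximum depth; descent is everything
#' before, ascent everything after. Phase durations are sample counts times
#' the sampling interval, so a one-sample "spike" bottom carries one full
#' interval and the three durations always sum exactly to the dive
#' duration. A dive whose maximum falls on the first or last sample gets an
#' empty (zero-duration) descent or ascent and is flagged `"degenerate"`.
#'
#' @param depths numeric depth vector of the dive's samples (>= 3).
#' @param interval_s sampling interval, s.
#' @param bottom_frac bottom-phase threshold as a fraction of max depth.
#' @return list: `bottom_start`, `bottom_end` (1-based sample indices),
#'   `descent_duration_min`, `bottom_duration_min`, `ascent_duration_min`,
#'   `total_duration_min`, `bottom_proportion`, `flag`.
#' @examples
#' segment_phases(c(40, 80, 120, 160, 190, 200, 190, 160, 120, 80, 40), 60)
#' @export
segment_phases <- function(depths, interval_s, bottom_frac = 0.75) {
  n <- length(depths)
  if (n < 3L) stop("dive must have >= 3 samples")
  thr <- bottom_frac * max(depths)
  in_bottom <- which(depths >= thr)
  bs <- min(in_bottom); be <- max(in_bottom)
  dmin <- interval_s / 60
  flag <- if (bs == 1L || be == n) "degenerate" else "ok"
  list(bottom_start = bs, bottom_end = be,
       descent_duration_min = (bs - 1L) * dmin,
       bottom_duration_min = (be - bs + 1L) * dmin,
       ascent_duration_min = (n - be) * dmin,
       total_duration_min = n * dmin,
       bottom_proportion = (be - bs + 1L) / n,
       flag = flag)
}

#' Segment all extracted dives of a series
#'
#' @param dives candidate table from [extract_dives()].
#' @param series the `tag_series` the candidates index into.
#' @inheritParams segment_phases
#' @return `dives` with phase columns added (`bot_start_idx`,
#'   `bot_end_idx`, phase durations in minutes, `bottom_proportion`,
#'   `phase_flag`).
#' @export
segment_dives <- function(dives, series, bottom_frac = 0.75) {
  if (nrow(dives) == 0L) {
    for (cl in c("bot_start_idx", "bot_end_idx", "descent_duration_min",
                 "bottom_duration_min", "ascent_duration_min",
                 "bottom_proportion")) dives[[cl]] <- numeric()
    dives$phase_flag <- character()
    return(dives)
  }
  segs <- lapply(seq_len(nrow(dives)), function(i) {
    idx <- dives$start_idx[i]:dives$end_idx[i]
    segment_phases(series$records$depth_m[idx], series$interval_s,
                   bottom_frac)
  })
  dives$bot_start_idx <- dives$start_idx +
    vapply(segs, `[[`, numeric(1), "bottom_start") - 1L
  dives$bot_end_idx <- dives$start_idx +
    vapply(segs, `[[`, numeric(1), "bottom_end") - 1L
  for (cl in c("descent_duration_min", "bottom_duration_min",
               "ascent_duration_min", "bottom_proportion"))
    dives[[cl]] <- vapply(segs, `[[`, numeric(1), cl)
  dives$phase_flag <- vapply(segs, `[[`, character(1), "flag")
  dives
}

#' Retain daytime dives below the euphotic zone
#'
#' Keeps dives whose start is after local sunrise and end before local
#' sunset (solar events at the day's position) and whose maximum depth
#' exceeds the deep chlorophyll maximum cutoff (mean DCM depth + 3 SDs) of
#' the dive's 10-degree latitude band. Scattering layers occur below the
#' euphotic zone, so only such dives can be layer forays.
#'
#' @param dives segmented dive table.
#' @param positions data.frame `date`, `lat`, `lon` (daily track).
#' @param dcm_table a DCM cutoff table: data.frame `lat_min`, `lat_max`,
#'   `mean_dcm_m`, `sd_m` (see [default_dcm_table()]).
#' @return list: `retained` (dive table subset), `rejections` (data.frame
#'   `dive_id`, `reason` in `"not daytime"` / `"above DCM limit"`), and
#'   `counts` (rejections per rule).
#' @export
filter_daytime_deep <- function(dives, positions, dcm_table) {
  if (nrow(dives) == 0L)
    return(list(retained = dives,
                rejections = data.frame(dive_id = integer(),
                                        reason = character()),
                counts = c(`not daytime` = 0L, `above DCM limit` = 0L)))
  reasons <- rep(NA_character_, nrow(dives))
  for (i in seq_len(nrow(dives))) {
    p <- positions[positions$date == dives$date[i], , drop = FALSE]
    if (nrow(p) == 0L)
      stop("no position for date ", format(dives$date[i]))
    ev <- solar_events(dives$date[i], p$lat[1L], p$lon[1L])
    daytime <- dives$start_time[i] > ev$sunrise &
      dives$end_time[i] < ev$sunset
    if (!daytime) {
      reasons[i] <- "not daytime"
      next
    }
    cutoff <- dcm_cutoff(p$lat[1L], dcm_table)
    if (dives$max_depth[i] <= cutoff) reasons[i] <- "above DCM limit"
  }
  rej <- !is.na(reasons)
  list(retained = dives[!rej, , drop = FALSE],
       rejections = data.frame(dive_id = dives$dive_id[rej],
                               reason = reasons[rej]),
       counts = c(`not daytime` = sum(reasons == "not daytime", na.rm = TRUE),
                  `above DCM limit` = sum(reasons == "above DCM limit",
                                          na.rm = TRUE)))
}

#' DCM depth cutoff (mean + 3 SD) for a latitude
#'
#' @param lat latitude, deg N.
#' @param dcm_table data.frame `lat_min`, `lat_max`, `mean_dcm_m`, `sd_m`
#'   per 10-degree band.
#' @return cutoff depth, m.
#' @export
dcm_cutoff <- function(lat, dcm_table) {
  row <- which(dcm_table$lat_min <= lat & lat < dcm_table$lat_max)
  if (length(row) == 0L)
    stop("no DCM latitude band covering ", 10 * floor(lat / 10), "-",
         10 * floor(lat / 10) + 10, " deg N")
  dcm_table$mean_dcm_m[row[1L]] + 3 * dcm_table$sd_m[row[1L]]
}

#' Classify dives as U-shaped (foraging) or V-shaped (searching)
#'
#' Default mode partitions (bottom proportion, log duration) into two
#' clusters with standardized features and deterministic initialization
#' (centers at the dives with the lowest and highest bottom proportion);
#' the cluster with the higher mean bottom proportion is labeled U.
#' Rule mode applies fixed thresholds calibrated to published U/V dive
#' descriptors: U if bottom proportion >= 0.5 and duration >= 10 min; V if
#' bottom proportion < 0.5 and duration within 5-23 min; otherwise
#' `"other"`.
#'
#' @param dives segmented dive table (needs `bottom_proportion`,
#'   `total_duration_min`).
#' @param mode `"cluster"` or `"rule"`. Clustering on fewer than 2 dives
#'   falls back to rule mode with a warning.
#' @return `dives` with a `class_label` column (`"U"`, `"V"`, `"other"`).
#' @export
classify_dives <- function(dives, mode = c("cluster", "rule")) {
  mode <- match.arg(mode)
  if (nrow(dives) == 0L) {
    dives$class_label <- character()
    return(dives)
  }
  if (mode == "cluster" && nrow(dives) < 2L) {
    warning("fewer than 2 dives: falling back to rule mode", call. = FALSE)
    mode <- "rule"
  }
  if (mode == "rule") {
    bp <- dives$bottom_proportion
    dur <- dives$total_duration_min
    lab <- ifelse(bp >= 0.5 & dur >= 10, "U",
             ifelse(bp < 0.5 & dur >= 5 & dur <= 23, "V", "other"))
    dives$class_label <- lab
    return(dives)
  }
  x <- cbind(dives$bottom_proportion, log(dives$total_duration_min))
  xs <- scale(x)
  xs[, apply(x, 2, stats::sd) == 0] <- 0
  init <- xs[c(which.min(dives$bottom_proportion),
               which.max(dives$bottom_proportion)), , drop = FALSE]
  if (all(init[1, ] == init[2, ])) { # all dives identical: one class
    dives$class_label <- "U"
    return(dives)
  }
  km <- stats::kmeans(xs, centers = init, iter.max = 100L)
  u_cluster <- which.max(tapply(dives$bottom_proportion, km$cluster, mean))
  dives$class_label <- ifelse(km$cluster == as.integer(u_cluster), "U", "V")
  dives
}

#' Per-dive environmental metrics
#'
#' For each dive: the minimum ambient temperature; the temperature change
#' relative to the day's mixed layer (mean temperature at depths above the
#' MLD); the descent rate (depth gain over the descent phase); and the
#' change in light in orders of magnitude (log10) between the dive start
#' and the bottom-phase midpoint. If the light channel is absent the light
#' metric is `NA` and flagged; the others are still computed.
#'
#' @param dives segmented dive table.
#' @param series the `tag_series`.
#' @param mld_by_day daily MLD table ([estimate_mld_daily()]).
#' @param light_channel `"log"` (tag records ln-irradiance; default from the
#'   series) or `"linear"`.
#' @return `dives` with `min_temp`, `delta_temp`, `descent_rate_ms`,
#'   `delta_light_orders`, `metric_flag` columns.
#' @export
compute_dive_metrics <- function(dives, series, mld_by_day,
                                 light_channel = series$light_channel) {
  recs <- series$records
  dates <- series_dates(series)
  have_light <- !is.null(recs$light) && any(is.finite(recs$light))
  n <- nrow(dives)
  min_temp <- delta_temp <- drate <- dlight <- rep(NA_real_, n)
  flag <- rep("ok", n)
  for (i in seq_len(n)) {
    idx <- dives$start_idx[i]:dives$end_idx[i]
    min_temp[i] <- min(recs$temp_c[idx])
    mld <- mld_by_day$mld[match(dives$date[i], mld_by_day$date)]
    above <- which(dates == dives$date[i] & recs$depth_m <= mld)
    if (length(above)) delta_temp[i] <- min_temp[i] - mean(recs$temp_c[above])
    if (dives$descent_duration_min[i] > 0)
      drate[i] <- (dives$max_depth[i] - recs$depth_m[dives$start_idx[i]]) /
        (dives$descent_duration_min[i] * 60)
    if (have_light) {
      midbot <- floor((dives$bot_start_idx[i] + dives$bot_end_idx[i]) / 2)
      l0 <- recs$light[dives$start_idx[i]]
      l1 <- recs$light[midbot]
      if (light_channel == "log") {
        dlight[i] <- (l1 - l0) / log(10)
      } else if (is.finite(l0) && is.finite(l1) && l0 > 0 && l1 > 0) {
        dlight[i] <- log10(l1) - log10(l0)
      } else flag[i] <- "light-invalid"
    } else flag[i] <- "light-missing"
  }
  dives$min_temp <- min_temp
  dives$delta_temp <- delta_temp
  dives$descent_rate_ms <- drate
  dives$delta_light_orders <- dlight
  dives$metric_flag <- flag
  dives
}
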