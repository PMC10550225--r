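#' Diel depth composite of volume backscatter
#'
#' Pools backscatter profiles whose position falls inside a region box and
#' averages them into an hour-of-day (local solar, `UTC + lon/15` rounded
#' to the integer hour) by depth-bin grid over 0-600 m. Cells with no
#' observations are missing (`NA`), never zero-filled.
#'
#' @param profiles data.frame `timestamp` (UTC POSIXct), `depth_m`,
#'   `sv_db`, `lat`, `lon`.
#' @param region_box list or one-row data.frame with `lat_min`, `lat_max`,
#'   `lon_min`, `lon_max` (deg E 0-360) and optionally `name`.
#' @param depth_bin_width depth bin width, m.
#' @param depth_max grid bottom, m.
#' @return an `adcp_composite`: list with `grid` (data.frame `hour`,
#'   `depth_m`, `mean_sv`, `n` over the full hour x bin lattice),
#'   `day_hours = c(6, 18)`, `region`, `depth_bin_width`.
#' @export
composite_diel <- function(profiles, region_box, depth_bin_width = 10,
                           depth_max = 600) {
  rb <- as.list(region_box)
  lon <- normalize_lon360(profiles$lon)
  inbox <- profiles$lat >= rb$lat_min & profiles$lat <= rb$lat_max &
    lon >= rb$lon_min & lon <= rb$lon_max
  sub <- profiles[inbox & profiles$depth_m <= depth_max, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no profiles inside the region box")
  hour <- round(local_solar_hour(sub$timestamp, sub$lon)) %% 24
  zbin <- floor(sub$depth_m / depth_bin_width) * depth_bin_width +
    depth_bin_width / 2
  lattice <- expand.grid(hour = 0:23,
                         depth_m = seq(depth_bin_width / 2, depth_max,
                                       by = depth_bin_width))
  agg_m <- tapply(sub$sv_db, list(hour = hour, depth_m = zbin), mean)
  agg_n <- tapply(sub$sv_db, list(hour = hour, depth_m = zbin), length)
  mi <- match(as.character(lattice$hour), rownames(agg_m))
  zi <- match(as.character(lattice$depth_m), colnames(agg_m))
  lattice$mean_sv <- agg_m[cbind(mi, zi)]
  lattice$n <- agg_n[cbind(mi, zi)]
  lattice$n[is.na(lattice$n)] <- 0L
  structure(list(grid = lattice, day_hours = c(6, 18),
                 region = if (!is.null(rb$name)) rb$name else "region",
                 depth_bin_width = depth_bin_width),
            class = "adcp_composite")
}

#' Trace scattering-layer depth per hour within a depth stratum
#'
#' Per hour of the composite: the backscatter-weighted mean depth and the
#' peak (argmax) depth within the stratum. The centroid uses linearized
#' backscatter (`10^(Sv/10)`) restricted to cells within `threshold_db` of
#' the stratum's hourly maximum -- the usual layer-core thresholding that
#' keeps the noise floor from dragging the centroid toward the stratum
#' midpoint. In a noise-only stratum roughly half the cells clear the
#' threshold and the centroid sits near the stratum midpoint. Hours with
#' no data yield `NA`.
#'
#' @param composite an `adcp_composite`.
#' @param stratum `c(min_depth, max_depth)`, m, within the grid.
#' @param threshold_db centroid inclusion threshold below the hourly
#'   stratum maximum, dB.
#' @return data.frame `hour`, `centroid_m`, `peak_m`.
#' @export
trace_layers <- function(composite, stratum, threshold_db = 6) {
  g <- composite$grid
  if (stratum[1] < 0 || stratum[2] > max(g$depth_m) + composite$depth_bin_width / 2)
    stop("stratum outside the composite grid")
  out <- lapply(0:23, function(h) {
    s <- g[g$hour == h & g$depth_m >= stratum[1] & g$depth_m <= stratum[2] &
             !is.na(g$mean_sv), , drop = FALSE]
    if (nrow(s) == 0L)
      return(data.frame(hour = h, centroid_m = NA_real_, peak_m = NA_real_))
    core <- s$mean_sv >= max(s$mean_sv) - threshold_db
    w <- 10^(s$mean_sv[core] / 10)
    data.frame(hour = h, centroid_m = sum(w * s$depth_m[core]) / sum(w),
               peak_m = s$depth_m[which.max(s$mean_sv)])
  })
  do.call(rbind, out)
}

#' Quartiles of daytime foraging-dive maximum depth for a composite overlay
#'
#' Type-7 (linear interpolation) quartiles of `max_depth` over the supplied
#' daytime U dives, for overlaying the predator's foraging depths on an
#' acoustic composite. Fewer than 4 dives triggers a warning but the
#' quartiles are still emitted; an empty set yields `NA` quartiles and an
#' unchanged composite.
#'
#' @param composite an `adcp_composite`.
#' @param dives dive table (daytime U dives in the composite's region).
#' @return the composite with an `overlay` element: `c(q25, q50, q75)` m.
#' @export
overlay_dive_quartiles <- function(composite, dives) {
  if (nrow(dives) == 0L) {
    composite$overlay <- c(q25 = NA_real_, q50 = NA_real_, q75 = NA_real_)
    return(composite)
  }
  if (nrow(dives) < 4L)
    warning("fewer than 4 dives for quartile overlay", call. = FALSE)
  q <- stats::quantile(dives$max_depth, c(0.25, 0.5, 0.75), type = 7,
                       names = FALSE)
  composite$overlay <- c(q25 = q[1], q50 = q[2], q75 = q[3])
  composite
}
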