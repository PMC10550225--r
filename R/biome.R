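#' Default study-region province boxes
#'
#' Rectangular modified-province boxes for the North Pacific study domain:
#' North Central Pacific (26-40 N, 200-220 E), northern California Current
#' (41-49 N, 228-235 E), southern California Current (25-33 N, 239-246 E).
#'
#' @return data.frame `name`, `lat_min`, `lat_max`, `lon_min`, `lon_max`
#'   (longitudes deg E, 0-360).
#' @export
default_provinces <- function() {
  data.frame(
    name = c("North Central Pacific", "northern California Current",
             "southern California Current"),
    lat_min = c(26, 41, 25), lat_max = c(40, 49, 33),
    lon_min = c(200, 228, 239), lon_max = c(220, 235, 246)
  )
}

#' Assign a position to a province
#'
#' First-match lookup in the province boxes; positions outside every box
#' are `"unassigned"`.
#'
#' @param lat,lon position (deg N / deg E, any longitude convention;
#'   normalized to 0-360). Vectorized.
#' @param provinces province table as in [default_provinces()].
#' @return character vector of province names.
#' @export
assign_province <- function(lat, lon, provinces = default_provinces()) {
  lon <- normalize_lon360(lon)
  vapply(seq_along(lat), function(i) {
    hit <- which(provinces$lat_min <= lat[i] & lat[i] <= provinces$lat_max &
                 provinces$lon_min <= lon[i] & lon[i] <= provinces$lon_max)
    if (length(hit)) provinces$name[hit[1L]] else "unassigned"
  }, character(1))
}

#' Summarize dive metrics by biome
#'
#' Per-province mean, SD and n for every numeric metric column.
#'
#' @param dives data.frame with a `province` column and numeric metric
#'   columns (e.g. the merged dive metrics + energetics table).
#' @param metrics character vector of columns to summarize (default: all
#'   numeric columns except ids/indices).
#' @return data.frame `province`, `metric`, `mean`, `sd`, `n`.
#' @export
summarize_by_biome <- function(dives, metrics = NULL) {
  stopifnot("province" %in% names(dives))
  if (is.null(metrics)) {
    num <- vapply(dives, is.numeric, logical(1))
    metrics <- setdiff(names(dives)[num],
                       c("dive_id", "start_idx", "end_idx", "bot_start_idx",
                         "bot_end_idx", "n_samples"))
  }
  provs <- unique(dives$province)
  out <- list()
  for (p in provs) {
    sub <- dives[dives$province == p, , drop = FALSE]
    if (nrow(sub) == 0L) {
      warning("province ", p, " has no dives; omitted", call. = FALSE)
      next
    }
    for (m in metrics) {
      v <- sub[[m]][is.finite(sub[[m]])]
      out[[length(out) + 1L]] <- data.frame(
        province = p, metric = m,
        mean = if (length(v)) mean(v) else NA_real_,
        sd = if (length(v) > 1) stats::sd(v) else 0,
        n = length(v))
    }
  }
  do.call(rbind, out)
}

#' Percent change between two biome means
#'
#' `100 * (to - from) / from`, the convention used to report, e.g., the
#' decrease in mean metabolic cost rate from a coastal to a pelagic biome.
#'
#' @param from,to the two means (order matters).
#' @param digits rounding for the report (default 0 decimal places).
#' @return percent change, rounded.
#' @examples
#' percent_change(5.7, 4.2)    # -26
#' percent_change(0.103, 0.141) # 37
#' @export
percent_change <- function(from, to, digits = 0) {
  round(100 * (to - from) / from, digits)
}

#' Percent change of a summarized metric between two provinces
#'
#' @param summary output of [summarize_by_biome()].
#' @param metric metric name.
#' @param from,to province names.
#' @inheritParams percent_change
#' @return rounded percent change of the metric mean.
#' @export
biome_percent_change <- function(summary, metric, from, to, digits = 0) {
  m1 <- summary$mean[summary$province == from & summary$metric == metric]
  m2 <- summary$mean[summary$province == to & summary$metric == metric]
  if (length(m1) != 1L || length(m2) != 1L)
    stop("metric ", metric, " not summarized for both provinces")
  percent_change(m1, m2, digits)
}

#' Fit a power function of cost rate versus minimum temperature
#'
#' Ordinary least squares on the log-log scale:
#' `ln(cost_rate) = ln(a) + b * ln(min_temp)`. The linearized temperature
#' sensitivity is `b * 10` percent change in cost rate per 10% increase in
#' minimum temperature; the exact form `(1.1^b - 1) * 100` is reported
#' alongside.
#'
#' @param min_temp minimum dive temperatures, deg C (> 0).
#' @param cost_rate metabolic cost rates, mg O2 kg^-1 min^-1 (> 0).
#' @return a `power_fit`: list `a`, `b`, `se_b`, `fit_method`,
#'   `sensitivity_linear_pct`, `sensitivity_exact_pct`, `n`.
#' @export
fit_costrate_power <- function(min_temp, cost_rate) {
  stopifnot(length(min_temp) == length(cost_rate))
  bad <- which(!(is.finite(min_temp) & is.finite(cost_rate) &
                 min_temp > 0 & cost_rate > 0))
  if (length(bad))
    stop("non-positive or non-finite pairs at indices: ",
         paste(utils::head(bad, 10), collapse = ", "))
  if (length(min_temp) < 10) stop("need >= 10 pairs")
  fit <- stats::lm(log(cost_rate) ~ log(min_temp))
  b <- unname(stats::coef(fit)[2L])
  se_b <- summary(fit)$coefficients[2L, 2L]
  structure(list(
    a = exp(unname(stats::coef(fit)[1L])), b = b, se_b = se_b,
    fit_method = "log-log OLS",
    sensitivity_linear_pct = 10 * b,
    sensitivity_exact_pct = (1.1^b - 1) * 100,
    n = length(min_temp)
  ), class = "power_fit")
}

#' @export
print.power_fit <- function(x, ...) {
  cat(sprintf("<power_fit> cost_rate = %.3g * T^%.3f (se_b %.3g, n %d)\n",
              x$a, x$b, x$se_b, x$n))
  cat(sprintf("  per +10%% min temp: %.1f%% (linearized), %.1f%% (exact)\n",
              x$sensitivity_linear_pct, x$sensitivity_exact_pct))
  invisible(x)
}

#' Inverse distance weighted interpolation on a geographic grid
#'
#' `value(g) = sum(w_i v_i) / sum(w_i)` with `w_i = d_i^-power` and `d_i`
#' the great-circle distance to sample i; a grid node coincident with a
#' sample takes that sample's value exactly. Output is always inside the
#' range of the sample values.
#'
#' @param samples data.frame `lat`, `lon`, `value`.
#' @param grid data.frame `lat`, `lon` of target nodes.
#' @param power distance-decay exponent (default 2).
#' @return `grid` with a `value` column added.
#' @export
idw_field <- function(samples, grid, power = 2) {
  if (nrow(samples) == 0L) stop("no samples")
  vals <- vapply(seq_len(nrow(grid)), function(i) {
    d <- great_circle_km(grid$lat[i], grid$lon[i], samples$lat, samples$lon)
    if (any(d == 0)) return(samples$value[which(d == 0)[1L]])
    w <- d^(-power)
    sum(w * samples$value) / sum(w)
  }, numeric(1))
  grid$value <- vals
  grid
}

#' Great-circle distance (haversine), km
#'
#' @param lat1,lon1,lat2,lon2 positions in degrees; vectorized.
#' @return distance in km.
#' @export
great_circle_km <- function(lat1, lon1, lat2, lon2) {
  r <- pi / 180
  dlat <- (lat2 - lat1) * r
  dlon <- (normalize_lon180(lon2) - normalize_lon180(lon1)) * r
  a <- sin(dlat / 2)^2 + cos(lat1 * r) * cos(lat2 * r) * sin(dlon / 2)^2
  6371 * 2 * asin(pmin(1, sqrt(a)))
}
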