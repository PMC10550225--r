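#' Build a midday light attenuation profile for one fish-day
#'
#' Within the midday window (local solar noon +/- `window_h` hours) at the
#' day's position, the diffuse attenuation is estimated from along-path
#' gradients: for every pair of consecutive samples whose depth change is
#' at least `min_dz` (i.e. taken during a vertical transit),
#' `k = -d(ln-irradiance)/d(depth)`, assigned to the pair's midpoint
#' depth. Pair estimates are pooled into fixed-width depth bins
#' (span-weighted mean; bins with fewer than `min_obs` pairs are
#' undefined). Negative k values are retained (and handled by QC), never
#' clipped.
#'
#' Differencing consecutive samples (30-60 s apart) rather than pooled bin
#' means makes the estimate insensitive to the diel surface-irradiance
#' drift across the two-hour window, which would otherwise bias
#' between-bin differences whenever different depths are sampled at
#' different times; descent and ascent passes carry opposite-signed
#' residual drift and average out. At ~1 m/s vertical speeds a pass yields
#' one pair per 20-60 m, so multiple window passes are pooled; the 10-m
#' default bin width balances resolution against occupancy.
#'
#' @param series a `tag_series`.
#' @param date the fish-day to profile (local solar date).
#' @param dcm_table optional DCM cutoff table; if supplied, `dcm_cutoff`
#'   and `extends_below_cutoff` are filled from the day's latitude band.
#' @param bin_width depth bin width, m.
#' @param min_obs minimum gradient pairs for a bin to be defined.
#' @param min_dz minimum depth change for a sample pair to count as a
#'   transit, m (excludes bottom-phase wiggle and surface occupation).
#' @param window_h half-width of the midday window, hours.
#' @param min_span_m minimum depth span within the window.
#' @param light_channel `"log"` or `"linear"` light semantics.
#' @param fish_id identifier carried through to outputs.
#' @return an `attenuation_profile`: list with `bins` (data.frame
#'   `depth_m` = bin center, `k_per_m`, `n_obs` = pairs pooled, `gap_m` =
#'   mean pair span), `epipelagic_mean_k` (mean k over 20-150 m),
#'   `dcm_cutoff`, `extends_below_cutoff`, `qc_pass` (NA until
#'   [qc_profile()]), plus ids and position.
#' @export
build_attenuation_profile <- function(series, date, dcm_table = NULL,
                                      bin_width = 10, min_obs = 1,
                                      min_dz = 5, window_h = 1,
                                      min_span_m = 50,
                                      light_channel = series$light_channel,
                                      fish_id = "fish1") {
  date <- as.Date(date)
  p <- series$positions[series$positions$date == date, , drop = FALSE]
  if (nrow(p) == 0L) stop("no position for date ", format(date))
  ev <- solar_events(date, p$lat[1L], p$lon[1L])
  recs <- series$records
  inwin <- recs$timestamp >= ev$solar_noon - window_h * 3600 &
    recs$timestamp <= ev$solar_noon + window_h * 3600
  w <- recs[inwin, , drop = FALSE]
  if (nrow(w) == 0L || diff(range(w$depth_m)) < min_span_m)
    stop("insufficient depth span in midday window (need >= ",
         min_span_m, " m)")
  lnl <- if (light_channel == "log") w$light else {
    keep <- is.finite(w$light) & w$light > 0
    w <- w[keep, , drop = FALSE]
    log(w$light)
  }
  if (nrow(w) < 2L || diff(range(lnl)) < 1e-9)
    stop("all-dark window: light channel at the sensor floor")
  nw <- nrow(w)
  dz <- w$depth_m[-1L] - w$depth_m[-nw]
  dl <- lnl[-1L] - lnl[-nw]
  dtp <- as.numeric(difftime(w$timestamp[-1L], w$timestamp[-nw],
                             units = "secs"))
  transit <- abs(dz) >= min_dz & dtp <= 2 * stats::median(dtp)
  if (!any(transit))
    stop("no vertical transits of >= ", min_dz, " m in midday window")
  kp <- -dl[transit] / dz[transit]
  zp <- (w$depth_m[-1L] + w$depth_m[-nw])[transit] / 2
  wt <- abs(dz[transit])
  bin <- floor(zp / bin_width)
  kbin <- tapply(kp * wt, bin, sum) / tapply(wt, bin, sum)
  nobs <- tapply(kp, bin, length)
  span <- tapply(wt, bin, mean)
  centers <- (as.numeric(names(kbin)) + 0.5) * bin_width
  ord <- order(centers)
  bins <- data.frame(
    depth_m = centers[ord],
    k_per_m = as.numeric(kbin)[ord],
    n_obs = as.integer(nobs)[ord],
    gap_m = as.numeric(span)[ord]
  )
  bins <- bins[bins$n_obs >= min_obs, , drop = FALSE]
  if (nrow(bins) < 2L)
    stop("fewer than 2 defined depth bins in midday window")
  epi <- bins$depth_m >= 20 & bins$depth_m <= 150
  cutoff <- if (!is.null(dcm_table)) dcm_cutoff(p$lat[1L], dcm_table) else NA_real_
  structure(list(
    fish_id = fish_id, date = date, lat = p$lat[1L], lon = p$lon[1L],
    bin_width = bin_width, bins = bins,
    epipelagic_mean_k = if (any(epi)) mean(bins$k_per_m[epi]) else NA_real_,
    dcm_cutoff = cutoff,
    extends_below_cutoff = if (is.na(cutoff)) NA else
      max(bins$depth_m) >= cutoff,
    qc_pass = NA, qc_fail = character(0)
  ), class = "attenuation_profile")
}

#' Quality-control rules for attenuation profiles
#'
#' @param min_bins minimum defined k bins (below the surface-exclusion
#'   depth) for a usable profile.
#' @param max_neg_frac maximum tolerated fraction of negative-k bins.
#' @param max_jump_per_m maximum attenuation change between adjacent bins,
#'   per meter of bin separation (cloud/occlusion spike heuristic).
#' @param surface_exclude_m bins shallower than this are excluded from QC
#'   statistics and detection (wave focusing / surface anomaly zone).
#' @return a list of rules for [qc_profile()].
#' @export
qc_rules <- function(min_bins = 8, max_neg_frac = 0.2,
                     max_jump_per_m = 0.003, surface_exclude_m = 20) {
  list(min_bins = min_bins, max_neg_frac = max_neg_frac,
       max_jump_per_m = max_jump_per_m,
       surface_exclude_m = surface_exclude_m)
}

#' Apply quality control to an attenuation profile
#'
#' QC failure is a state (`qc_pass = FALSE` with the failed rules
#' recorded), not an error.
#'
#' @param profile an `attenuation_profile`.
#' @param rules a [qc_rules()] list.
#' @return the profile with `qc_pass`, `qc_fail` and `bins$surface_excluded`
#'   filled.
#' @export
qc_profile <- function(profile, rules = qc_rules()) {
  b <- profile$bins
  b$surface_excluded <- b$depth_m < rules$surface_exclude_m
  use <- b[!b$surface_excluded, , drop = FALSE]
  fail <- character(0)
  if (nrow(use) < rules$min_bins) fail <- c(fail, "too-few-bins")
  if (nrow(use) > 0 && mean(use$k_per_m < 0) > rules$max_neg_frac)
    fail <- c(fail, "negative-k")
  if (nrow(use) > 1) {
    jump <- abs(diff(use$k_per_m)) / diff(use$depth_m)
    if (max(jump) > rules$max_jump_per_m) fail <- c(fail, "jump")
  }
  profile$bins <- b
  profile$qc_pass <- length(fail) == 0L
  profile$qc_fail <- fail
  profile
}

#' Detect deep attenuation increases consistent with scattering layers
#'
#' Presence-only detector. Below the latitude band's DCM cutoff (mean DCM
#' depth + 3 SDs) chlorophyll should not contribute to attenuation, so a
#' marked increase there is consistent with a dense scattering layer. The
#' within-profile reference is the minimum attenuation over bins at or
#' below (cutoff - one bin); overlap is declared when at least two
#' consecutive defined bins deeper than the cutoff exceed the reference by
#' the relative `margin`. `overlap = FALSE` means "no detection", not "no
#' layer".
#'
#' @param profile a QC'ed `attenuation_profile`.
#' @param dcm_table optional cutoff table if the profile has no
#'   `dcm_cutoff` yet.
#' @param margin relative excess over the reference minimum (0.25 = 25%).
#' @return a `detection_result`: list `evaluated`, `overlap`,
#'   `reference_min_k`, `peak_depths`, `peak_excess`, `cutoff`. When the
#'   preconditions fail (no QC pass, or profile does not extend below the
#'   cutoff) `evaluated = FALSE` and `overlap = NA` (distinct from a clean
#'   non-detection).
#' @export
detect_scattering_overlap <- function(profile, dcm_table = NULL,
                                      margin = 0.25) {
  cutoff <- profile$dcm_cutoff
  if (is.na(cutoff)) {
    if (is.null(dcm_table))
      stop("profile has no dcm_cutoff and no dcm_table supplied")
    cutoff <- dcm_cutoff(profile$lat, dcm_table)
  }
  not_eval <- structure(list(evaluated = FALSE, overlap = NA,
                             reference_min_k = NA_real_,
                             peak_depths = numeric(0),
                             peak_excess = NA_real_, cutoff = cutoff,
                             margin = margin), class = "detection_result")
  b <- profile$bins
  if (!is.null(b$surface_excluded)) b <- b[!b$surface_excluded, , drop = FALSE]
  if (!isTRUE(profile$qc_pass) || nrow(b) == 0L ||
      max(b$depth_m) < cutoff) return(not_eval)
  ref_region <- b$depth_m >= cutoff - profile$bin_width
  if (!any(ref_region)) return(not_eval)
  ref <- min(b$k_per_m[ref_region])
  # "increases" are assessed below the within-profile minimum: only bins
  # deeper than where the minimum occurs can qualify, so a monotonically
  # decreasing profile can never trigger a detection
  ref_depth <- b$depth_m[ref_region][which.min(b$k_per_m[ref_region])]
  deep <- b[b$depth_m > max(cutoff, ref_depth), , drop = FALSE]
  qual <- deep$k_per_m >= ref * (1 + margin)
  r <- rle(qual)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  runs <- which(r$values & r$lengths >= 2L)
  peaks <- vapply(runs, function(j) {
    seg <- starts[j]:ends[j]
    deep$depth_m[seg[which.max(deep$k_per_m[seg])]]
  }, numeric(1))
  structure(list(
    evaluated = TRUE, overlap = length(peaks) > 0L,
    reference_min_k = ref, peak_depths = peaks,
    peak_excess = if (nrow(deep)) max(deep$k_per_m) / ref - 1 else NA_real_,
    cutoff = cutoff, margin = margin
  ), class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  if (!isTRUE(x$evaluated)) {
    cat(sprintf("<detection_result> not evaluated (cutoff %.0f m)\n",
                x$cutoff))
  } else {
    cat(sprintf(
      "overlap detected: %s; peak depth(s): %s m (cutoff %.0f m)\n",
      x$overlap,
      if (length(x$peak_depths)) paste(x$peak_depths, collapse = ", ")
      else "none", x$cutoff))
  }
  invisible(x)
}

#' @export
print.attenuation_profile <- function(x, ...) {
  cat(sprintf(
    "<attenuation_profile> %s %s: %d bins to %.0f m, epipelagic k %.4f, QC %s\n",
    x$fish_id, format(x$date), nrow(x$bins), max(x$bins$depth_m),
    x$epipelagic_mean_k, x$qc_pass))
  invisible(x)
}

#' Cluster attenuation profiles within a biome and composite them
#'
#' Profiles are aligned on a common bin-depth grid (missing bins
#' mean-imputed per depth), standardized per depth, and partitioned with
#' seeded k-means. Each cluster's composite is the per-depth arithmetic
#' mean of member k values with a normal-approximation 95% confidence
#' interval; clusters are ordered by their mean attenuation over depths
#' <= 100 m (the shallow-attenuation color scale of composite figures).
#'
#' @param profiles list of `attenuation_profile` objects (same biome).
#' @param k_clusters number of clusters.
#' @param seed seed for the deterministic k-means initialization.
#' @return list with `clusters` (each: `cluster_id`, `members`,
#'   `composite` data.frame `depth_m`, `mean_k`, `ci95_lo`, `ci95_hi`, `n`,
#'   `shallow_mean_k`) and `assignment` (integer vector over profiles).
#' @export
cluster_profiles <- function(profiles, k_clusters, seed = 1L) {
  if (length(profiles) < k_clusters)
    stop("too few profiles (", length(profiles), ") for ", k_clusters,
         " clusters")
  grid <- sort(unique(unlist(lapply(profiles, function(p) p$bins$depth_m))))
  X <- t(vapply(profiles, function(p)
    p$bins$k_per_m[match(grid, p$bins$depth_m)], numeric(length(grid))))
  for (j in seq_along(grid)) { # per-depth mean imputation
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- mean(X[, j], na.rm = TRUE)
  }
  keep <- colSums(is.finite(X)) > 0
  Xs <- scale(X[, keep, drop = FALSE])
  Xs[, !is.finite(colSums(Xs))] <- 0
  if (k_clusters == 1L) {
    cl <- rep(1L, length(profiles))
  } else {
    set.seed(as.integer(seed))
    cl <- stats::kmeans(Xs, centers = k_clusters, nstart = 10L,
                        iter.max = 100L)$cluster
  }
  clusters <- lapply(seq_len(k_clusters), function(g) {
    mem <- which(cl == g)
    sub <- X[mem, keep, drop = FALSE]
    mu <- colMeans(sub)
    nn <- nrow(sub)
    se <- if (nn > 1) apply(sub, 2, stats::sd) / sqrt(nn) else rep(0, ncol(sub))
    comp <- data.frame(depth_m = grid[keep], mean_k = mu,
                       ci95_lo = mu - 1.96 * se, ci95_hi = mu + 1.96 * se,
                       n = nn)
    shallow <- comp$depth_m <= 100
    list(cluster_id = g, members = mem, composite = comp,
         shallow_mean_k = if (any(shallow)) mean(comp$mean_k[shallow])
                          else NA_real_)
  })
  ord <- order(vapply(clusters, `[[`, numeric(1), "shallow_mean_k"))
  clusters <- clusters[ord]
  relabel <- integer(k_clusters)
  for (g in seq_len(k_clusters)) {
    clusters[[g]]$cluster_id <- g
    relabel[ord[g]] <- g
  }
  list(clusters = clusters, assignment = relabel[cl])
}
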