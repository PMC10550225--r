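#' Run the dive pipeline end to end on one tag series
#'
#' Convenience wrapper: daily MLD estimation, dive extraction (boundaries
#' 10 m below the MLD), phase segmentation, daytime/euphotic-depth
#' filtering, U/V classification, per-dive environmental metrics, and
#' per-dive energetics; assigns each dive a province from its daily
#' position.
#'
#' @param series a `tag_series`.
#' @param dcm_table DCM cutoff table (default the packaged synthetic
#'   placeholder).
#' @param model a [metabolic_model()].
#' @param provinces province boxes ([default_provinces()]).
#' @param classify_mode `"cluster"` or `"rule"`.
#' @param offset,min_duration_min dive-extraction settings.
#' @return list: `dives` (retained, classified, with metrics, energetics
#'   and `province`), `mld` (daily table), `rejections`, `candidates`
#'   (count of pre-filter candidates).
#' @export
run_dive_pipeline <- function(series, dcm_table = default_dcm_table(),
                              model = metabolic_model(),
                              provinces = default_provinces(),
                              classify_mode = "cluster",
                              offset = 10, min_duration_min = 5) {
  mld <- estimate_mld_daily(series)
  cand <- extract_dives(series, mld, offset = offset,
                        min_duration_min = min_duration_min)
  cand <- segment_dives(cand, series)
  filt <- filter_daytime_deep(cand, series$positions, dcm_table)
  dives <- filt$retained
  if (nrow(dives)) {
    dives <- classify_dives(dives, mode = classify_mode)
    dives <- compute_dive_metrics(dives, series, mld)
    en <- dive_energetics(dives, series, model)
    dives <- merge(dives, en, by = "dive_id", sort = FALSE)
    pos <- series$positions[match(dives$date, series$positions$date), ]
    dives$province <- assign_province(pos$lat, pos$lon, provinces)
  }
  list(dives = dives, mld = mld, rejections = filt$rejections,
       candidates = nrow(cand))
}
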