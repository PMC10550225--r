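#' Write a tag series to delimited text
#'
#' Records go to `<prefix>_series.csv` with header
#' `timestamp,depth_m,temp_c,light` (ISO-8601 UTC timestamps) and daily
#' positions to `<prefix>_positions.csv` with header `date,lat,lon`.
#'
#' @param series a `tag_series`.
#' @param prefix output path prefix.
#' @return invisibly, the two file paths.
#' @export
write_tag_series <- function(series, prefix) {
  recs <- series$records
  recs$timestamp <- format(recs$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  f1 <- paste0(prefix, "_series.csv")
  f2 <- paste0(prefix, "_positions.csv")
  utils::write.csv(recs, f1, row.names = FALSE, quote = FALSE)
  utils::write.csv(series$positions, f2, row.names = FALSE, quote = FALSE)
  invisible(c(series = f1, positions = f2))
}

#' Read a tag series from delimited text
#'
#' Reads the format written by [write_tag_series()] (the same reader
#' handles real tag exports using those column names). Validates that
#' timestamps are strictly increasing at a fixed interval and that every
#' record date has a position.
#'
#' @param series_file CSV with `timestamp,depth_m,temp_c,light`.
#' @param positions_file CSV with `date,lat,lon`.
#' @param fish_length fork length, m.
#' @param light_channel `"log"` (default: the tag records ln-irradiance) or
#'   `"linear"`.
#' @return a `tag_series`.
#' @export
read_tag_series <- function(series_file, positions_file, fish_length = 0.8,
                            light_channel = c("log", "linear")) {
  light_channel <- match.arg(light_channel)
  recs <- utils::read.csv(series_file)
  recs$timestamp <- as.POSIXct(recs$timestamp,
                               format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  dts <- diff(as.numeric(recs$timestamp))
  if (any(dts <= 0)) stop("timestamps must be strictly increasing")
  if (length(unique(dts)) > 1L)
    stop("timestamps must be evenly spaced")
  pos <- utils::read.csv(positions_file)
  pos$date <- as.Date(pos$date)
  # positions are keyed by local solar date (the pipeline's day unit)
  rec_dates <- unique(solar_date(recs$timestamp, stats::median(pos$lon)))
  if (!all(rec_dates %in% pos$date))
    stop("every record date needs exactly one position")
  structure(list(records = recs, positions = pos,
                 fish_length = fish_length, interval_s = dts[1L],
                 light_channel = light_channel, schedule = NULL),
            class = "tag_series")
}

#' Packaged placeholder DCM cutoff table
#'
#' Synthetic per-10-degree-band deep chlorophyll maximum depth
#' distributions (mean and SD; the cutoff used by the pipeline is mean +
#' 3 SD). These are plausible placeholders consistent with published
#' qualitative mid-latitude ranges (cutoffs of roughly 145-165 m), NOT a
#' published climatology: replace with a real table for real analyses.
#'
#' @return data.frame `lat_min`, `lat_max`, `mean_dcm_m`, `sd_m`.
#' @export
default_dcm_table <- function() {
  path <- system.file("extdata", "dcm_table_synthetic.csv",
                      package = "seatag")
  utils::read.csv(path)
}

#' Write/read helpers for the small config tables
#'
#' @param table a data.frame (DCM table or province boxes).
#' @param path CSV path.
#' @return `read_config_table` returns the data.frame.
#' @export
write_config_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_config_table
#' @export
read_config_table <- function(path) utils::read.csv(path)

#' Write backscatter profiles to long-format delimited text
#'
#' Columns `timestamp,depth_m,sv_db,lat,lon`.
#'
#' @param profiles backscatter data.frame ([simulate_backscatter()]).
#' @param path CSV path.
#' @export
write_backscatter <- function(profiles, path) {
  profiles$timestamp <- format(profiles$timestamp, "%Y-%m-%dT%H:%M:%SZ",
                               tz = "UTC")
  utils::write.csv(profiles, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_backscatter
#' @export
read_backscatter <- function(path) {
  p <- utils::read.csv(path)
  p$timestamp <- as.POSIXct(p$timestamp, format = "%Y-%m-%dT%H:%M:%SZ",
                            tz = "UTC")
  p
}
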