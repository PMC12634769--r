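# CSV/YAML readers and writers for the pipeline's external interfaces.
# Timestamps are serialised as ISO-8601 with a UTC offset and parsed back
# into the requested timezone.

read_csv_quiet <- function(path, ...) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE, ...)
}

parse_timestamp <- function(x, tz) {
  out <- lubridate::ymd_hms(x, tz = "UTC", quiet = TRUE)
  if (any(is.na(out) & !is.na(x))) {
    abort("unparseable ISO-8601 timestamp(s)")
  }
  lubridate::with_tz(out, tz)
}

#' Read a transmitter calibration CSV
#'
#' Expected columns: `transmitter_id`, `bath_temp_C`, `pulse_interval_ms`.
#' @param path CSV path.
#' @return A tibble of calibration points.
#' @export
read_calibration_csv <- function(path) {
  df <- read_csv_quiet(path)
  assert_cols(df, c("transmitter_id", "bath_temp_C", "pulse_interval_ms"),
              path)
  df
}

#' Read a pulse-log CSV
#'
#' Expected columns: `timestamp` (ISO-8601 with offset), `transmitter_id`,
#' `pulse_interval_ms`.
#' @param path CSV path.
#' @param tz Timezone to represent timestamps in.
#' @return A tibble of pulse records.
#' @export
read_pulse_csv <- function(path, tz = "UTC") {
  df <- read_csv_quiet(path, col_types = readr::cols(
    timestamp = readr::col_character()))
  assert_cols(df, c("timestamp", "transmitter_id", "pulse_interval_ms"),
              path)
  mutate(df, timestamp = parse_timestamp(.data$timestamp, tz))
}

#' Read a weather-station CSV
#'
#' Expected columns: `timestamp`, `air_temp_C`, `rel_humidity_pct`,
#' `pressure_hPa`, `rain_mm`, `wind_kmh`.
#' @inheritParams read_pulse_csv
#' @return A tibble of weather samples.
#' @export
read_weather_csv <- function(path, tz = "UTC") {
  df <- read_csv_quiet(path, col_types = readr::cols(
    timestamp = readr::col_character()))
  assert_cols(df, c("timestamp", "air_temp_C", "rel_humidity_pct",
                    "pressure_hPa", "rain_mm", "wind_kmh"), path)
  mutate(df, timestamp = parse_timestamp(.data$timestamp, tz))
}

#' Read a capture body-mass CSV
#'
#' Expected columns: `site`, `sex`, `timepoint`, `mass_g` (optional `age`,
#' `forearm_mm`).
#' @param path CSV path.
#' @return A tibble of capture records.
#' @export
read_bodymass_csv <- function(path) {
  df <- read_csv_quiet(path)
  assert_cols(df, c("site", "sex", "timepoint", "mass_g"), path)
  df
}

# Serialise any POSIXct columns and write a deterministic CSV.
write_output_csv <- function(df, path) {
  df <- dplyr::mutate(df, dplyr::across(dplyr::where(lubridate::is.POSIXct),
                                        format_iso8601))
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}
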