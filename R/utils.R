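# Shared helpers: column checks, civil-night conventions, night lookup.

assert_cols <- function(df, cols, name = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("`%s` is missing required column(s): %s",
                  name, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

#' Convert a duration in hours to days
#'
#' Reporting convenience used in bout summaries (e.g. a 304.8 h bout is a
#' 12.7 day bout at the default precision).
#'
#' @param hours Numeric duration(s) in hours.
#' @param digits Decimal places for the result (default 1).
#' @return Numeric duration(s) in days.
#' @export
hours_to_days <- function(hours, digits = 1) {
  round(hours / 24, digits)
}

#' Transmitter load as a percentage of body mass
#'
#' External transmitters should stay below ~5% of the carrier's body mass;
#' this computes the attachment load for a given transmitter and bat.
#'
#' @param transmitter_g Transmitter (plus adhesive) mass in grams.
#' @param body_mass_g Body mass in grams.
#' @return Load in percent of body mass.
#' @export
transmitter_load <- function(transmitter_g, body_mass_g) {
  if (any(!is.finite(transmitter_g)) || any(transmitter_g <= 0)) {
    abort("`transmitter_g` must be positive and finite")
  }
  if (any(!is.finite(body_mass_g)) || any(body_mass_g <= 0)) {
    abort("`body_mass_g` must be positive and finite")
  }
  100 * transmitter_g / body_mass_g
}

# The "civil night" of an instant: the date of the sunset bounding the
# noon-to-noon day the instant falls in. 02:00 on July 5 belongs to the
# night of July 4; 17:30 on July 4 also belongs to the night of July 4.
civil_night_date <- function(t, tz) {
  as.Date(lubridate::with_tz(t, tz) - lubridate::dhours(12), tz = tz)
}

# Index into `nights` of the [sunset, sunrise_next) window containing each
# time, NA when outside all windows.
night_index <- function(times, nights) {
  if (is.null(nights) || nrow(nights) == 0) {
    return(rep(NA_integer_, length(times)))
  }
  o <- order(nights$sunset)
  nights <- nights[o, ]
  i <- findInterval(as.numeric(times), as.numeric(nights$sunset))
  inside <- i >= 1 &
    as.numeric(times) < as.numeric(nights$sunrise_next)[pmax(i, 1L)]
  out <- ifelse(inside, i, NA_integer_)
  # map back to the caller's row order
  ifelse(is.na(out), NA_integer_, o[pmax(out, 1L)])
}

is_night_time <- function(times, nights) {
  !is.na(night_index(times, nights))
}

# Fixed serialisation for timestamps in exported CSVs.
format_iso8601 <- function(t) {
  format(t, "%Y-%m-%dT%H:%M:%S%z")
}
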