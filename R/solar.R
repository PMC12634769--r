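# Sunset/sunrise computation (NOAA solar position equations) and
# sunset-to-sunrise night windows.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Solar declination (degrees) and equation of time (minutes) at a Julian
# century. NOAA's low-precision solar position algorithm; adequate to well
# under a minute for sunrise/sunset at mid latitudes.
solar_position <- function(jc) {
  gml <- (280.46646 + jc * (36000.76983 + 0.0003032 * jc)) %% 360
  gma <- 357.52911 + jc * (35999.05029 - 0.0001537 * jc)
  ecc <- 0.016708634 - jc * (0.000042037 + 0.0000001267 * jc)
  gmar <- deg2rad(gma)
  eq_centre <- sin(gmar) * (1.914602 - jc * (0.004817 + 0.000014 * jc)) +
    sin(2 * gmar) * (0.019993 - 0.000101 * jc) +
    sin(3 * gmar) * 0.000289
  true_long <- gml + eq_centre
  omega <- deg2rad(125.04 - 1934.136 * jc)
  app_long <- true_long - 0.00569 - 0.00478 * sin(omega)
  mean_obliq <- 23 + (26 + (21.448 - jc * (46.815 + jc * (0.00059 - jc * 0.001813))) / 60) / 60
  obliq <- mean_obliq + 0.00256 * cos(omega)
  decl <- rad2deg(asin(sin(deg2rad(obliq)) * sin(deg2rad(app_long))))
  y <- tan(deg2rad(obliq / 2))^2
  eot <- 4 * rad2deg(
    y * sin(2 * deg2rad(gml)) -
      2 * ecc * sin(gmar) +
      4 * ecc * y * sin(gmar) * cos(2 * deg2rad(gml)) -
      0.5 * y^2 * sin(4 * deg2rad(gml)) -
      1.25 * ecc^2 * sin(2 * gmar)
  )
  list(decl = decl, eot = eot)
}

# Sunrise/sunset for one or more dates, as minutes past 00:00 UTC (may fall
# outside 0..1440 for longitudes far from Greenwich). Zenith 90.833 degrees
# (refraction + solar radius). Iterative refinement: the declination and
# equation of time are re-evaluated at the current event estimate.
sun_event_minutes_utc <- function(lat, lon, dates, rise) {
  jd0 <- as.numeric(as.Date(dates)) + 2440587.5
  t_min <- rep(720, length(jd0))
  for (iter in 1:3) {
    jc <- (jd0 + t_min / 1440 - 2451545) / 36525
    sp <- solar_position(jc)
    cos_ha <- cos(deg2rad(90.833)) / (cos(deg2rad(lat)) * cos(deg2rad(sp$decl))) -
      tan(deg2rad(lat)) * tan(deg2rad(sp$decl))
    if (any(abs(cos_ha) > 1)) {
      abort("sun never rises or never sets on a requested date (polar day/night)")
    }
    ha <- rad2deg(acos(cos_ha))
    noon <- 720 - 4 * lon - sp$eot
    t_min <- if (rise) noon - 4 * ha else noon + 4 * ha
  }
  t_min
}

#' Sunrise and sunset times for a site
#'
#' Computes apparent sunrise and sunset (zenith 90.833 degrees) with the
#' NOAA solar position equations, accurate to within about a minute of
#' published almanac values at the mid latitudes this package targets.
#'
#' @param lat,lon Site latitude and longitude in decimal degrees
#'   (|lat| < 60; polar latitudes are not supported).
#' @param dates Date vector (or anything coercible with [as.Date()]).
#' @param tz Olson timezone of the site (e.g. "Australia/Sydney"); returned
#'   times are in this zone, with daylight-saving honoured.
#' @return A tibble with columns `date`, `sunrise`, `sunset` (POSIXct).
#' @export
sun_times <- function(lat, lon, dates, tz = "UTC") {
  if (!is.finite(lat) || abs(lat) >= 60) {
    abort("unsupported latitude: |lat| must be < 60 degrees")
  }
  dates <- as.Date(dates)
  base <- as.POSIXct(paste(dates, "00:00:00"), tz = "UTC")
  rise <- base + 60 * sun_event_minutes_utc(lat, lon, dates, rise = TRUE)
  set <- base + 60 * sun_event_minutes_utc(lat, lon, dates, rise = FALSE)
  tibble(
    date = dates,
    sunrise = lubridate::with_tz(rise, tz),
    sunset = lubridate::with_tz(set, tz)
  )
}

#' Sunset-to-sunrise night windows
#'
#' The analysis night of a given date runs from that date's sunset to the
#' next day's sunrise; nightly weather covariates and the nocturnal
#' classification of arousals and normothermia both use these windows, with
#' half-open membership `[sunset, sunrise_next)`.
#'
#' @inheritParams sun_times
#' @param site Optional site identifier carried into the result.
#' @return A tibble with columns `site`, `night_date` (date of the sunset),
#'   `sunset` and `sunrise_next` (POSIXct in `tz`).
#' @export
night_window <- function(lat, lon, tz, dates, site = NA_character_) {
  dates <- as.Date(dates)
  st0 <- sun_times(lat, lon, dates, tz)
  st1 <- sun_times(lat, lon, dates + 1, tz)
  out <- tibble(
    site = site,
    night_date = dates,
    sunset = st0$sunset,
    sunrise_next = st1$sunrise
  )
  stopifnot(all(out$sunset < out$sunrise_next))
  out
}
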