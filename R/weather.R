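# Nightly weather covariates: absolute humidity and sunset-to-sunrise
# aggregation of station series.

#' Absolute humidity from air temperature and relative humidity
#'
#' Converts relative humidity to absolute humidity (water vapour mass per
#' volume of air), a temperature-independent moisture measure that is the
#' biologically relevant quantity for evaporative water loss in hibernating
#' bats. Uses the Magnus saturation vapour pressure approximation
#' (6.112 hPa, 17.67, 243.5 degC):
#' \deqn{AH = 216.74 \cdot \frac{6.112\, e^{17.67 T/(T+243.5)} \cdot RH/100}{T+273.15}}
#'
#' @param air_temp_C Air temperature in degC (-40 to 50).
#' @param rel_humidity_pct Relative humidity in percent (0 to 100).
#' @return Absolute humidity in g/m^3.
#' @examples
#' absolute_humidity(20, 100) # ~17.3 g/m^3, the saturated density at 20 degC
#' @export
absolute_humidity <- function(air_temp_C, rel_humidity_pct) {
  if (any(!is.finite(air_temp_C)) || any(air_temp_C < -40 | air_temp_C > 50)) {
    abort("`air_temp_C` must be finite and within -40..50 degC")
  }
  if (any(!is.finite(rel_humidity_pct)) ||
      any(rel_humidity_pct < 0 | rel_humidity_pct > 100)) {
    abort("`rel_humidity_pct` must be finite and within 0..100")
  }
  svp <- 6.112 * exp(17.67 * air_temp_C / (air_temp_C + 243.5))
  216.74 * (svp * rel_humidity_pct / 100) / (air_temp_C + 273.15)
}

#' Aggregate a weather series into nightly covariates
#'
#' For each night window, computes the five covariates used as predictors of
#' torpor responses: mean nightly air temperature, mean nightly absolute
#' humidity (converted per sample, then averaged), mean nightly wind speed,
#' total nightly rain, and the overnight barometric pressure change
#' `delta_bp` (pressure at the sample nearest sunrise minus pressure at the
#' sample nearest sunset; missing if either endpoint has no sample within
#' `bp_max_gap_min`). Sample membership is the half-open interval
#' `[sunset, sunrise_next)`. Nights with fewer than `min_coverage` of their
#' expected samples are emitted with missing covariates.
#'
#' @param samples Data frame with columns `timestamp` (POSIXct),
#'   `air_temp_C`, `rel_humidity_pct`, `pressure_hPa`, `rain_mm`,
#'   `wind_kmh`.
#' @param nights Night windows from [night_window()].
#' @param cadence_min Native station cadence in minutes (default 30).
#' @param min_coverage Minimum fraction of expected samples for a valid
#'   night (default 0.7).
#' @param bp_max_gap_min Maximum distance (minutes) from a window endpoint to
#'   the pressure sample used for `delta_bp` (default 45).
#' @return A tibble keyed by (`site`, `night_date`) with `sunset`,
#'   `sunrise_next`, `ta_mean`, `ah_mean`, `wind_mean`, `rain_total`,
#'   `delta_bp` and `n_samples`.
#' @export
nightly_aggregate <- function(samples, nights, cadence_min = 30,
                              min_coverage = 0.7, bp_max_gap_min = 45) {
  assert_cols(samples, c("timestamp", "air_temp_C", "rel_humidity_pct",
                         "pressure_hPa", "rain_mm", "wind_kmh"), "samples")
  assert_cols(nights, c("night_date", "sunset", "sunrise_next"), "nights")
  if (any(samples$rel_humidity_pct < 0 | samples$rel_humidity_pct > 100,
          na.rm = TRUE)) {
    abort("relative humidity outside 0..100")
  }
  if (any(samples$rain_mm < 0, na.rm = TRUE) ||
      any(samples$wind_kmh < 0, na.rm = TRUE)) {
    abort("rain and wind speed must be non-negative")
  }
  if (any(samples$pressure_hPa < 850 | samples$pressure_hPa > 1100,
          na.rm = TRUE)) {
    abort("barometric pressure outside 850..1100 hPa")
  }
  samples <- arrange(samples, .data$timestamp)
  t_num <- as.numeric(samples$timestamp)

  nearest_pressure <- function(target) {
    i <- which.min(abs(t_num - as.numeric(target)))
    if (length(i) == 0) return(NA_real_)
    if (abs(t_num[i] - as.numeric(target)) > bp_max_gap_min * 60) {
      return(NA_real_)
    }
    samples$pressure_hPa[i]
  }

  purrr::pmap_dfr(
    list(nights$night_date, nights$sunset, nights$sunrise_next,
         if ("site" %in% names(nights)) nights$site else
           rep(NA_character_, nrow(nights))),
    function(night_date, sunset, sunrise_next, site) {
      inside <- t_num >= as.numeric(sunset) & t_num < as.numeric(sunrise_next)
      night_min <- as.numeric(difftime(sunrise_next, sunset, units = "mins"))
      expected <- floor(night_min / cadence_min) + 1
      n_in <- sum(inside)
      base <- tibble(site = site, night_date = night_date,
                     sunset = sunset, sunrise_next = sunrise_next,
                     n_samples = n_in)
      if (n_in < min_coverage * expected) {
        return(mutate(base, ta_mean = NA_real_, ah_mean = NA_real_,
                      wind_mean = NA_real_, rain_total = NA_real_,
                      delta_bp = NA_real_))
      }
      s <- samples[inside, ]
      mutate(base,
             ta_mean = mean(s$air_temp_C),
             ah_mean = mean(absolute_humidity(s$air_temp_C,
                                              s$rel_humidity_pct)),
             wind_mean = mean(s$wind_kmh),
             rain_total = sum(s$rain_mm),
             delta_bp = nearest_pressure(sunrise_next) -
               nearest_pressure(sunset)) %>%
        select("site", "night_date", "sunset", "sunrise_next", "ta_mean",
               "ah_mean", "wind_mean", "rain_total", "delta_bp", "n_samples")
    }
  ) %>%
    select("site", "night_date", "sunset", "sunrise_next", "ta_mean",
           "ah_mean", "wind_mean", "rain_total", "delta_bp", "n_samples")
}
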