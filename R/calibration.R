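# Transmitter calibration: cubic pulse-interval -> temperature curves,
# pulse-log decoding onto a regular grid, and calibration-drift flagging.

#' Fit a cubic calibration curve for one transmitter
#'
#' Temperature-sensitive transmitters encode temperature in the interval
#' between pulses; each transmitter is calibrated in a water bath at several
#' known temperatures. This fits an ordinary least squares 3rd-order
#' polynomial of bath temperature on pulse interval. The fit is performed on
#' the centred pulse interval for numerical stability and the coefficients
#' are expanded back to the raw-interval basis.
#'
#' @param points Data frame of calibration points with columns
#'   `bath_temp_C` (0-45 degC) and `pulse_interval_ms` (> 0). A
#'   `transmitter_id` column, if present, must be constant.
#' @param transmitter_id Identifier for the transmitter; defaults to the
#'   `transmitter_id` column of `points` when present.
#' @return An object of class `calibration_curve`: a list with
#'   `transmitter_id`, `coefficients` (named c0..c3, temperature =
#'   c0 + c1*p + c2*p^2 + c3*p^3 for pulse interval p in ms),
#'   `valid_range` (min/max calibrated pulse interval), `fit_rmse` (degC),
#'   `n_points`, and `monotone` (whether the fitted cubic is monotone over
#'   `valid_range`).
#' @examples
#' pts <- data.frame(bath_temp_C = 2 + 0.01 * seq(500, 1500, length.out = 5),
#'                   pulse_interval_ms = seq(500, 1500, length.out = 5))
#' fit_calibration(pts, "tx1")
#' @export
fit_calibration <- function(points, transmitter_id = NULL) {
  assert_cols(points, c("bath_temp_C", "pulse_interval_ms"), "points")
  if (is.null(transmitter_id)) {
    ids <- unique(points$transmitter_id)
    if (length(ids) != 1) {
      abort("`points` must contain a single transmitter; pass `transmitter_id`")
    }
    transmitter_id <- ids
  }
  temp <- points$bath_temp_C
  p <- points$pulse_interval_ms
  if (any(!is.finite(temp)) || any(!is.finite(p))) {
    abort("calibration points must be finite")
  }
  if (any(temp < 0 | temp > 45)) {
    abort("bath temperatures must lie within 0-45 degC")
  }
  if (any(p <= 0)) {
    abort("pulse intervals must be positive")
  }
  if (length(unique(p)) < 4) {
    abort("calibration cubic is underdetermined: need >= 4 distinct pulse intervals")
  }
  ord <- order(p)
  if (is.unsorted(temp[ord]) && is.unsorted(rev(temp[ord]))) {
    warn(sprintf("transmitter %s: bath temperature is not monotone in pulse interval",
                 transmitter_id))
  }

  centre <- mean(p)
  u <- p - centre
  fit <- lm(temp ~ u + I(u^2) + I(u^3))
  b <- unname(coef(fit))
  # expand T = b0 + b1 u + b2 u^2 + b3 u^3, u = p - m, to raw powers of p
  m <- centre
  coefs <- c(
    c0 = b[1] - b[2] * m + b[3] * m^2 - b[4] * m^3,
    c1 = b[2] - 2 * b[3] * m + 3 * b[4] * m^2,
    c2 = b[3] - 3 * b[4] * m,
    c3 = b[4]
  )
  rmse <- sqrt(mean(stats::residuals(fit)^2))
  curve <- structure(
    list(
      transmitter_id = transmitter_id,
      coefficients = coefs,
      valid_range = range(p),
      fit_rmse = rmse,
      n_points = length(p),
      monotone = NA
    ),
    class = "calibration_curve"
  )
  curve$monotone <- curve_is_monotone(curve)
  if (!curve$monotone) {
    warn(sprintf("transmitter %s: fitted cubic is not monotone over its valid range",
                 transmitter_id))
  }
  curve
}

#' Fit calibration curves for every transmitter in a table
#'
#' @param points Data frame with columns `transmitter_id`, `bath_temp_C`,
#'   `pulse_interval_ms`.
#' @return A tibble with one row per transmitter: `transmitter_id`, a `curve`
#'   list-column of [fit_calibration()] objects, `fit_rmse` and `n_points`.
#' @export
fit_calibrations <- function(points) {
  assert_cols(points, c("transmitter_id", "bath_temp_C", "pulse_interval_ms"),
              "points")
  points %>%
    group_by(.data$transmitter_id) %>%
    dplyr::group_modify(function(d, key) {
      cv <- fit_calibration(d, key$transmitter_id)
      tibble(curve = list(cv), fit_rmse = cv$fit_rmse, n_points = cv$n_points)
    }) %>%
    ungroup()
}

curve_is_monotone <- function(curve, n_grid = 512) {
  p <- seq(curve$valid_range[1], curve$valid_range[2], length.out = n_grid)
  cf <- curve$coefficients
  d <- cf[["c1"]] + 2 * cf[["c2"]] * p + 3 * cf[["c3"]] * p^2
  all(d >= -1e-12) || all(d <= 1e-12)
}

#' @export
predict.calibration_curve <- function(object, pulse_interval_ms, ...) {
  cf <- object$coefficients
  p <- pulse_interval_ms
  cf[["c0"]] + cf[["c1"]] * p + cf[["c2"]] * p^2 + cf[["c3"]] * p^3
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> transmitter %s\n", x$transmitter_id))
  cat(sprintf("  T(p) = %.6g + %.6g p + %.6g p^2 + %.6g p^3  (p in ms)\n",
              x$coefficients[["c0"]], x$coefficients[["c1"]],
              x$coefficients[["c2"]], x$coefficients[["c3"]]))
  cat(sprintf("  valid range: %.1f-%.1f ms, fit RMSE %.3g degC, %d points%s\n",
              x$valid_range[1], x$valid_range[2], x$fit_rmse, x$n_points,
              if (isTRUE(x$monotone)) "" else " [non-monotone]"))
  invisible(x)
}

#' @export
tidy.calibration_curve <- function(x, ...) {
  tibble(term = names(x$coefficients), estimate = unname(x$coefficients))
}

#' @export
glance.calibration_curve <- function(x, ...) {
  tibble(
    transmitter_id = x$transmitter_id,
    fit_rmse = x$fit_rmse,
    n_points = x$n_points,
    range_min_ms = x$valid_range[1],
    range_max_ms = x$valid_range[2],
    monotone = x$monotone
  )
}

#' Decode a pulse log into a regular-grid skin-temperature trace
#'
#' Maps pulse intervals through a transmitter's calibration cubic and snaps
#' the resulting temperatures onto a regular sampling grid (default 10 min,
#' the logging cadence of the receiver stations). Records are assigned to the
#' nearest grid slot (ties to the earlier slot); multiple records in one slot
#' are averaged; slots with no record are kept as explicit missing samples.
#' Pulse intervals outside the calibrated range are decoded by extrapolating
#' the cubic and flagged. Decoded temperatures outside a plausible
#' -10 to 45 degC band are discarded as noise.
#'
#' @param records Data frame of pulse detections with columns `timestamp`
#'   (POSIXct), `transmitter_id` and `pulse_interval_ms`.
#' @param curve A [fit_calibration()] object for the records' transmitter.
#' @param sampling_interval Grid spacing in minutes (default 10).
#' @param bat_id Identifier for the animal; defaults to the transmitter id.
#' @param site,cave Optional identifiers carried into the trace.
#' @return A tibble with columns `bat_id`, `site`, `cave`, `timestamp`,
#'   `tsk_C` (NA for missing slots) and `extrapolated`. The grid covers the
#'   full record span; `sampling_interval` (minutes) is stored as an
#'   attribute.
#' @export
decode_trace <- function(records, curve, sampling_interval = 10,
                         bat_id = curve$transmitter_id,
                         site = NA_character_, cave = NA_character_) {
  assert_cols(records, c("timestamp", "transmitter_id", "pulse_interval_ms"),
              "records")
  records <- filter(records, .data$transmitter_id == curve$transmitter_id)
  if (nrow(records) == 0) {
    abort(sprintf("no pulse records for transmitter %s", curve$transmitter_id))
  }
  if (any(records$pulse_interval_ms <= 0)) {
    abort("pulse intervals must be positive")
  }
  records <- arrange(records, .data$timestamp)
  tz <- attr(records$timestamp, "tzone") %||% "UTC"
  step <- sampling_interval * 60

  t_num <- as.numeric(records$timestamp)
  origin <- floor(min(t_num) / step) * step
  k <- (t_num - origin) / step
  # nearest slot, ties (exactly half way) to the earlier slot
  frac <- k - floor(k)
  tie <- abs(frac - 0.5) < 1e-9
  slot <- ifelse(tie, floor(k), floor(k + 0.5))

  temp <- predict(curve, records$pulse_interval_ms)
  out_of_range <- records$pulse_interval_ms < curve$valid_range[1] |
    records$pulse_interval_ms > curve$valid_range[2]

  per_slot <- tibble(slot = slot, temp = temp, extrap = out_of_range) %>%
    group_by(.data$slot) %>%
    summarise(tsk_C = mean(.data$temp), extrapolated = any(.data$extrap),
              .groups = "drop")

  n_slots <- max(per_slot$slot) - min(per_slot$slot) + 1L
  grid <- tibble(slot = seq(min(per_slot$slot), max(per_slot$slot)))
  trace <- left_join(grid, per_slot, by = "slot") %>%
    mutate(
      bat_id = bat_id,
      site = site,
      cave = cave,
      timestamp = as.POSIXct(origin + .data$slot * step,
                             origin = "1970-01-01", tz = tz),
      extrapolated = dplyr::coalesce(.data$extrapolated, FALSE)
    ) %>%
    select("bat_id", "site", "cave", "timestamp", "tsk_C", "extrapolated")

  implausible <- !is.na(trace$tsk_C) & (trace$tsk_C < -10 | trace$tsk_C > 45)
  if (any(implausible)) {
    inform(sprintf("decode_trace: %d decoded sample(s) outside -10..45 degC set to missing",
                   sum(implausible)))
    trace$tsk_C[implausible] <- NA_real_
  }
  stopifnot(nrow(trace) == n_slots)
  attr(trace, "sampling_interval") <- sampling_interval
  trace
}

#' Flag non-linear calibration drift in a trace
#'
#' Some transmitters drift over a deployment: the apparent skin temperature
#' of the stable torpid plateau creeps up or down even though the bat's true
#' plateau is fixed by the cave temperature. Drifted traces remain usable for
#' bout timing, but torpid-temperature summaries should be suppressed. The
#' detector takes all samples inside long below-threshold (torpid) runs,
#' computes a daily median plateau level, regresses it on the day number by
#' ordinary least squares, and flags the trace when the fitted change across
#' the deployment exceeds `tolerance`.
#'
#' @param trace A decoded trace (see [decode_trace()]).
#' @param window_days Minimum number of plateau days required before drift is
#'   assessed (default 5); with fewer, the trace is not flagged and a warning
#'   is raised.
#' @param tolerance Flag when |fitted plateau change| across the deployment
#'   exceeds this many degC (default 1).
#' @param threshold Skin temperature ceiling (degC) defining torpid samples
#'   (default 32.2, the species-level onset threshold).
#' @param min_run Minimum run length (samples) of consecutive torpid samples
#'   for a run to count as a stable plateau (default 6, i.e. 1 h at 10-min
#'   sampling).
#' @return Logical drift flag, with attributes `slope_C_per_day`,
#'   `fitted_change_C` and `n_days`.
#' @export
flag_drift <- function(trace, window_days = 5, tolerance = 1,
                       threshold = 32.2, min_run = 6) {
  assert_cols(trace, c("timestamp", "tsk_C"), "trace")
  no_drift <- function(msg) {
    warn(msg)
    structure(FALSE, slope_C_per_day = NA_real_, fitted_change_C = NA_real_,
              n_days = 0L)
  }
  if (nrow(trace) == 0 || all(is.na(trace$tsk_C))) {
    return(no_drift("flag_drift: trace has no observed samples"))
  }
  torpid <- !is.na(trace$tsk_C) & trace$tsk_C < threshold
  r <- rle(torpid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run
  if (!any(keep)) {
    return(no_drift("flag_drift: no stable torpid plateau found"))
  }
  idx <- unlist(purrr::map2(starts[keep], ends[keep], seq))
  tz <- attr(trace$timestamp, "tzone") %||% "UTC"
  plateau <- tibble(
    day = as.numeric(as.Date(trace$timestamp[idx], tz = tz)),
    tsk = trace$tsk_C[idx]
  ) %>%
    group_by(.data$day) %>%
    summarise(level = median(.data$tsk), n = n(), .groups = "drop") %>%
    filter(.data$n >= 3)
  if (nrow(plateau) < window_days) {
    return(no_drift(sprintf(
      "flag_drift: only %d plateau day(s), need >= %d", nrow(plateau),
      window_days)))
  }
  fit <- lm(level ~ day, data = plateau)
  slope <- unname(coef(fit)[2])
  change <- slope * (max(plateau$day) - min(plateau$day))
  structure(abs(change) > tolerance,
            slope_C_per_day = slope,
            fitted_change_C = change,
            n_days = nrow(plateau))
}
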