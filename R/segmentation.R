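# Torpor/arousal/normothermia segmentation of a regular-grid skin
# temperature trace.
#
# Rules, applied to the sequence of grid samples classified as below
# threshold (B), at-or-above threshold (A) or missing (M):
#   1. A-runs shorter than `min_arousal_samples` flanked by B on both sides
#      are treated as part of the torpid run (default 1: no smoothing).
#   2. M-runs of length <= gap_limit flanked by B on both sides are bridged
#      (the bout continues through the short telemetry gap).
#   3. A maximal B-run of >= 3 samples is a torpor bout ("more than two
#      consecutive data points", i.e. > 10 min at 10-min sampling); its
#      onset is the run's first sample.
#   4. The bout ends at the first subsequent A sample (observed arousal,
#      half-open bout [onset, end)); a short (<= gap_limit) gap before that
#      A sample still counts as an observed arousal.
#   5. If instead the signal is lost for > gap_limit samples while the last
#      two observed inter-sample differences were both rising by more than
#      `rise_min_C`, the bat is taken to have rewarmed and flown out of
#      range: the bout ends at the last detection.
#   6. Any other loss (trace end, long gap without a rising trend) censors
#      the bout; censored bouts keep their last-detection timestamp but are
#      excluded from duration summaries and arousal-based products.

#' Segment a skin-temperature trace into torpor, arousal and normothermia
#'
#' @param trace Regular-grid trace (see [decode_trace()]): columns `bat_id`,
#'   `timestamp`, `tsk_C` (NA = missing slot); optional `site`, `cave`.
#' @param threshold Torpor onset threshold in degC (see
#'   [species_threshold()]).
#' @param nights Optional night windows from [night_window()] covering the
#'   trace span; required for `rel_sunset_h`, `is_night` and `touches_night`
#'   (NA otherwise).
#' @param gap_limit Maximum telemetry gap, in samples, bridged inside a bout
#'   (default 3, i.e. 30 min at 10-min sampling).
#' @param min_arousal_samples Minimum number of consecutive above-threshold
#'   samples that terminate a bout (default 1: a single above-threshold
#'   sample ends the bout).
#' @param rise_min_C Minimum rise per sampling step, over each of the last
#'   two observed steps, for a long gap to be read as an out-of-range
#'   arousal (default 0.5 degC).
#' @return An object of class `torpor_segmentation`: a list of three tibbles.
#'   `bouts` (`bat_id`, `site`, `cave`, `onset`, `end`, `duration_h`,
#'   `end_type` in observed_arousal/last_detection, `censored`), `arousals`
#'   (`bat_id`, `site`, `timestamp`, `rel_sunset_h`, `is_night`) and
#'   `normothermia` (`bat_id`, `site`, `start`, `end`, `duration_h`,
#'   `touches_night`).
#' @export
segment_trace <- function(trace, threshold, nights = NULL, gap_limit = 3,
                          min_arousal_samples = 1, rise_min_C = 0.5) {
  assert_cols(trace, c("bat_id", "timestamp", "tsk_C"), "trace")
  if (!is.finite(threshold)) abort("`threshold` must be finite")
  n <- nrow(trace)
  empty <- segmentation_result(
    bouts_empty(), arousals_empty(), normothermia_empty(),
    threshold, gap_limit, min_arousal_samples, rise_min_C)
  if (n == 0 || all(is.na(trace$tsk_C))) return(empty)

  dt <- diff(as.numeric(trace$timestamp))
  if (length(dt) > 0 && (max(dt) - min(dt)) > 1) {
    abort("`trace` must be on a regular time grid (use decode_trace())")
  }
  step_h <- if (length(dt) > 0) dt[1] / 3600 else NA_real_
  tz <- attr(trace$timestamp, "tzone") %||% "UTC"
  bat <- trace$bat_id[1]
  site <- if ("site" %in% names(trace)) trace$site[1] else NA_character_
  cave <- if ("cave" %in% names(trace)) trace$cave[1] else NA_character_

  x <- trace$tsk_C
  st <- ifelse(is.na(x), 2L, ifelse(x < threshold, 1L, 0L)) # 0 A, 1 B, 2 M
  st <- recode_runs(st, from = 0L, max_len = min_arousal_samples - 1L)
  st <- recode_runs(st, from = 2L, max_len = gap_limit)

  r <- rle(st)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  v <- r$values
  nr <- length(v)

  b_onset <- b_end <- integer(0)
  b_type <- character(0)
  b_cens <- logical(0)
  for (j in seq_len(nr)) {
    if (v[j] != 1L || r$lengths[j] < 3L) next
    onset_i <- run_start[j]
    last_i <- run_end[j]
    end_i <- NA_integer_
    end_type <- NA_character_
    censored <- FALSE
    if (j == nr) {
      censored <- TRUE
      end_i <- last_i
    } else if (v[j + 1] == 0L) {
      end_i <- run_start[j + 1]
      end_type <- "observed_arousal"
    } else { # missing run follows (never B: adjacent runs differ)
      if (j + 1 < nr && r$lengths[j + 1] <= gap_limit && v[j + 2] == 0L) {
        end_i <- run_start[j + 2]
        end_type <- "observed_arousal"
      } else {
        rising <- run_is_rising(x, onset_i, last_i, rise_min_C)
        end_i <- last_i
        if (rising) {
          end_type <- "last_detection"
        } else {
          censored <- TRUE
        }
      }
    }
    b_onset <- c(b_onset, onset_i)
    b_end <- c(b_end, end_i)
    b_type <- c(b_type, end_type)
    b_cens <- c(b_cens, censored)
  }
  if (length(b_onset) == 0) return(empty)
  bouts <- tibble(
    bat_id = rep(bat, length(b_onset)), site = site, cave = cave,
    onset = trace$timestamp[b_onset],
    end = trace$timestamp[b_end],
    duration_h = as.numeric(trace$timestamp[b_end] -
                              trace$timestamp[b_onset], units = "hours"),
    end_type = b_type,
    censored = b_cens
  )

  # arousal events: every non-censored bout ends in one
  ar_idx <- which(!bouts$censored)
  arousals <- tibble(
    bat_id = bat, site = site,
    timestamp = bouts$end[ar_idx],
    rel_sunset_h = rep(NA_real_, length(ar_idx)),
    is_night = rep(NA, length(ar_idx))
  )
  if (!is.null(nights) && nrow(arousals) > 0) {
    arousals$rel_sunset_h <- arousal_rel_sunset(arousals$timestamp, nights,
                                                tz = tz, strict = FALSE)
    arousals$is_night <- is_night_time(arousals$timestamp, nights)
  }

  # normothermia: arousal -> next torpor onset
  normo <- list()
  for (k in seq_len(nrow(bouts))) {
    if (bouts$censored[k] || k == nrow(bouts)) next
    start <- bouts$end[k]
    nxt <- bouts$onset[k + 1]
    if (nxt <= start) next
    normo[[length(normo) + 1]] <- tibble(
      bat_id = bat, site = site, start = start, end = nxt,
      duration_h = as.numeric(difftime(nxt, start, units = "hours")),
      touches_night = if (is.null(nights)) NA else
        is_night_time(start, nights) || is_night_time(nxt, nights)
    )
  }
  normothermia <- if (length(normo)) bind_rows(normo) else normothermia_empty()

  segmentation_result(bouts, arousals, normothermia,
                      threshold, gap_limit, min_arousal_samples, rise_min_C)
}

# Recode runs of `from` with length <= max_len into B (1) when flanked by B
# on both sides.
recode_runs <- function(st, from, max_len) {
  if (max_len < 1) return(st)
  r <- rle(st)
  v <- r$values
  if (length(v) >= 3) {
    for (j in 2:(length(v) - 1)) {
      if (v[j] == from && r$lengths[j] <= max_len &&
          v[j - 1] == 1L && v[j + 1] == 1L) {
        v[j] <- 1L
      }
    }
  }
  inverse.rle(list(values = v, lengths = r$lengths))
}

run_is_rising <- function(x, onset_i, last_i, rise_min_C) {
  if (last_i - onset_i < 2) return(FALSE)
  d1 <- x[last_i] - x[last_i - 1]
  d2 <- x[last_i - 1] - x[last_i - 2]
  isTRUE(d1 > rise_min_C && d2 > rise_min_C)
}

segmentation_result <- function(bouts, arousals, normothermia, threshold,
                                gap_limit, min_arousal_samples, rise_min_C) {
  structure(
    list(bouts = bouts, arousals = arousals, normothermia = normothermia,
         params = list(threshold = threshold, gap_limit = gap_limit,
                       min_arousal_samples = min_arousal_samples,
                       rise_min_C = rise_min_C)),
    class = "torpor_segmentation"
  )
}

bouts_empty <- function() {
  tibble(bat_id = character(), site = character(), cave = character(),
         onset = as.POSIXct(character()), end = as.POSIXct(character()),
         duration_h = numeric(), end_type = character(),
         censored = logical())
}

arousals_empty <- function() {
  tibble(bat_id = character(), site = character(),
         timestamp = as.POSIXct(character()),
         rel_sunset_h = numeric(), is_night = logical())
}

normothermia_empty <- function() {
  tibble(bat_id = character(), site = character(),
         start = as.POSIXct(character()), end = as.POSIXct(character()),
         duration_h = numeric(), touches_night = logical())
}

#' @export
print.torpor_segmentation <- function(x, ...) {
  cat(sprintf("<torpor_segmentation> threshold %.1f degC\n",
              x$params$threshold))
  cat(sprintf("  %d bout(s) (%d censored), %d arousal(s), %d normothermia bout(s)\n",
              nrow(x$bouts), sum(x$bouts$censored), nrow(x$arousals),
              nrow(x$normothermia)))
  invisible(x)
}

#' Segment many traces at once
#'
#' @param traces A trace tibble holding one or more bats (split on
#'   `bat_id`), or a list of per-bat traces.
#' @inheritParams segment_trace
#' @return A `torpor_segmentation` with the per-bat results row-bound.
#' @export
segment_traces <- function(traces, threshold, nights = NULL, gap_limit = 3,
                           min_arousal_samples = 1, rise_min_C = 0.5) {
  if (is.data.frame(traces)) {
    traces <- split(traces, traces$bat_id)
  }
  parts <- purrr::map(traces, segment_trace, threshold = threshold,
                      nights = nights, gap_limit = gap_limit,
                      min_arousal_samples = min_arousal_samples,
                      rise_min_C = rise_min_C)
  segmentation_result(
    bind_rows(purrr::map(parts, "bouts")),
    bind_rows(purrr::map(parts, "arousals")),
    bind_rows(purrr::map(parts, "normothermia")),
    threshold, gap_limit, min_arousal_samples, rise_min_C
  )
}

#' Arousal time relative to sunset
#'
#' Signed hours from the sunset of the event's civil night (the noon-to-noon
#' day containing the event): negative before sunset, positive after. An
#' arousal 9 minutes after sunset is +0.15 h.
#'
#' @param timestamps POSIXct event times.
#' @param nights Night windows from [night_window()].
#' @param tz Timezone for the civil-day convention; defaults to the
#'   timezone of the `nights` sunsets.
#' @param strict Error when an event's night is not covered by `nights`
#'   (default TRUE); otherwise NA.
#' @return Signed hours relative to sunset.
#' @export
arousal_rel_sunset <- function(timestamps, nights, tz = NULL, strict = TRUE) {
  assert_cols(nights, c("night_date", "sunset"), "nights")
  tz <- tz %||% attr(nights$sunset, "tzone") %||% "UTC"
  nd <- civil_night_date(timestamps, tz)
  i <- match(nd, nights$night_date)
  if (strict && any(is.na(i))) {
    abort("no night window available for some event date(s)")
  }
  as.numeric(difftime(timestamps, nights$sunset[i], units = "hours"))
}

#' Completed nights in torpor at a given night
#'
#' Counts how many nights a bat has been in the current torpor bout when a
#' given night is evaluated: 0 on the night the bout started, 1 the next
#' night, and so on. Used as a predictor of nightly arousal probability.
#'
#' @param onset Torpor bout onset (POSIXct).
#' @param end Torpor bout end (POSIXct).
#' @param night_date Date(s) of the evaluated night(s) (sunset date).
#' @param tz Timezone of the site.
#' @return Integer count(s).
#' @export
days_in_torpor <- function(onset, end, night_date, tz = "UTC") {
  night_date <- as.Date(night_date)
  n0 <- civil_night_date(onset, tz)
  n1 <- civil_night_date(end, tz)
  if (any(night_date < n0 | night_date > n1)) {
    abort("night does not overlap the torpor bout")
  }
  as.integer(night_date - n0)
}
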