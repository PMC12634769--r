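# Analysis-ready model frames for the three torpor response models:
# torpor bout duration (gamma, log link), nightly arousal probability
# (binomial) and nightly normothermia duration (Gaussian on sqrt scale).
# The penalized-spline mixed-model fitting itself is out of scope: the
# frames are exported for external fitting, and nonparametric Spearman
# sign diagnostics are provided in-package.

covariate_cols <- c("ta_mean", "ah_mean", "wind_mean", "rain_total",
                    "delta_bp")

#' Build the three model frames
#'
#' Joins segmentation output to nightly weather covariates:
#' * `tbd` (torpor bout duration): one row per non-censored bout, with the
#'   covariates of the night the bout started and the day of year of that
#'   night.
#' * `arousal` (nightly arousal probability): one row per (bat, night) a bat
#'   was in torpor, with `aroused` = 1 on the night the bout ended (by
#'   observed arousal or last detection - a last detection is treated as an
#'   arousal) and 0 otherwise, plus `days_in_torpor`.
#' * `nd` (normothermia duration): one row per night-touching normothermia
#'   bout, with the covariates of the night the bout started.
#'
#' A bout's nights run from the civil night of its onset to the last night
#' whose sunset precedes the bout end. Rows whose night has missing weather
#' covariates are dropped (a count is reported). Censored bouts contribute
#' to no frame.
#'
#' @param segmentation A [segment_trace()]/[segment_traces()] result, or a
#'   list with `bouts`, `arousals`, `normothermia` tables.
#' @param nightly_weather Output of [nightly_aggregate()].
#' @param nights Night windows from [night_window()].
#' @param tz Timezone for civil-night conventions; defaults to the `nights`
#'   sunset timezone.
#' @return A named list of tibbles `tbd`, `arousal`, `nd`.
#' @export
build_model_frames <- function(segmentation, nightly_weather, nights,
                               tz = NULL) {
  bouts <- segmentation$bouts
  normo <- segmentation$normothermia
  assert_cols(nightly_weather, c("night_date", covariate_cols),
              "nightly_weather")
  assert_cols(nights, c("night_date", "sunset"), "nights")
  tz <- tz %||% attr(nights$sunset, "tzone") %||% "UTC"
  weather <- select(nightly_weather, "night_date",
                    dplyr::all_of(covariate_cols))

  join_weather <- function(df) {
    out <- left_join(df, weather, by = "night_date") %>%
      mutate(doy = lubridate::yday(.data$night_date))
    complete <- stats::complete.cases(out[, covariate_cols])
    if (any(!complete)) {
      inform(sprintf("model frames: dropped %d row(s) with missing nightly covariates",
                     sum(!complete)))
    }
    out[complete, , drop = FALSE]
  }

  live <- filter(bouts, !.data$censored)

  tbd <- live %>%
    mutate(night_date = civil_night_date(.data$onset, tz)) %>%
    select("bat_id", "site", "night_date", "duration_h") %>%
    join_weather()

  arousal <- if (nrow(live) == 0) {
    tibble(bat_id = character(), site = character(),
           night_date = as.Date(character()), days_in_torpor = integer(),
           aroused = integer())
  } else {
    n0 <- civil_night_date(live$onset, tz)
    # last night whose sunset precedes the bout end
    srt <- sort(nights$sunset)
    pos <- findInterval(as.numeric(live$end), as.numeric(srt))
    n1 <- as.Date(ifelse(pos >= 1,
                         civil_night_date(srt[pmax(pos, 1)], tz), n0),
                  origin = "1970-01-01")
    n1 <- pmax(n1, n0)
    n_nights <- as.integer(n1 - n0) + 1L
    idx <- rep(seq_len(nrow(live)), n_nights)
    offs <- sequence(n_nights) - 1L
    tibble(bat_id = live$bat_id[idx], site = live$site[idx],
           night_date = n0[idx] + offs,
           days_in_torpor = offs,
           aroused = as.integer(offs == n_nights[idx] - 1L)) %>%
      join_weather()
  }

  nd_frame <- normo %>%
    filter(!is.na(.data$touches_night) & .data$touches_night) %>%
    mutate(night_date = civil_night_date(.data$start, tz)) %>%
    select("bat_id", "site", "night_date", "duration_h") %>%
    join_weather()

  list(tbd = tbd, arousal = arousal, nd = nd_frame)
}

#' Spearman sign diagnostics for a model frame
#'
#' Rank correlation of each nightly covariate (and day of year, and
#' `days_in_torpor` where present) with the frame's response - a
#' distribution-free check of effect directions ahead of any external
#' smooth-model fit.
#'
#' @param frame One of the [build_model_frames()] tibbles.
#' @param response Response column name (`"duration_h"` or `"aroused"`).
#' @param covariates Covariate columns (defaults to the five nightly
#'   covariates plus `doy` and, if present, `days_in_torpor`).
#' @return A tibble with `covariate`, `rho`, `p_value`, `n`.
#' @export
frame_sign_diagnostics <- function(frame, response,
                                   covariates = NULL) {
  if (is.null(covariates)) {
    covariates <- intersect(c(covariate_cols, "doy", "days_in_torpor"),
                            names(frame))
  }
  assert_cols(frame, c(response, covariates), "frame")
  purrr::map_dfr(covariates, function(cv) {
    ok <- is.finite(frame[[cv]]) & is.finite(frame[[response]])
    if (sum(ok) < 3 || sd(frame[[cv]][ok]) == 0 ||
        sd(frame[[response]][ok]) == 0) {
      return(tibble(covariate = cv, rho = NA_real_, p_value = NA_real_,
                    n = sum(ok)))
    }
    ct <- suppressWarnings(
      cor.test(frame[[cv]][ok], frame[[response]][ok], method = "spearman"))
    tibble(covariate = cv, rho = unname(ct$estimate),
           p_value = ct$p.value, n = sum(ok))
  })
}
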