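# Descriptive summaries: per-site torpor bout statistics, nocturnality
# percentages, and body-mass change tables.

#' Per-site torpor bout summaries
#'
#' Computes, for each site and overall: bout and individual counts, mean,
#' sample SD (n - 1), minimum and maximum bout duration (0.1 h precision,
#' the maximum also in days), the percentage of bouts longer/shorter than
#' 24 h, and - when arousal and normothermia tables are supplied - the
#' percentage of arousals and of normothermia bouts occurring at night.
#' Censored (deployment-truncated) bouts are excluded.
#'
#' @param bouts Bout table from [segment_trace()] (or any data frame with
#'   `bat_id`, `site`, `duration_h`, `censored`).
#' @param arousals Optional arousal table with `site` and `is_night`.
#' @param normothermia Optional normothermia table with `site` and
#'   `touches_night`.
#' @return A tibble with one row per site plus a row with `site = "all"`.
#' @export
bout_summaries <- function(bouts, arousals = NULL, normothermia = NULL) {
  assert_cols(bouts, c("bat_id", "site", "duration_h", "censored"), "bouts")
  bouts <- filter(bouts, !.data$censored)
  if (nrow(bouts) == 0) {
    return(tibble(site = character(), n_bouts = integer(),
                  n_individuals = integer(), mean_duration_h = numeric(),
                  sd_duration_h = numeric(), min_duration_h = numeric(),
                  max_duration_h = numeric(), max_duration_d = numeric(),
                  pct_gt_24h = numeric(), pct_lt_24h = numeric(),
                  pct_arousals_night = numeric(),
                  pct_normothermia_night = numeric()))
  }
  one_group <- function(b, label) {
    tibble(
      site = label,
      n_bouts = nrow(b),
      n_individuals = n_distinct(b$bat_id),
      mean_duration_h = round(mean(b$duration_h), 1),
      sd_duration_h = round(sd(b$duration_h), 1),
      min_duration_h = round(min(b$duration_h), 1),
      max_duration_h = round(max(b$duration_h), 1),
      max_duration_d = hours_to_days(max(b$duration_h)),
      pct_gt_24h = round(100 * mean(b$duration_h > 24), 1),
      pct_lt_24h = round(100 * mean(b$duration_h < 24), 1),
      pct_arousals_night = pct_night(arousals, label, "is_night"),
      pct_normothermia_night = pct_night(normothermia, label,
                                         "touches_night")
    )
  }
  sites <- sort(unique(bouts$site))
  bind_rows(
    purrr::map_dfr(sites, function(s) one_group(bouts[bouts$site == s, ], s)),
    one_group(bouts, "all")
  )
}

pct_night <- function(tbl, site_label, col) {
  if (is.null(tbl) || nrow(tbl) == 0) return(NA_real_)
  if (site_label != "all") tbl <- tbl[tbl$site == site_label, ]
  v <- tbl[[col]]
  v <- v[!is.na(v)]
  if (length(v) == 0) return(NA_real_)
  round(100 * mean(v), 1)
}

#' Ratio of mean bout duration between the extreme sites
#'
#' Longest site mean over shortest site mean, computed on the 0.1 h rounded
#' site means and reported at 0.1 precision (e.g. 30.8 h vs 6.7 h gives 4.6).
#'
#' @param summary A [bout_summaries()] table.
#' @return The duration ratio as a single number.
#' @export
duration_ratio <- function(summary) {
  s <- filter(summary, .data$site != "all")
  if (nrow(s) < 2) abort("need at least two sites for a duration ratio")
  round(max(s$mean_duration_h) / min(s$mean_duration_h), 1)
}

mass_timepoints <- c("late_summer", "early_winter", "mid_winter",
                     "late_winter", "early_spring")

validate_mass_records <- function(records) {
  assert_cols(records, c("site", "sex", "timepoint", "mass_g"), "records")
  bad <- !records$timepoint %in% mass_timepoints
  if (any(bad)) {
    abort(sprintf("unknown timepoint(s): %s",
                  paste(unique(records$timepoint[bad]), collapse = ", ")))
  }
  if (any(records$mass_g <= 5 | records$mass_g >= 30)) {
    abort("body mass outside the plausible 5-30 g range for this species")
  }
  invisible(records)
}

#' Group mean body mass per timepoint
#'
#' @param records Capture records with `site`, `sex`, `timepoint`, `mass_g`.
#' @param by Grouping columns besides `timepoint` (default site and sex;
#'   use `"site"` for site-level means).
#' @return A tibble of group means, sample SDs and counts per timepoint.
#' @export
mass_summary <- function(records, by = c("site", "sex")) {
  validate_mass_records(records)
  records %>%
    group_by(dplyr::across(dplyr::all_of(c(by, "timepoint")))) %>%
    summarise(mean_g = mean(.data$mass_g), sd_g = sd(.data$mass_g),
              n = n(), .groups = "drop") %>%
    mutate(timepoint = factor(.data$timepoint, levels = mass_timepoints)) %>%
    arrange(dplyr::across(dplyr::all_of(by)), .data$timepoint)
}

#' Body-mass change between two timepoints
#'
#' Absolute (g) and percent change of the group mean body mass between two
#' named timepoints, the percent computed on the earlier timepoint's group
#' mean and both rounded to 0.1. Changes are computed on group means rather
#' than paired individuals because tagged bats are not recaptured. Groups
#' missing either timepoint are emitted with missing changes.
#'
#' @inheritParams mass_summary
#' @param from,to Timepoint names (see the five-point seasonal design:
#'   late_summer, early_winter, mid_winter, late_winter, early_spring).
#' @return A tibble per group: `mean_from`, `mean_to`, `change_g`,
#'   `change_pct`, `n_from`, `n_to`.
#' @examples
#' rec <- data.frame(site = "cold", sex = rep(c("f", "m"), each = 4),
#'                   timepoint = rep(c("late_summer", "early_winter"), 4),
#'                   mass_g = c(14.7, 16.7, 14.9, 16.9, 14.7, 16.8, 14.9, 16.8))
#' body_mass_changes(rec, "late_summer", "early_winter", by = "site")
#' @export
body_mass_changes <- function(records, from = "late_summer",
                              to = "early_winter", by = c("site", "sex")) {
  stopifnot(from %in% mass_timepoints, to %in% mass_timepoints)
  ms <- mass_summary(records, by = by)
  wide <- ms %>%
    select(dplyr::all_of(by), "timepoint", "mean_g", "n") %>%
    filter(.data$timepoint %in% c(from, to)) %>%
    tidyr::pivot_wider(names_from = "timepoint",
                       values_from = c("mean_g", "n"))
  col_or_na <- function(nm) {
    if (nm %in% names(wide)) wide[[nm]] else rep(NA_real_, nrow(wide))
  }
  mean_from <- col_or_na(paste0("mean_g_", from))
  mean_to <- col_or_na(paste0("mean_g_", to))
  n_from <- col_or_na(paste0("n_", from))
  n_to <- col_or_na(paste0("n_", to))
  dplyr::bind_cols(
    wide[, by, drop = FALSE],
    tibble(
      from = rep(from, nrow(wide)), to = rep(to, nrow(wide)),
      mean_from = mean_from, mean_to = mean_to,
      change_g = round(mean_to - mean_from, 1),
      change_pct = round(100 * (mean_to - mean_from) / mean_from, 1),
      n_from = n_from, n_to = n_to
    )
  )
}
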