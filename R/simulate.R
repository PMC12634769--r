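# Ground-truthed synthetic biologging generator: weather series,
# torpor-arousal schedules with a weather-dependent nightly arousal hazard,
# Newtonian skin-temperature traces, calibration-encoded pulse logs with
# dropouts, and site/sex-structured body-mass records.

#' Simulation configuration
#'
#' Bundles the site, weather, bat, arousal-hazard and dropout parameters of
#' the generator. Two presets mirror the study's hibernacula: `"cold"` (a
#' high-elevation karst site, 10.6 degC cave, long multiday bouts) and
#' `"warm"` (a coastal site, 16.1 degC cave, short sub-daily bouts).
#' Defaults are tuned so default cohorts land near the observed site mean
#' bout durations (about 31 h cold, 7-8 h warm); the tuning constants are
#' all visible here and in the returned object.
#'
#' @param preset `"cold"` or `"warm"`.
#' @param n_bats Number of simulated bats (default 20).
#' @param days Length of the simulated winter in days (default 90).
#' @param start First simulated date (default 2023-06-01).
#' @param seed Integer seed; identical configurations (including the seed)
#'   reproduce byte-identical outputs.
#' @param ... Named overrides for any nested parameter, e.g.
#'   `bat = list(tsk_sd = 0)` or `hazard = list(b_ta = 0)` (partial lists
#'   are merged into the preset).
#' @return A list of class `sim_config` with components `site`, `weather`,
#'   `bat`, `hazard`, `dropout`, `n_bats`, `days`, `start`, `seed`.
#' @export
sim_config <- function(preset = c("cold", "warm"), n_bats = 20, days = 90,
                       start = as.Date("2023-06-01"), seed = 1, ...) {
  preset <- match.arg(preset)
  cold <- preset == "cold"
  cfg <- list(
    preset = preset,
    n_bats = n_bats,
    days = days,
    start = as.Date(start),
    seed = as.integer(seed),
    site = list(
      name = preset,
      lat = if (cold) -33.8 else -31.1,
      lon = if (cold) 150.0 else 152.7,
      tz = "Australia/Sydney",
      cave_temp_C = if (cold) 10.6 else 16.1,
      mean_mass_g = if (cold) 15.6 else 15.0
    ),
    weather = list(
      ta_mean = if (cold) 6 else 12,      # winter reference air temp, degC
      seasonal_amp = 2.5,                  # depth of the mid-winter trough
      diel_amp = if (cold) 4 else 3.5,     # half daily range
      ar1 = 0.8, ar_sd = 2.5,              # 30-min AR(1) anomaly
      synoptic_amp = 3,                    # multi-day cold/warm spells, degC
      synoptic_period_d = 10,              # spell length scale, days
      rh_base = if (cold) 75 else 80, rh_slope = 2, rh_sd = 4,
      bp_mean = 1013, bp_amp = 7, bp_period_d = 6, bp_ar1 = 0.9, bp_sd = 1,
      rain_p = 0.03, rain_shape = 0.8, rain_scale = 2.5,
      wind_meanlog = log(9), wind_sdlog = 0.45
    ),
    bat = list(
      t_norm_C = 35.5,                     # normothermic skin temperature
      cooling_k_h = if (cold) 0.8 else 1,  # Newtonian cooling constant, /h
      rewarm_C_min = 0.5,                  # linear rewarming rate
      tsk_sd = 0.2,                        # sensor noise, degC
      threshold_C = 32.2,                  # onset threshold for truth times
      kappa = if (cold) 4 else 2,          # arousal timing concentration
      arousal_offset_h = if (cold) 0.15 else 0.28, # mode after sunset
      pre_sunset_compress = 0.25,          # shrink pre-sunset deviations
      nd_meanlog = if (cold) log(6.5) - 0.4^2 / 2 else log(9.1) - 0.32^2 / 2,
      nd_sdlog = if (cold) 0.4 else 0.32,  # nightly normothermia, lognormal h
      day_bouts_lambda = if (cold) 0 else 1.3, # extra sub-bouts per torpor day
      min_sub_h = 1.5,                     # shortest sub-bout
      interruption_meanlog = log(0.85), interruption_sdlog = 0.25,
      min_first_bout_h = 6
    ),
    hazard = list(                         # logit P(arouse on night) =
      b0 = if (cold) -0.75 else 0.2,       #   b0 + b_ta * ta_mean
      b_ta = if (cold) 0.25 else 0.12,     #      + b_days * days_in_torpor
      b_days = if (cold) 0.45 else 0.5
    ),
    dropout = list(
      p_dropout = 0.05,                    # per-sample missed detection
      rewarm_loss_p = 0.3,                 # P(bat leaves range at arousal)
      forage_gap_h = 3,                    # out-of-range span after leaving
      departure_C = 32.2,                  # Tsk at which a leaver disappears
      drift_C_per_day = 0                  # injected calibration drift
    )
  )
  overrides <- list(...)
  for (nm in names(overrides)) {
    if (!nm %in% names(cfg)) abort(sprintf("unknown sim_config field `%s`", nm))
    if (is.list(cfg[[nm]]) && is.list(overrides[[nm]])) {
      bad <- setdiff(names(overrides[[nm]]), names(cfg[[nm]]))
      if (length(bad)) {
        abort(sprintf("unknown %s parameter(s): %s", nm,
                      paste(bad, collapse = ", ")))
      }
      cfg[[nm]][names(overrides[[nm]])] <- overrides[[nm]]
    } else {
      cfg[[nm]] <- overrides[[nm]]
    }
  }
  structure(cfg, class = "sim_config")
}

sim_span <- function(config) {
  tz <- config$site$tz
  t0 <- as.POSIXct(paste(config$start, "12:00:00"), tz = tz)
  list(t_start = t0, t_end = t0 + config$days * 86400, tz = tz)
}

#' Simulate a 30-min weather-station series
#'
#' Air temperature is a seasonal sinusoid (trough at mid-winter) plus a diel
#' sinusoid (peak mid-afternoon) plus AR(1) noise; relative humidity is
#' anticorrelated with the temperature anomaly and clipped to 20-100;
#' pressure is a slow synoptic sinusoid plus AR(1) noise; rain is
#' Bernoulli-gamma bursts; wind is lognormal.
#'
#' @param config A [sim_config()].
#' @param seed Optional seed; when NULL the caller's RNG stream is used.
#' @return A tibble with `timestamp` (30-min cadence, site timezone),
#'   `air_temp_C`, `rel_humidity_pct`, `pressure_hPa`, `rain_mm`,
#'   `wind_kmh`.
#' @export
simulate_weather <- function(config, seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  w <- config$weather
  tz <- config$site$tz
  t0 <- as.POSIXct(paste(config$start, "00:00:00"), tz = tz)
  n <- (config$days + 2) * 48
  timestamp <- t0 + 1800 * (seq_len(n) - 1)
  lt <- lubridate::with_tz(timestamp, tz)
  doy <- lubridate::yday(lt)
  hour <- lubridate::hour(lt) + lubridate::minute(lt) / 60

  ar_noise <- function(phi, marginal_sd, n) {
    if (marginal_sd <= 0) return(rep(0, n))
    innov <- rnorm(n, 0, marginal_sd * sqrt(1 - phi^2))
    as.numeric(stats::filter(innov, phi, method = "recursive"))
  }

  el_days <- as.numeric(timestamp - timestamp[1], units = "days")
  syn_phase <- runif(1, 0, 2 * pi)
  temp <- w$ta_mean -
    w$seasonal_amp * cos(2 * pi * (doy - 196) / 365.25) +
    w$diel_amp * cos(2 * pi * (hour - 14) / 24) +
    w$synoptic_amp * sin(2 * pi * el_days / w$synoptic_period_d + syn_phase) +
    ar_noise(w$ar1, w$ar_sd, n)
  rh <- pmin(pmax(w$rh_base - w$rh_slope * (temp - mean(temp)) +
                    rnorm(n, 0, w$rh_sd), 20), 100)
  phase <- runif(1, 0, 2 * pi)
  bp <- w$bp_mean + w$bp_amp * sin(2 * pi * as.numeric(timestamp - timestamp[1],
                                                       units = "days") /
                                     w$bp_period_d + phase) +
    ar_noise(w$bp_ar1, w$bp_sd, n)
  rain <- rbinom(n, 1, w$rain_p) * rgamma(n, w$rain_shape,
                                          scale = w$rain_scale)
  wind <- rlnorm(n, w$wind_meanlog, w$wind_sdlog)
  tibble(timestamp = timestamp, air_temp_C = temp, rel_humidity_pct = rh,
         pressure_hPa = bp, rain_mm = rain, wind_kmh = wind)
}

# True nightly mean air temperature (generator-side covariate for the
# arousal hazard), named by night date.
sim_nightly_ta <- function(weather, nights) {
  t_num <- as.numeric(weather$timestamp)
  ta <- vapply(seq_len(nrow(nights)), function(i) {
    inside <- t_num >= as.numeric(nights$sunset[i]) &
      t_num < as.numeric(nights$sunrise_next[i])
    if (!any(inside)) return(NA_real_)
    mean(weather$air_temp_C[inside])
  }, numeric(1))
  setNames(ta, as.character(nights$night_date))
}

#' Simulate one bat's torpor-arousal schedule and skin-temperature trace
#'
#' The bat alternates torpor and normothermia. On each night in torpor the
#' bat arouses with probability `plogis(b0 + b_ta * ta_mean + b_days *
#' days_in_torpor)`; the arousal instant is drawn von Mises around sunset
#' plus a configured offset. Normothermia duration is lognormal. At the
#' warm preset the day's torpor interval may be split into several short
#' sub-bouts separated by brief normothermic interruptions
#' (`day_bouts_lambda`), reproducing sub-daily torpor at mild roosts. Skin
#' temperature follows Newtonian cooling toward the cave temperature during
#' torpor, `Tsk(t) = T_cave + (T_norm - T_cave) exp(-k t)`, and linear
#' rewarming at the configured rate; ground truth (including the instants
#' the cooling and rewarming curves cross the onset threshold) is recorded
#' before any noise or dropout.
#'
#' @param config A [sim_config()].
#' @param nightly_ta Named vector of true nightly mean air temperature by
#'   night date (see the cohort wrapper [simulate_cohort()]).
#' @param nights Night windows covering the span.
#' @param bat_id Identifier for the simulated bat.
#' @param seed Optional seed; when NULL the caller's RNG stream is used.
#' @return A list with `truth` (one row per torpor bout: `onset`,
#'   `arousal`, `onset_cross`, `arousal_cross`, `torpor_len_h`, `final`,
#'   `censored`) and `trace` (10-min grid `bat_id`, `site`, `timestamp`,
#'   `tsk_C`).
#' @export
simulate_bat <- function(config, nightly_ta, nights, bat_id = "bat01",
                         seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  sp <- sim_span(config)
  bp <- config$bat
  hz <- config$hazard
  cave <- config$site$cave_temp_C
  thr <- bp$threshold_C
  k <- bp$cooling_k_h
  rate_h <- bp$rewarm_C_min * 60
  t_end <- as.numeric(sp$t_end)
  sunsets <- as.numeric(nights$sunset)
  night_dates <- as.numeric(nights$night_date)
  ta_by_night <- unname(nightly_ta[as.character(nights$night_date)])

  cool_T <- function(len_h) cave + (bp$t_norm_C - cave) * exp(-k * len_h)
  cross_h <- log((bp$t_norm_C - cave) / (thr - cave)) / k
  rewarm_h <- function(T_from) (bp$t_norm_C - T_from) / rate_h

  # accumulated numerics (seconds since epoch / hours / flags)
  o_on <- o_ar <- o_len <- numeric(0)
  o_final <- o_cens <- logical(0)

  onset <- as.numeric(sp$t_start) + runif(1, 2, 10) * 3600
  while (onset < t_end - 3600) {
    n0 <- as.numeric(civil_night_date(onset_posix(onset, sp$tz), sp$tz))
    cand <- which(night_dates > n0 &
                    sunsets > onset + bp$min_first_bout_h * 3600)
    arousal <- NA_real_
    for (i in cand) {
      ta <- ta_by_night[i]
      if (is.na(ta)) next
      d <- night_dates[i] - n0
      p <- plogis(hz$b0 + hz$b_ta * ta + hz$b_days * d)
      if (runif(1) < p) {
        dev <- rvonmises_hours(1, 0, bp$kappa)
        if (dev < 0) dev <- dev * bp$pre_sunset_compress
        arousal <- sunsets[i] + (bp$arousal_offset_h + dev) * 3600
        break
      }
    }
    if (is.na(arousal) || arousal >= t_end) {
      # still torpid when the deployment ends
      o_on <- c(o_on, onset); o_ar <- c(o_ar, NA_real_)
      o_len <- c(o_len, (t_end - onset) / 3600)
      o_final <- c(o_final, TRUE); o_cens <- c(o_cens, TRUE)
      break
    }
    arousal <- max(arousal, onset + bp$min_sub_h * 2 * 3600)

    sub <- split_day_bouts(onset, arousal, bp, cool_T, rewarm_h)
    m <- length(sub$len)
    o_on <- c(o_on, sub$onset); o_ar <- c(o_ar, sub$arousal)
    o_len <- c(o_len, sub$len)
    o_final <- c(o_final, seq_len(m) == m)
    o_cens <- c(o_cens, rep(FALSE, m))

    nd_h <- min(max(rlnorm(1, bp$nd_meanlog, bp$nd_sdlog), 1), 20)
    onset <- arousal + (rewarm_h(cool_T(sub$len[m])) + nd_h) * 3600
  }
  truth <- tibble(
    bat_id = rep(bat_id, length(o_on)),
    onset = onset_posix(o_on, sp$tz),
    arousal = onset_posix(o_ar, sp$tz),
    onset_cross = onset_posix(o_on + cross_h * 3600, sp$tz),
    arousal_cross = onset_posix(
      o_ar + vapply(o_len, rewarm_h2_cross, numeric(1), cave = cave,
                    bp = bp) * 3600, sp$tz),
    torpor_len_h = o_len, final = o_final, censored = o_cens
  )
  trace <- schedule_to_trace(truth, config, bat_id)
  list(truth = truth, trace = trace)
}

onset_posix <- function(x, tz) {
  as.POSIXct(x, origin = "1970-01-01", tz = tz)
}

# Hours after the rewarming start at which Tsk crosses the threshold.
rewarm_h2_cross <- function(torpor_len_h, cave, bp) {
  T_aa <- cave + (bp$t_norm_C - cave) * exp(-bp$cooling_k_h * torpor_len_h)
  (bp$threshold_C - T_aa) / (bp$rewarm_C_min * 60)
}

# Split the torpor interval [onset, arousal] (numeric seconds) into
# 1 + Poisson(lambda) sub-bouts separated by brief normothermic
# interruptions; the final sub-bout always ends at the drawn
# (sunset-anchored) arousal. Returns numeric vectors.
split_day_bouts <- function(onset, arousal, bp, cool_T, rewarm_h) {
  interval_h <- (arousal - onset) / 3600
  m <- if (bp$day_bouts_lambda > 0) 1 + rpois(1, bp$day_bouts_lambda) else 1
  single <- list(onset = onset, arousal = arousal, len = interval_h)
  if (m == 1) return(single)
  repeat {
    inter <- pmin(pmax(rlnorm(m - 1, bp$interruption_meanlog,
                              bp$interruption_sdlog), 0.7), 2)
    overhead <- sum(inter) + (m - 1) * 0.6 # ~rewarm time per interruption
    avail <- interval_h - overhead
    if (avail >= m * bp$min_sub_h) break
    m <- m - 1
    if (m == 1) return(single)
  }
  w <- runif(m)
  len <- avail * w / sum(w)
  if (any(len < bp$min_sub_h)) len <- rep(avail / m, m)
  onsets <- rep(onset, m)
  arousals <- rep(arousal, m)
  for (j in seq_len(m - 1)) {
    arousals[j] <- onsets[j] + len[j] * 3600
    onsets[j + 1] <- arousals[j] +
      (rewarm_h(cool_T(len[j])) + inter[j]) * 3600
  }
  final_len <- (arousal - onsets[m]) / 3600
  if (final_len < 0.75 * bp$min_sub_h) return(single)
  list(onset = onsets, arousal = arousals,
       len = c(len[seq_len(m - 1)], final_len))
}

# Materialise the skin-temperature trace for one bat's truth schedule on
# the 10-min grid.
schedule_to_trace <- function(truth, config, bat_id) {
  sp <- sim_span(config)
  bp <- config$bat
  cave <- config$site$cave_temp_C
  rate_h <- bp$rewarm_C_min * 60
  times <- seq(sp$t_start, sp$t_end, by = 600)
  tsk <- rep(bp$t_norm_C, length(times))
  t_num <- as.numeric(times)
  # grid indices in [a, b): t_num is sorted, so use binary search
  span_idx <- function(a, b) {
    lo <- findInterval(a - 1e-6, t_num) + 1L
    hi <- findInterval(b - 1e-6, t_num)
    if (hi < lo) integer(0) else lo:hi
  }
  for (i in seq_len(nrow(truth))) {
    on_n <- as.numeric(truth$onset[i])
    ar_n <- if (truth$censored[i]) as.numeric(sp$t_end) + 1 else
      as.numeric(truth$arousal[i])
    cool <- span_idx(on_n, ar_n)
    tsk[cool] <- cave + (bp$t_norm_C - cave) *
      exp(-bp$cooling_k_h * (t_num[cool] - on_n) / 3600)
    if (!truth$censored[i]) {
      T_aa <- cave + (bp$t_norm_C - cave) *
        exp(-bp$cooling_k_h * truth$torpor_len_h[i])
      re <- span_idx(ar_n, ar_n + (bp$t_norm_C - T_aa) / rate_h * 3600)
      tsk[re] <- pmin(T_aa + rate_h * (t_num[re] - ar_n) / 3600, bp$t_norm_C)
    }
  }
  if (bp$tsk_sd > 0) tsk <- tsk + rnorm(length(tsk), 0, bp$tsk_sd)
  tibble(bat_id = bat_id, site = config$site$name, cave = NA_character_,
         timestamp = times, tsk_C = tsk)
}

#' Simulate water-bath calibration points for a set of transmitters
#'
#' Each transmitter's pulse interval responds to temperature through a
#' monotone quadratic with small per-transmitter variation; five bath
#' temperatures between 5 and 40 degC are recorded with a little pulse
#' measurement noise.
#'
#' @param transmitter_ids Character vector of transmitter identifiers.
#' @param seed Optional seed.
#' @param pulse_noise_ms SD of pulse-interval measurement noise (default
#'   0.5 ms).
#' @return A tibble with `transmitter_id`, `bath_temp_C`,
#'   `pulse_interval_ms`.
#' @export
simulate_calibration <- function(transmitter_ids, seed = NULL,
                                 pulse_noise_ms = 0.5) {
  if (!is.null(seed)) withr::local_seed(seed)
  baths <- seq(5, 40, length.out = 5)
  purrr::map_dfr(transmitter_ids, function(id) {
    a <- rnorm(1, 1250, 20)
    b <- rnorm(1, 14, 0.5)
    cc <- rnorm(1, 0.06, 0.005)
    tibble(transmitter_id = id, bath_temp_C = baths,
           pulse_interval_ms = a - b * baths + cc * baths^2 +
             rnorm(5, 0, pulse_noise_ms))
  })
}

#' Encode a trace as a degraded pulse log
#'
#' Inverts the calibration cubic numerically (monotone over its valid range
#' is required) to turn each skin-temperature sample into a pulse interval,
#' then degrades the log: optional linear calibration drift added before
#' encoding, per-sample Bernoulli dropout, and - with probability
#' `rewarm_loss_p` per arousal - removal of every sample from the moment the
#' rewarming bat reaches `departure_C` until `forage_gap_h` later, emulating
#' a bat flying out of receiver range at arousal.
#'
#' @param trace A skin-temperature trace (`timestamp`, `tsk_C`).
#' @param curve A [fit_calibration()] curve.
#' @param p_dropout Per-sample missed-detection probability.
#' @param rewarm_loss_p Probability an arousal takes the bat out of range.
#' @param forage_gap_h Out-of-range span (hours) after departure.
#' @param departure_C Skin temperature at which a departing bat disappears.
#' @param drift_C_per_day Linear calibration drift injected before encoding.
#' @param seed Optional seed.
#' @return A pulse-record tibble (`timestamp`, `transmitter_id`,
#'   `pulse_interval_ms`).
#' @export
encode_and_degrade <- function(trace, curve, p_dropout = 0,
                               rewarm_loss_p = 0, forage_gap_h = 3,
                               departure_C = 32.2, drift_C_per_day = 0,
                               seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  assert_cols(trace, c("timestamp", "tsk_C"), "trace")
  keep0 <- !is.na(trace$tsk_C)
  trace <- trace[keep0, , drop = FALSE]
  n <- nrow(trace)
  temps <- trace$tsk_C
  if (drift_C_per_day != 0) {
    el_days <- as.numeric(trace$timestamp - trace$timestamp[1],
                          units = "days")
    temps <- temps + drift_C_per_day * el_days
  }

  span <- diff(curve$valid_range)
  pgrid <- seq(curve$valid_range[1] - 0.2 * span,
               curve$valid_range[2] + 0.2 * span, length.out = 4000)
  tgrid <- predict(curve, pgrid)
  d <- diff(tgrid)
  if (!(all(d > 0) || all(d < 0))) {
    abort("calibration cubic is not monotone over the inversion range; cannot encode")
  }
  pulse <- approx(tgrid, pgrid, xout = temps, rule = 2)$y
  cf <- curve$coefficients
  for (it in 1:2) { # Newton refinement
    f <- predict(curve, pulse) - temps
    fp <- cf[["c1"]] + 2 * cf[["c2"]] * pulse + 3 * cf[["c3"]] * pulse^2
    pulse <- pulse - f / fp
  }

  drop <- runif(n) < p_dropout
  if (rewarm_loss_p > 0) {
    rise <- c(FALSE, diff(trace$tsk_C) > 3)
    r <- rle(rise)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    t_num <- as.numeric(trace$timestamp)
    for (j in which(r$values)) {
      if (runif(1) >= rewarm_loss_p) next
      look <- starts[j]:min(ends[j] + 12L, n)
      hot <- look[trace$tsk_C[look] >= departure_C]
      if (length(hot) == 0) next
      gone <- t_num >= t_num[hot[1]] &
        t_num < t_num[hot[1]] + forage_gap_h * 3600
      drop <- drop | gone
    }
  }
  tibble(timestamp = trace$timestamp[!drop],
         transmitter_id = curve$transmitter_id,
         pulse_interval_ms = pulse[!drop])
}

default_mass_means <- function() {
  tibble::tribble(
    ~site,  ~sex, ~late_summer, ~early_winter, ~mid_winter, ~late_winter, ~early_spring,
    "cold", "m",  14.4,         16.0,          15.2,        13.87,        13.5,
    "cold", "f",  15.2,         17.6,          16.1,        13.45,        13.0,
    "warm", "m",  14.6,         14.9,          14.5,        13.9,         13.6,
    "warm", "f",  14.8,         15.1,          14.6,        13.2,         13.0
  ) %>%
    tidyr::pivot_longer(dplyr::all_of(mass_timepoints),
                        names_to = "timepoint", values_to = "mean_g")
}

#' Simulate seasonal capture body-mass records
#'
#' Draws Gaussian individual masses around configured (site, sex, timepoint)
#' group means. The default means implement the study's qualitative
#' structure: pre-winter fattening much stronger at the cold site, cold-site
#' females heavier than males in early winter and losing mass faster over
#' the winter.
#'
#' @param sites Site(s) to generate (default both).
#' @param n_per_group Individuals per (site, sex, timepoint) group.
#' @param sd_g Individual mass SD within a group (default 0.5 g).
#' @param means Group-mean table as from `default_mass_means()`.
#' @param seed Optional seed.
#' @return A capture-record tibble: `site`, `sex`, `age`, `timepoint`,
#'   `mass_g`, `forearm_mm`.
#' @export
simulate_body_mass <- function(sites = c("cold", "warm"), n_per_group = 20,
                               sd_g = 0.5, means = default_mass_means(),
                               seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  means <- filter(means, .data$site %in% sites)
  purrr::pmap_dfr(means, function(site, sex, timepoint, mean_g) {
    tibble(site = site, sex = sex, age = "adult", timepoint = timepoint,
           mass_g = pmin(pmax(rnorm(n_per_group, mean_g, sd_g), 5.1), 29.9),
           forearm_mm = rnorm(n_per_group, 47.5, 1.2))
  })
}

#' Simulate a full cohort
#'
#' One call that runs the whole generator under a single RNG stream seeded
#' from the configuration: weather, night windows, per-bat schedules and
#' traces, water-bath calibration points (one transmitter per bat), and
#' body-mass records. Identical configurations give identical output.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_cohort`: `config`, `weather`, `nights`,
#'   `nightly_ta`, `truth` (all bats' bouts), `traces` (row-bound traces),
#'   `calibration`, `bodymass`.
#' @export
simulate_cohort <- function(config) {
  withr::local_seed(config$seed)
  site <- config$site
  dates <- seq(config$start - 1, config$start + config$days, by = "day")
  nights <- night_window(site$lat, site$lon, site$tz, dates,
                         site = site$name)
  weather <- simulate_weather(config)
  nightly_ta <- sim_nightly_ta(weather, nights)
  bat_ids <- sprintf("%s%02d", site$name, seq_len(config$n_bats))
  bats <- purrr::map2(bat_ids, seq_along(bat_ids), function(id, i) {
    simulate_bat(config, nightly_ta, nights, bat_id = id)
  })
  calibration <- simulate_calibration(sprintf("tx%02d",
                                              seq_len(config$n_bats)))
  bodymass <- simulate_body_mass(sites = site$name)
  structure(
    list(config = config,
         weather = weather,
         nights = nights,
         nightly_ta = nightly_ta,
         truth = bind_rows(purrr::map(bats, "truth")),
         traces = bind_rows(purrr::map(bats, "trace")),
         calibration = calibration,
         bodymass = bodymass),
    class = "sim_cohort"
  )
}

#' Score segmentation recovery against the truth schedule
#'
#' Matches each true (non-censored) torpor bout to a detected bout whose
#' onset lies within `tol_samples` sampling steps of the true
#' threshold-crossing onset, and reports boundary errors.
#'
#' @param truth Truth table from [simulate_cohort()] / [simulate_bat()].
#' @param bouts Detected bout table from [segment_trace()].
#' @param interval_min Sampling interval in minutes (default 10).
#' @param tol_samples Matching tolerance in samples (default 1).
#' @return A list with `n_truth`, `n_detected`, `n_matched`,
#'   `max_onset_err_samples`, `max_end_err_samples` (end error over matched
#'   bouts ending in an observed arousal).
#' @export
match_truth <- function(truth, bouts, interval_min = 10, tol_samples = 1) {
  truth <- filter(truth, !.data$censored)
  bouts <- filter(bouts, !.data$censored)
  step <- interval_min * 60
  onset_err <- rep(NA_real_, nrow(truth))
  end_err <- rep(NA_real_, nrow(truth))
  for (i in seq_len(nrow(truth))) {
    cand <- bouts[bouts$bat_id == truth$bat_id[i], ]
    if (nrow(cand) == 0) next
    de <- abs(as.numeric(cand$onset) - as.numeric(truth$onset_cross[i]))
    j <- which.min(de)
    if (de[j] <= tol_samples * step) {
      onset_err[i] <- de[j] / step
      if (!is.na(cand$end_type[j]) && cand$end_type[j] == "observed_arousal") {
        end_err[i] <- abs(as.numeric(cand$end[j]) -
                            as.numeric(truth$arousal_cross[i])) / step
      }
    }
  }
  list(n_truth = nrow(truth), n_detected = nrow(bouts),
       n_matched = sum(!is.na(onset_err)),
       max_onset_err_samples = if (any(!is.na(onset_err)))
         max(onset_err, na.rm = TRUE) else NA_real_,
       max_end_err_samples = if (any(!is.na(end_err)))
         max(end_err, na.rm = TRUE) else NA_real_)
}
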