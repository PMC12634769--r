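test_that("zero-noise weather is exactly the configured sinusoids", {
  cfg <- sim_config("cold", days = 5, seed = 1,
                    weather = list(ar_sd = 0, rh_sd = 0, rain_p = 0,
                                   bp_sd = 0, synoptic_amp = 0))
  w <- simulate_weather(cfg, seed = 1)
  lt <- lubridate::with_tz(w$timestamp, cfg$site$tz)
  doy <- lubridate::yday(lt)
  hour <- lubridate::hour(lt) + lubridate::minute(lt) / 60
  expected <- cfg$weather$ta_mean -
    cfg$weather$seasonal_amp * cos(2 * pi * (doy - 196) / 365.25) +
    cfg$weather$diel_amp * cos(2 * pi * (hour - 14) / 24)
  expect_equal(w$air_temp_C, expected, tolerance = 1e-12)
  expect_true(all(w$rain_mm == 0))
  expect_true(all(w$rel_humidity_pct >= 20 & w$rel_humidity_pct <= 100))
})

test_that("the weather generator is deterministic under a fixed seed", {
  cfg <- sim_config("warm", days = 3, seed = 9)
  expect_identical(simulate_weather(cfg, seed = 9),
                   simulate_weather(cfg, seed = 9))
  co1 <- simulate_cohort(sim_config("cold", n_bats = 2, days = 10,
                                    seed = 4))
  co2 <- simulate_cohort(sim_config("cold", n_bats = 2, days = 10,
                                    seed = 4))
  expect_identical(co1$traces, co2$traces)
  expect_identical(co1$truth, co2$truth)
  expect_identical(co1$bodymass, co2$bodymass)
})

test_that("the AR(1) temperature anomaly has the configured autocorrelation", {
  cfg <- sim_config("cold", days = 207, seed = 2, # > 10,000 samples
                    weather = list(seasonal_amp = 0, diel_amp = 0,
                                   synoptic_amp = 0, ar1 = 0.8, ar_sd = 1))
  w <- simulate_weather(cfg, seed = 2)
  r1 <- stats::acf(w$air_temp_C, lag.max = 1, plot = FALSE)$acf[2]
  expect_equal(r1, 0.8, tolerance = 0.02)
})

test_that("torpid cooling follows the closed-form exponential", {
  cfg <- sim_config("cold", n_bats = 1, days = 10, seed = 6,
                    bat = list(tsk_sd = 0, t_norm_C = 35, cooling_k_h = 0.5))
  co <- simulate_cohort(cfg)
  b <- co$truth[!co$truth$censored & co$truth$torpor_len_h > 3, ][1, ]
  tr <- co$traces
  sel <- tr$timestamp > b$onset & tr$timestamp < b$onset + 2.5 * 3600
  dt_h <- as.numeric(tr$timestamp[sel] - b$onset, units = "hours")
  expect_equal(tr$tsk_C[sel], 10.6 + (35 - 10.6) * exp(-0.5 * dt_h),
               tolerance = 1e-9)
  # the printed spot value: Tsk(2 h) = 10.6 + 24.4 e^-1 ~ 19.58
  expect_equal(10.6 + (35 - 10.6) * exp(-0.5 * 2), 19.576, tolerance = 1e-3)
})

test_that("a saturating hazard forces one-night bouts", {
  cfg <- sim_config("cold", n_bats = 3, days = 15, seed = 8,
                    hazard = list(b0 = 50), bat = list(tsk_sd = 0))
  co <- simulate_cohort(cfg)
  live <- co$truth[!co$truth$censored, ]
  tz <- cfg$site$tz
  n_on <- batbouts:::civil_night_date(live$onset, tz)
  n_ar <- batbouts:::civil_night_date(live$arousal, tz)
  expect_true(all(as.integer(n_ar - n_on) == 1))
  expect_true(all(live$torpor_len_h < 30))
})

test_that("encode/decode round-trips a noise-free trace through the cubic", {
  cfg <- sim_config("cold", n_bats = 1, days = 10, seed = 14,
                    bat = list(tsk_sd = 0))
  co <- simulate_cohort(cfg)
  pts <- simulate_calibration("tx1", seed = 3, pulse_noise_ms = 0)
  cv <- fit_calibration(pts)
  rec <- encode_and_degrade(co$traces, cv, p_dropout = 0,
                            rewarm_loss_p = 0)
  expect_equal(nrow(rec), nrow(co$traces))
  back <- decode_trace(rec, cv, bat_id = "cold01")
  expect_equal(back$tsk_C, co$traces$tsk_C, tolerance = 0.01)
})

test_that("per-sample dropout deletes the configured fraction", {
  n <- 10000
  tr <- make_trace(rep(20, n))
  pts <- simulate_calibration("tx1", seed = 3, pulse_noise_ms = 0)
  cv <- fit_calibration(pts)
  rec <- encode_and_degrade(tr, cv, p_dropout = 0.1, seed = 99)
  missing_frac <- 1 - nrow(rec) / n
  expect_equal(missing_frac, 0.1, tolerance = 0.01)
})

test_that("guaranteed rewarm loss turns every completed bout into a last detection", {
  cfg <- sim_config("cold", n_bats = 3, days = 20, seed = 17,
                    bat = list(tsk_sd = 0))
  co <- simulate_cohort(cfg)
  pts <- simulate_calibration(unique(co$traces$bat_id), seed = 5,
                              pulse_noise_ms = 0)
  curves <- fit_calibrations(pts)
  bats <- unique(co$traces$bat_id)
  for (i in seq_along(bats)) {
    tr <- co$traces[co$traces$bat_id == bats[i], ]
    rec <- encode_and_degrade(tr, curves$curve[[i]], p_dropout = 0,
                              rewarm_loss_p = 1, seed = 100 + i)
    back <- decode_trace(rec, curves$curve[[i]], bat_id = bats[i])
    seg <- segment_trace(back, 32.2)
    done <- seg$bouts[!seg$bouts$censored, ]
    expect_gt(nrow(done), 0)
    expect_true(all(done$end_type == "last_detection"))
  }
})

test_that("drift injection is visible to the drift detector after decoding", {
  cfg <- sim_config("cold", n_bats = 1, days = 30, seed = 19,
                    bat = list(tsk_sd = 0.1),
                    hazard = list(b0 = -5, b_ta = 0, b_days = 0.1))
  co <- simulate_cohort(cfg) # long bouts: plenty of torpid plateau
  pts <- simulate_calibration("tx1", seed = 3, pulse_noise_ms = 0)
  cv <- fit_calibration(pts)
  rec <- encode_and_degrade(co$traces, cv, drift_C_per_day = 0.05,
                            seed = 7)
  back <- decode_trace(rec, cv, bat_id = "cold01")
  expect_true(as.logical(flag_drift(back, tolerance = 1)))
  rec0 <- encode_and_degrade(co$traces, cv, drift_C_per_day = 0, seed = 7)
  back0 <- decode_trace(rec0, cv, bat_id = "cold01")
  expect_false(as.logical(flag_drift(back0, tolerance = 1)))
})

test_that("noise-free body-mass draws sit exactly on the configured means", {
  rec <- simulate_body_mass(n_per_group = 3, sd_g = 0, seed = 44)
  ms <- mass_summary(rec)
  joined <- dplyr::left_join(
    ms, batbouts:::default_mass_means(),
    by = c("site", "sex", "timepoint"))
  expect_equal(joined$mean_g.x, joined$mean_g.y, tolerance = 1e-12)
  expect_identical(simulate_body_mass(n_per_group = 5, seed = 44),
                   simulate_body_mass(n_per_group = 5, seed = 44))
})

test_that("truth schedules strictly interleave torpor and normothermia", {
  co <- simulate_cohort(sim_config("warm", n_bats = 3, days = 20,
                                   seed = 31))
  for (b in split(co$truth, co$truth$bat_id)) {
    expect_true(all(diff(as.numeric(b$onset)) > 0))
    live <- b[!b$censored, ]
    expect_true(all(live$arousal > live$onset))
    if (nrow(b) > 1) {
      expect_true(all(as.numeric(b$onset[-1]) >
                        as.numeric(b$arousal[-nrow(b)]), na.rm = TRUE))
    }
  }
})
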