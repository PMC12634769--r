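mk_nightly <- function(dates) {
  withr::with_seed(50, tibble::tibble(
    night_date = as.Date(dates),
    ta_mean = runif(length(dates), 0, 10),
    ah_mean = runif(length(dates), 3, 8),
    wind_mean = runif(length(dates), 0, 20),
    rain_total = runif(length(dates), 0, 5),
    delta_bp = runif(length(dates), -6, 6)
  ))
}

mk_seg <- function(bouts, normothermia = NULL) {
  list(bouts = bouts,
       arousals = tibble::tibble(),
       normothermia = normothermia %||%
         tibble::tibble(bat_id = character(), site = character(),
                        start = as.POSIXct(character()),
                        end = as.POSIXct(character()),
                        duration_h = numeric(),
                        touches_night = logical()))
}
`%||%` <- function(x, y) if (is.null(x)) y else x

test_that("a 70-h bout becomes three arousal-frame rows with one arousal", {
  dates <- seq(as.Date("2023-07-01"), as.Date("2023-07-06"), by = "day")
  nights <- make_nights(dates)
  onset <- as.POSIXct("2023-07-01 17:30:00", tz = "UTC")
  bouts <- tibble::tibble(
    bat_id = "b1", site = "cold", cave = NA_character_,
    onset = onset, end = onset + 70 * 3600, duration_h = 70,
    end_type = "observed_arousal", censored = FALSE)
  fr <- build_model_frames(mk_seg(bouts), mk_nightly(dates), nights)
  expect_equal(nrow(fr$arousal), 3)
  expect_equal(fr$arousal$days_in_torpor, 0:2)
  expect_equal(fr$arousal$aroused, c(0L, 0L, 1L))
  expect_equal(fr$arousal$night_date,
               as.Date(c("2023-07-01", "2023-07-02", "2023-07-03")))
  # TBD frame keys the bout to its onset night
  expect_equal(nrow(fr$tbd), 1)
  expect_equal(fr$tbd$night_date, as.Date("2023-07-01"))
  expect_equal(fr$tbd$duration_h, 70)
  expect_equal(fr$tbd$doy, as.integer(strftime("2023-07-01", "%j")))
})

test_that("last-detection bouts count as arousals; censored bouts are excluded", {
  dates <- seq(as.Date("2023-07-01"), as.Date("2023-07-06"), by = "day")
  nights <- make_nights(dates)
  o0 <- as.POSIXct("2023-07-01 20:00:00", tz = "UTC")
  bouts <- tibble::tibble(
    bat_id = c("b1", "b2"), site = "cold", cave = NA_character_,
    onset = c(o0, o0), end = c(o0 + 40 * 3600, o0 + 30 * 3600),
    duration_h = c(40, 30),
    end_type = c("last_detection", NA_character_),
    censored = c(FALSE, TRUE))
  fr <- build_model_frames(mk_seg(bouts), mk_nightly(dates), nights)
  expect_true(all(fr$arousal$bat_id == "b1"))
  expect_equal(sum(fr$arousal$aroused), 1L)
  expect_equal(nrow(fr$tbd), 1)
})

test_that("each bout yields exactly one arousal and days_in_torpor_max + 1 rows", {
  cfg <- sim_config("cold", n_bats = 4, days = 30, seed = 23)
  co <- simulate_cohort(cfg)
  nightly <- nightly_aggregate(co$weather, co$nights)
  seg <- segment_traces(co$traces, 32.2, nights = co$nights)
  fr <- build_model_frames(seg, nightly, co$nights)
  live <- seg$bouts[!seg$bouts$censored, ]
  ar <- dplyr::arrange(fr$arousal, bat_id, night_date)
  # every bout contributes a contiguous block of nights starting at day 0
  blocks <- split(ar, cumsum(ar$days_in_torpor == 0))
  expect_equal(length(blocks), nrow(live))
  for (b in blocks) {
    expect_equal(b$days_in_torpor, seq_len(nrow(b)) - 1L)
    expect_equal(sum(b$aroused), 1L)
    expect_equal(b$aroused[nrow(b)], 1L) # the arousal is the last night
  }
  # days_in_torpor stays within a night of the true bout span
  expect_true(all(vapply(blocks, nrow, 1L) <=
                    ceiling(max(live$duration_h) / 24) + 1))
})

test_that("rows with missing nightly covariates are dropped with a message", {
  dates <- seq(as.Date("2023-07-01"), as.Date("2023-07-06"), by = "day")
  nights <- make_nights(dates)
  nightly <- mk_nightly(dates)
  nightly$ta_mean[2] <- NA
  onset <- as.POSIXct("2023-07-01 17:30:00", tz = "UTC")
  bouts <- tibble::tibble(
    bat_id = "b1", site = "cold", cave = NA_character_,
    onset = onset, end = onset + 70 * 3600, duration_h = 70,
    end_type = "observed_arousal", censored = FALSE)
  expect_message(
    fr <- build_model_frames(mk_seg(bouts), nightly, nights),
    "dropped 1 row")
  expect_equal(nrow(fr$arousal), 2)
})

test_that("the normothermia frame keeps only night-touching bouts", {
  dates <- seq(as.Date("2023-07-01"), as.Date("2023-07-06"), by = "day")
  nights <- make_nights(dates)
  normo <- tibble::tibble(
    bat_id = "b1", site = "cold",
    start = as.POSIXct(c("2023-07-02 18:00:00", "2023-07-03 09:00:00"),
                       tz = "UTC"),
    end = as.POSIXct(c("2023-07-03 01:00:00", "2023-07-03 15:00:00"),
                     tz = "UTC"),
    duration_h = c(7, 6), touches_night = c(TRUE, FALSE))
  empty_bouts <- tibble::tibble(
    bat_id = character(), site = character(), cave = character(),
    onset = as.POSIXct(character()), end = as.POSIXct(character()),
    duration_h = numeric(), end_type = character(), censored = logical())
  fr <- build_model_frames(mk_seg(empty_bouts, normo), mk_nightly(dates),
                           nights)
  expect_equal(nrow(fr$nd), 1)
  expect_equal(fr$nd$night_date, as.Date("2023-07-02"))
  expect_equal(fr$nd$duration_h, 7)
})

test_that("sign diagnostics report rank correlations per covariate", {
  withr::with_seed(60, {
    fr <- tibble::tibble(ta_mean = rnorm(50), doy = 1:50,
                         duration_h = 100 - (1:50) + rnorm(50, 0, 5))
  })
  d <- frame_sign_diagnostics(fr, "duration_h",
                              covariates = c("ta_mean", "doy"))
  expect_equal(nrow(d), 2)
  expect_lt(d$rho[d$covariate == "doy"], -0.9)
  expect_lt(d$p_value[d$covariate == "doy"], 1e-6)
})
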