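test_that("calibration fit recovers exact polynomial relationships", {
  pulses <- seq(600, 1400, by = 200)

  # linear relation: T = 2 + 0.01 p (higher-order terms vanish)
  lin <- cubic_points(c(2, 0.01, 0, 0), pulses)
  cv <- fit_calibration(lin)
  expect_equal(unname(cv$coefficients[c("c0", "c1")]), c(2, 0.01),
               tolerance = 1e-8)
  expect_lt(max(abs(cv$coefficients[c("c2", "c3")])), 1e-10)
  expect_lt(cv$fit_rmse, 1e-8)

  # full cubic recovered to numerical precision (this particular cubic dips
  # and rises over the range, so the monotonicity warnings are expected)
  coefs <- c(31, -0.02, 1e-5, -1e-9)
  cub <- cubic_points(coefs, pulses)
  cv2 <- suppressWarnings(fit_calibration(cub))
  expect_equal(unname(cv2$coefficients), coefs, tolerance = 1e-6)
  # round trip through an independent polynomial evaluation
  p_check <- seq(600, 1400, length.out = 50)
  manual <- coefs[1] + coefs[2] * p_check + coefs[3] * p_check^2 +
    coefs[4] * p_check^3
  expect_equal(predict(cv2, p_check), manual, tolerance = 1e-7)
  expect_equal(cv2$valid_range, c(600, 1400))
})

test_that("calibration validates its inputs", {
  pulses <- seq(600, 1000, by = 200)
  three <- cubic_points(c(2, 0.01, 0, 0), pulses)
  expect_error(fit_calibration(three), "underdetermined")
  # four rows but duplicated pulse intervals are still underdetermined
  dup <- cubic_points(c(2, 0.01, 0, 0), c(600, 600, 800, 1000))
  expect_error(fit_calibration(dup), "underdetermined")
  bad <- cubic_points(c(2, 0.01, 0, 0), seq(600, 1400, 200))
  bad$bath_temp_C[1] <- NA
  expect_error(fit_calibration(bad), "finite")
  neg <- cubic_points(c(50, 0.01, 0, 0), seq(600, 1400, 200))
  expect_error(fit_calibration(neg), "0-45")
})

test_that("non-monotone calibration points raise a warning, not an error", {
  pts <- tibble::tibble(transmitter_id = "tx9",
                        bath_temp_C = c(10, 30, 12, 35, 14),
                        pulse_interval_ms = seq(600, 1400, by = 200))
  w <- capture_warnings(cv <- fit_calibration(pts))
  expect_true(any(grepl("monotone", w)))
  expect_s3_class(cv, "calibration_curve")
})

test_that("tidy and glance expose the fit", {
  cv <- fit_calibration(cubic_points(c(2, 0.01, 0, 0), seq(600, 1400, 200)))
  td <- tidy(cv)
  expect_equal(td$term, c("c0", "c1", "c2", "c3"))
  gl <- glance(cv)
  expect_equal(gl$n_points, 5)
  expect_true(gl$monotone)
})

test_that("decode_trace snaps to the grid, averages duplicates, flags extrapolation", {
  cv <- fit_calibration(cubic_points(c(0, 0.05, 0, 0), seq(400, 800, 100)))
  t0 <- as.POSIXct("2023-07-01 00:00:00", tz = "UTC")
  # intervals decode as 0.05 * p: 700 -> 35.0, 696 -> 34.8, 402 -> 20.1
  rec <- tibble::tibble(
    timestamp = t0 + c(0, 600, 1200),
    transmitter_id = "tx1",
    pulse_interval_ms = c(700, 696, 402)
  )
  tr <- decode_trace(rec, cv)
  expect_equal(nrow(tr), 3)
  expect_equal(tr$tsk_C, c(35.0, 34.8, 20.1), tolerance = 1e-9)
  expect_false(any(tr$extrapolated))

  # two records in one 10-min slot are averaged (34 and 36 -> 35)
  rec2 <- tibble::tibble(
    timestamp = t0 + c(0, 120, 600),
    transmitter_id = "tx1",
    pulse_interval_ms = c(680, 720, 700)
  )
  tr2 <- decode_trace(rec2, cv)
  expect_equal(nrow(tr2), 2)
  expect_equal(tr2$tsk_C[1], 35.0, tolerance = 1e-9)

  # out-of-range interval: decoded by extrapolation and flagged
  rec3 <- tibble::tibble(timestamp = t0 + c(0, 600, 1200),
                         transmitter_id = "tx1",
                         pulse_interval_ms = c(700, 850, 700))
  tr3 <- decode_trace(rec3, cv)
  expect_true(tr3$extrapolated[2])
  expect_equal(tr3$tsk_C[2], 42.5, tolerance = 1e-9)

  expect_error(decode_trace(rec[0, ], cv), "no pulse records")
})

test_that("decode_trace is grid-complete with explicit missing slots", {
  cv <- fit_calibration(cubic_points(c(0, 0.05, 0, 0), seq(400, 800, 100)))
  t0 <- as.POSIXct("2023-07-01 00:00:00", tz = "UTC")
  withr::with_seed(11, {
    for (rep in 1:10) {
      times <- sort(t0 + runif(20, 0, 86400))
      rec <- tibble::tibble(timestamp = times, transmitter_id = "tx1",
                            pulse_interval_ms = runif(20, 420, 780))
      tr <- decode_trace(rec, cv)
      span <- as.numeric(max(tr$timestamp) - min(tr$timestamp),
                         units = "secs")
      expect_equal(nrow(tr), floor(span / 600) + 1)
      expect_equal(as.numeric(unique(diff(tr$timestamp)), units = "mins"),
                   10)
    }
  })
})

test_that("drift flagging catches an injected plateau ramp and ignores stable traces", {
  days <- 30
  n <- days * 144
  day_idx <- rep(seq_len(days) - 1, each = 144)
  withr::with_seed(5, {
    stable <- make_trace(11 + rnorm(n, 0, 0.1))
    expect_false(as.logical(flag_drift(stable)))

    ramp <- make_trace(11 + 0.05 * day_idx + rnorm(n, 0, 0.1))
    fd <- flag_drift(ramp, tolerance = 1)
    expect_true(as.logical(fd))
    # brute-force check of the fitted ramp: ~0.05 degC/day
    expect_equal(attr(fd, "slope_C_per_day"), 0.05, tolerance = 0.2)
  })

  expect_warning(res <- flag_drift(make_trace(rep(NA_real_, 100))),
                 "no observed samples")
  expect_false(as.logical(res))
})
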