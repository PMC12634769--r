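thr <- 32.2

test_that("a single clean torpor bout is segmented with the half-open convention", {
  x <- c(rep(35, 36), rep(15, 288), rep(35, 6))
  nights <- make_nights(seq(as.Date("2023-06-30"), as.Date("2023-07-04"),
                            by = "day"))
  seg <- segment_trace(make_trace(x), thr, nights = nights)
  expect_equal(nrow(seg$bouts), 1)
  b <- seg$bouts
  expect_equal(b$onset, make_trace(x)$timestamp[37])
  expect_equal(b$end, make_trace(x)$timestamp[325]) # first above sample
  expect_equal(b$duration_h, 48)
  expect_equal(b$end_type, "observed_arousal")
  expect_false(b$censored)
  expect_equal(nrow(seg$arousals), 1)
  expect_equal(seg$arousals$timestamp, b$end)
})

test_that("a below-threshold run of exactly two samples is not a bout", {
  x <- c(rep(35, 10), rep(20, 2), rep(35, 10))
  seg <- segment_trace(make_trace(x), thr)
  expect_equal(nrow(seg$bouts), 0)
  # three samples (just over 10 min at 10-min sampling) is the minimum
  x3 <- c(rep(35, 10), rep(20, 3), rep(35, 10))
  expect_equal(nrow(segment_trace(make_trace(x3), thr)$bouts), 1)
})

test_that("a rising tail before a long gap ends the bout at the last detection", {
  x <- c(rep(35, 6), rep(15, 30), 22, 28, rep(NA, 72), rep(35, 6))
  tr <- make_trace(x)
  seg <- segment_trace(tr, thr)
  expect_equal(nrow(seg$bouts), 1)
  expect_equal(seg$bouts$end_type, "last_detection")
  expect_equal(seg$bouts$end, tr$timestamp[38]) # the 28 degC sample
  expect_equal(nrow(seg$arousals), 1)

  # same gap without the rising tail censors the bout instead
  x2 <- c(rep(35, 6), rep(15, 32), rep(NA, 72), rep(35, 6))
  seg2 <- segment_trace(make_trace(x2), thr)
  expect_equal(nrow(seg2$bouts), 1)
  expect_true(seg2$bouts$censored)
  expect_equal(nrow(seg2$arousals), 0)
})

test_that("short gaps are bridged inside a bout; long non-rising gaps split it", {
  x <- c(rep(35, 4), rep(15, 10), rep(NA, 3), rep(15, 10), rep(35, 4))
  seg <- segment_trace(make_trace(x), thr, gap_limit = 3)
  expect_equal(nrow(seg$bouts), 1)
  expect_equal(seg$bouts$duration_h, 23 * 10 / 60)

  x2 <- c(rep(35, 4), rep(15, 10), rep(NA, 5), rep(15, 10), rep(35, 4))
  seg2 <- segment_trace(make_trace(x2), thr, gap_limit = 3)
  expect_equal(nrow(seg2$bouts), 2)
  expect_true(seg2$bouts$censored[1])
  expect_false(seg2$bouts$censored[2])
})

test_that("a one-sample blip ends a bout by default but can be smoothed", {
  x <- c(rep(35, 4), rep(15, 12), 35, rep(15, 12), rep(35, 4))
  tr <- make_trace(x)
  seg1 <- segment_trace(tr, thr, min_arousal_samples = 1)
  expect_equal(nrow(seg1$bouts), 2)
  expect_equal(nrow(seg1$normothermia), 1)
  expect_equal(seg1$normothermia$duration_h, 10 / 60)

  seg2 <- segment_trace(tr, thr, min_arousal_samples = 2)
  expect_equal(nrow(seg2$bouts), 1)
  expect_equal(seg2$bouts$duration_h, 25 * 10 / 60)
})

test_that("degenerate traces are handled", {
  expect_equal(nrow(segment_trace(make_trace(rep(NA_real_, 50)),
                                  thr)$bouts), 0)
  irregular <- make_trace(rep(20, 10))
  irregular$timestamp[5] <- irregular$timestamp[5] + 30
  expect_error(segment_trace(irregular, thr), "regular")
  expect_error(segment_trace(make_trace(rep(20, 10)), NA_real_), "finite")
})

test_that("segmentation matches the brute-force oracle on random traces", {
  withr::with_seed(101, {
    for (rep in 1:200) {
      n <- sample(20:120, 1)
      x <- random_trace_values(n)
      mas <- sample(c(1L, 2L), 1)
      seg <- segment_trace(make_trace(x), thr, gap_limit = 3,
                           min_arousal_samples = mas)
      got <- bouts_as_indices(seg$bouts, make_trace(x))
      want <- oracle_segment(x, thr, gap_limit = 3,
                             min_arousal_samples = mas)
      expect_equal(got$onset, as.integer(want$onset))
      expect_equal(got$end, as.integer(want$end))
      expect_identical(got$end_type, want$end_type)
      expect_identical(got$censored, want$censored)
    }
  })
})

test_that("raising the threshold never shrinks torpid time or retained bouts", {
  withr::with_seed(202, {
    for (rep in 1:25) {
      x <- pmin(pmax(32 + cumsum(rnorm(300, 0, 1.2)), 10), 42) # no gaps
      lo <- segment_trace(make_trace(x), 30)
      hi <- segment_trace(make_trace(x), 34)
      expect_gte(sum(x < 34), sum(x < 30))
      lo_b <- lo$bouts[!lo$bouts$censored, ]
      for (i in seq_len(nrow(lo_b))) {
        container <- hi$bouts[hi$bouts$onset <= lo_b$onset[i] &
                                hi$bouts$end >= lo_b$end[i], ]
        expect_equal(nrow(container), 1)
        expect_gte(container$duration_h, lo_b$duration_h[i])
      }
    }
  })
})

test_that("bouts and normothermia partition the record without overlap", {
  withr::with_seed(303, {
    for (rep in 1:50) {
      x <- random_trace_values(200)
      seg <- segment_trace(make_trace(x), thr)
      iv <- rbind(
        data.frame(s = as.numeric(seg$bouts$onset),
                   e = as.numeric(seg$bouts$end)),
        data.frame(s = as.numeric(seg$normothermia$start),
                   e = as.numeric(seg$normothermia$end))
      )
      iv <- iv[order(iv$s), ]
      if (nrow(iv) > 1) {
        expect_true(all(iv$e[-nrow(iv)] <= iv$s[-1] + 1e-9))
      }
      # every observed arousal is followed by normothermia or trace end
      obs <- seg$bouts[!seg$bouts$censored &
                         seg$bouts$end_type == "observed_arousal", ]
      for (i in seq_len(nrow(obs))) {
        later_onsets <- seg$bouts$onset[seg$bouts$onset > obs$end[i]]
        if (length(later_onsets) > 0) {
          expect_true(any(abs(as.numeric(seg$normothermia$start) -
                                as.numeric(obs$end[i])) < 1e-9))
        }
      }
    }
  })
})

test_that("arousal timing relative to sunset follows the civil-night convention", {
  nights <- make_nights(seq(as.Date("2023-07-01"), as.Date("2023-07-05"),
                            by = "day"))
  at <- function(s) as.POSIXct(s, tz = "UTC")
  expect_equal(arousal_rel_sunset(at("2023-07-02 17:00:00"), nights), 0)
  expect_equal(arousal_rel_sunset(at("2023-07-02 17:09:00"), nights), 0.15)
  expect_equal(arousal_rel_sunset(at("2023-07-02 16:00:00"), nights), -1)
  # a small-hours event belongs to the previous evening's sunset
  expect_equal(arousal_rel_sunset(at("2023-07-03 02:00:00"), nights), 9)
  expect_error(arousal_rel_sunset(at("2023-08-20 17:00:00"), nights),
               "night window")
})

test_that("days in torpor counts completed nights since onset", {
  onset <- as.POSIXct("2023-07-01 22:00:00", tz = "UTC")
  end <- onset + 70 * 3600
  expect_equal(days_in_torpor(onset, end, as.Date("2023-07-01")), 0L)
  expect_equal(days_in_torpor(onset, end, as.Date("2023-07-03")), 2L)
  expect_error(days_in_torpor(onset, end, as.Date("2023-07-09")),
               "overlap")
})
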