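# Fixture builders shared across test files.

# A regular-grid trace from a numeric vector (NA = missing slot).
make_trace <- function(tsk, start = "2023-07-01 00:00:00", tz = "UTC",
                       interval_min = 10, bat_id = "b1", site = "cold") {
  t0 <- as.POSIXct(start, tz = tz)
  tibble::tibble(
    bat_id = bat_id, site = site, cave = NA_character_,
    timestamp = t0 + (seq_along(tsk) - 1) * interval_min * 60,
    tsk_C = tsk
  )
}

# Stylised night windows: sunset 17:00, sunrise 07:00 local, for a run of
# dates. Good enough for segmentation logic tests that do not need real
# solar geometry.
make_nights <- function(dates, tz = "UTC", sunset_h = 17, sunrise_h = 7,
                        site = "cold") {
  dates <- as.Date(dates)
  tibble::tibble(
    site = site,
    night_date = dates,
    sunset = as.POSIXct(paste(dates, sprintf("%02d:00:00", sunset_h)),
                        tz = tz),
    sunrise_next = as.POSIXct(paste(dates + 1,
                                    sprintf("%02d:00:00", sunrise_h)),
                              tz = tz)
  )
}

# Random trace for oracle-equivalence checks: a temperature random walk
# straddling the threshold, with both scattered and run-structured gaps.
random_trace_values <- function(n) {
  x <- 32.2 + cumsum(stats::rnorm(n, 0, 1.5))
  x <- pmin(pmax(x, 8), 42)
  x[stats::runif(n) < 0.12] <- NA
  n_gaps <- stats::rpois(1, 2)
  for (g in seq_len(n_gaps)) {
    at <- sample.int(n, 1)
    len <- sample.int(8, 1)
    x[at:min(at + len - 1, n)] <- NA
  }
  x
}

# Calibration points lying exactly on a given cubic.
cubic_points <- function(coefs, pulses, transmitter_id = "tx1") {
  tibble::tibble(
    transmitter_id = transmitter_id,
    bath_temp_C = coefs[1] + coefs[2] * pulses + coefs[3] * pulses^2 +
      coefs[4] * pulses^3,
    pulse_interval_ms = pulses
  )
}
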