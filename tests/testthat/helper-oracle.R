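# Independent brute-force segmentation oracle: a sample-by-sample pointer
# scan over the trace values, kept deliberately naive and separate from the
# package's run-length implementation. Returns integer sample indices.

oracle_segment <- function(x, threshold, gap_limit = 3,
                           min_arousal_samples = 1, rise_min = 0.5) {
  n <- length(x)
  s <- character(n)
  for (i in seq_len(n)) {
    s[i] <- if (is.na(x[i])) "M" else if (x[i] < threshold) "B" else "A"
  }
  # short above-threshold blips inside a torpid run
  i <- 1
  while (i <= n) {
    if (s[i] == "A") {
      j <- i
      while (j < n && s[j + 1] == "A") j <- j + 1
      if (i > 1 && j < n && s[i - 1] == "B" && s[j + 1] == "B" &&
          (j - i + 1) < min_arousal_samples) {
        s[i:j] <- "B"
      }
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  # bridge short gaps inside a torpid run
  i <- 1
  while (i <= n) {
    if (s[i] == "M") {
      j <- i
      while (j < n && s[j + 1] == "M") j <- j + 1
      if (i > 1 && j < n && s[i - 1] == "B" && s[j + 1] == "B" &&
          (j - i + 1) <= gap_limit) {
        s[i:j] <- "B"
      }
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  onset <- end <- integer(0)
  type <- character(0)
  cens <- logical(0)
  i <- 1
  while (i <= n) {
    if (s[i] != "B") {
      i <- i + 1
      next
    }
    j <- i
    while (j < n && s[j + 1] == "B") j <- j + 1
    if (j - i + 1 >= 3) {
      if (j == n) {
        o <- i; e <- j; ty <- NA_character_; cn <- TRUE
      } else if (s[j + 1] == "A") {
        o <- i; e <- j + 1; ty <- "observed_arousal"; cn <- FALSE
      } else {
        g <- j + 1
        while (g < n && s[g + 1] == "M") g <- g + 1
        if (g < n && (g - j) <= gap_limit && s[g + 1] == "A") {
          o <- i; e <- g + 1; ty <- "observed_arousal"; cn <- FALSE
        } else {
          rising <- (j - i + 1) >= 3 &&
            isTRUE((x[j] - x[j - 1]) > rise_min) &&
            isTRUE((x[j - 1] - x[j - 2]) > rise_min)
          o <- i; e <- j
          if (rising) {
            ty <- "last_detection"; cn <- FALSE
          } else {
            ty <- NA_character_; cn <- TRUE
          }
        }
      }
      onset <- c(onset, o); end <- c(end, e)
      type <- c(type, ty); cens <- c(cens, cn)
    }
    i <- j + 1
  }
  data.frame(onset = onset, end = end, end_type = type, censored = cens,
             stringsAsFactors = FALSE)
}

# Convert a segment_trace() bout table back to sample indices on the grid
# of `trace` for comparison against the oracle.
bouts_as_indices <- function(bouts, trace) {
  t_num <- as.numeric(trace$timestamp)
  data.frame(
    onset = match(as.numeric(bouts$onset), t_num),
    end = match(as.numeric(bouts$end), t_num),
    end_type = bouts$end_type,
    censored = bouts$censored,
    stringsAsFactors = FALSE
  )
}
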