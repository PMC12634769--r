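# Circular statistics on arousal timing: Rayleigh uniformity test and a
# von Mises kernel mode, on the 24-hour clock anchored at sunset.

hours_to_angle <- function(h) 2 * pi * ((h %% 24) / 24)
angle_to_hours <- function(theta) {
  h <- (theta %% (2 * pi)) * 24 / (2 * pi)
  ifelse(h > 12, h - 24, h) # map to (-12, 12] around the anchor
}

#' Rayleigh test of circular uniformity
#'
#' Tests whether arousal times (as hours relative to sunset, mapped onto the
#' 24-h circle) are uniformly distributed. The mean resultant length is
#' \eqn{\bar r = |\sum e^{i\theta}|/n}, the test statistic \eqn{z = n\bar r^2},
#' and the p-value uses the standard series approximation
#' \deqn{p = e^{-z}\left(1 + \frac{2z - z^2}{4n}
#'   - \frac{24z - 132z^2 + 76z^3 - 9z^4}{288 n^2}\right)}
#' clipped to \[0, 1\].
#'
#' @param x Numeric sample: hours relative to sunset (any real; reduced
#'   modulo 24) or angles in radians, per `units`.
#' @param units `"hours"` (default, 24-h circle) or `"radians"`.
#' @return An object of class `rayleigh_test` with elements `rbar`, `z`,
#'   `p_value`, `n`.
#' @examples
#' rayleigh_test(rep(0.15, 10))$rbar # perfectly concentrated: 1
#' @export
rayleigh_test <- function(x, units = c("hours", "radians")) {
  units <- match.arg(units)
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2) abort("Rayleigh test needs at least 2 observations")
  theta <- if (units == "hours") hours_to_angle(x) else x %% (2 * pi)
  c_bar <- mean(cos(theta))
  s_bar <- mean(sin(theta))
  rbar <- sqrt(c_bar^2 + s_bar^2)
  z <- n * rbar^2
  p <- exp(-z) * (1 + (2 * z - z^2) / (4 * n) -
                    (24 * z - 132 * z^2 + 76 * z^3 - 9 * z^4) / (288 * n^2))
  structure(
    list(rbar = rbar, z = z, p_value = min(max(p, 0), 1), n = n,
         mean_direction_h = angle_to_hours(atan2(s_bar, c_bar)),
         units = units),
    class = "rayleigh_test"
  )
}

#' @export
print.rayleigh_test <- function(x, ...) {
  cat(sprintf("Rayleigh test of uniformity: n = %d, rbar = %.3f, z = %.3f, p %s\n",
              x$n, x$rbar, x$z,
              if (x$p_value < 0.001) "< 0.001" else
                sprintf("= %.3f", x$p_value)))
  invisible(x)
}

#' @export
tidy.rayleigh_test <- function(x, ...) {
  tibble(rbar = x$rbar, statistic = x$z, p.value = x$p_value, n = x$n,
         mean_direction_h = x$mean_direction_h)
}

#' @export
glance.rayleigh_test <- function(x, ...) tidy(x)

#' Circular mode of arousal timing
#'
#' The most common arousal time relative to sunset, estimated as the argmax
#' of a von Mises kernel density on the 24-h circle and reported in hours
#' after sunset to 0.01 h.
#'
#' @param x Hours relative to sunset.
#' @param bandwidth Concentration parameter (kappa) of the von Mises kernel
#'   (default 25, roughly a 45-min kernel standard deviation on the 24-h
#'   circle).
#' @param grid_n Number of evaluation points around the circle (default
#'   2400, i.e. 0.01 h resolution).
#' @return Mode in hours after sunset, in (-12, 12], rounded to 0.01 h.
#'   Warns when the sample is nearly uniform (mean resultant length < 0.1),
#'   where the mode is unstable.
#' @export
circular_mode <- function(x, bandwidth = 25, grid_n = 2400) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 5) abort("circular mode needs at least 5 observations")
  theta <- hours_to_angle(x)
  rbar <- sqrt(mean(cos(theta))^2 + mean(sin(theta))^2)
  if (rbar < 0.1) {
    warn("circular_mode: sample is nearly uniform (rbar < 0.1); mode is unstable")
  }
  grid <- seq(0, 2 * pi, length.out = grid_n + 1)[-(grid_n + 1)]
  dens <- vapply(grid, function(g) sum(exp(bandwidth * cos(g - theta))),
                 numeric(1))
  round(angle_to_hours(grid[which.max(dens)]), 2)
}

# von Mises sampler, Best & Fisher (1979) rejection algorithm.
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 1e-8) return(runif(n, -pi, pi) + mu)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      c_ <- kappa * (r - f)
      if (c_ * (2 - c_) - u[2] > 0 || log(c_ / u[2]) + 1 - c_ >= 0) {
        out[i] <- sign(u[3] - 0.5) * acos(f)
        break
      }
    }
  }
  out + mu
}

# Hour offsets around an anchor on the 24-h circle (used by the simulator
# for arousal timing around sunset).
rvonmises_hours <- function(n, mu_h = 0, kappa = 1) {
  theta <- rvonmises(n, 0, kappa)
  mu_h + theta * 24 / (2 * pi)
}
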