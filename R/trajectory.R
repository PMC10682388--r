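#' Elbow-joint trajectory container
#'
#' A thin container for a uniformly sampled elbow-joint angle time series,
#' as recorded by a joint encoder during guided or self-produced movement.
#'
#' @param angle Numeric vector of joint angles in degrees.
#' @param rate Sampling rate in samples per second (Hz).
#' @return An object of class `prl_trajectory` with fields `angle` and
#'   `rate`.
#' @examples
#' tr <- trajectory(45 + 20 * sin(2 * pi * 0.4 * seq(0, 10, by = 1 / 250)))
#' tr
#' @export
trajectory <- function(angle, rate = 250) {
  angle <- as.numeric(angle)
  if (anyNA(angle) || any(!is.finite(angle))) {
    stopf("trajectory angles must be finite")
  }
  assert_number(rate, "rate", lower = 1e-9)
  structure(list(angle = angle, rate = as.numeric(rate)),
            class = "prl_trajectory")
}

traj_angles <- function(x) {
  if (inherits(x, "prl_trajectory")) x$angle else as.numeric(x)
}

traj_rate <- function(x, default = 250) {
  if (inherits(x, "prl_trajectory")) x$rate else default
}

#' @export
print.prl_trajectory <- function(x, ...) {
  n <- length(x$angle)
  cat(sprintf("<trajectory: %d samples @ %g Hz (%.2f s), range [%.1f, %.1f] deg>\n",
              n, x$rate, n / x$rate, min(x$angle), max(x$angle)))
  invisible(x)
}

#' @export
length.prl_trajectory <- function(x) length(x$angle)

#' @export
plot.prl_trajectory <- function(x, ...) {
  t <- seq_along(x$angle) / x$rate
  plot(t, x$angle, type = "l", xlab = "time (s)", ylab = "elbow angle (deg)",
       ...)
  invisible(x)
}

#' @export
as.data.frame.prl_trajectory <- function(x, ...) {
  data.frame(time_s = seq_along(x$angle) / x$rate, angle_deg = x$angle)
}
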