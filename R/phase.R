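# Hilbert-based continuous relative phase between bow velocity and bow
# angular velocity. Velocity-domain signals are used because they are
# naturally zero-centered, which keeps the analytic-signal phase free of
# baseline artifacts.

#' Continuous instantaneous phase of a quasi-sinusoidal signal
#'
#' Phase of the analytic signal (FFT-based Hilbert transform), unwrapped so
#' that no adjacent-sample jump exceeds 180 degrees. For a pure sinusoid the
#' result increases by 360 degrees per period.
#'
#' @param x signal samples, approximately zero-centered
#' @param sample_rate_hz sampling rate in Hz
#' @param t0 time of the first sample (seconds)
#' @return object of class `continuous_phase`: list with `time` and
#'   `phase_deg` (unwrapped, degrees)
#' @export
continuous_phase <- function(x, sample_rate_hz, t0 = 0) {
  if (all(x == 0)) stop("phase of the all-zero signal is undefined")
  ph <- unwrap_phase(Arg(analytic_signal(x))) * 180 / pi
  structure(list(time = t0 + (seq_along(x) - 1) / sample_rate_hz,
                 phase_deg = ph),
            class = "continuous_phase")
}

# subtract the nearest integer multiple of `base` (default 90 deg) from a
# robust central estimate of the series, referencing it to zero
.reference_offset <- function(delta, base = 90, trim_frac = 0.1) {
  n <- length(delta)
  lo <- max(1, floor(n * trim_frac))
  hi <- min(n, ceiling(n * (1 - trim_frac)))
  base * round(stats::median(delta[lo:hi]) / base)
}

#' Continuous relative phase between velocity and angular velocity
#'
#' `delta = phase(angular velocity) - phase(velocity)`, so a positive value
#' means bow inclination leads bow velocity. For the figure-of-eight pattern
#' the velocity phase is first divided by two to compensate for the 2:1
#' frequency relation, and the resulting relative phase is multiplied by two
#' so that it is expressed in degrees of the velocity cycle, comparable with
#' the circular patterns. Finally the constant nominal quadrature offset --
#' the nearest integer multiple of 90 degrees (+90, -90 and 0 for CW, ACW and
#' Fo8) -- is subtracted so the series is referenced to zero.
#'
#' @param vel_phase [continuous_phase()] of bow velocity
#' @param angvel_phase [continuous_phase()] of bow angular velocity, on the
#'   same time grid
#' @param pattern "CW", "ACW" or "Fo8"
#' @return object of class `relative_phase_series`: list with `time`,
#'   `delta_phi_deg`, `pattern` and the subtracted `offset_deg`
#' @export
relative_phase <- function(vel_phase, angvel_phase, pattern = c("CW", "ACW", "Fo8")) {
  pattern <- match.arg(pattern)
  stopifnot(inherits(vel_phase, "continuous_phase"),
            inherits(angvel_phase, "continuous_phase"))
  if (length(vel_phase$time) != length(angvel_phase$time) ||
      max(abs(vel_phase$time - angvel_phase$time)) > 1e-9)
    stop("phase series must share the same time grid")
  raw <- if (pattern == "Fo8") {
    2 * (angvel_phase$phase_deg - vel_phase$phase_deg / 2)
  } else {
    angvel_phase$phase_deg - vel_phase$phase_deg
  }
  off <- .reference_offset(raw)
  structure(list(time = vel_phase$time, delta_phi_deg = raw - off,
                 pattern = pattern, offset_deg = off),
            class = "relative_phase_series")
}

#' Relative phase at given time points
#'
#' Linear interpolation of the continuous relative phase, e.g. at the moment
#' of a bow change.
#'
#' @param series a `relative_phase_series`
#' @param t time(s) in seconds, within the series support
#' @return degrees
#' @export
phase_at <- function(series, t) {
  stopifnot(inherits(series, "relative_phase_series"))
  if (any(t < min(series$time) - 1e-12 | t > max(series$time) + 1e-12))
    stop("t outside the series support")
  stats::approx(series$time, series$delta_phi_deg, xout = t, rule = 2)$y
}
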