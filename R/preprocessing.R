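# Zero-phase filtering and differentiation of bowing channels.
# Pipeline defaults: bow velocity LP 2nd-order 30 Hz; angular velocity LP
# 30 Hz after differentiation; band-width channel LP 2nd-order 48 Hz; all
# Butterworth, applied back-and-forth to avoid phase shifts.

#' Low-pass filter specification
#'
#' @param order Butterworth order (the forward-backward application doubles
#'   the effective order)
#' @param cutoff_hz -3 dB cutoff in Hz
#' @export
filter_spec <- function(order = 2, cutoff_hz = 30) {
  if (order < 1) stop("order must be >= 1")
  if (cutoff_hz <= 0) stop("cutoff_hz must be positive")
  structure(list(order = as.integer(order), cutoff_hz = cutoff_hz,
                 kind = "low-pass"), class = "filter_spec")
}

#' Default filter set of the analysis pipeline
#' @return named list of [filter_spec()]: `velocity`, `angular_velocity`,
#'   `band_width`
#' @export
default_filters <- function() {
  list(velocity = filter_spec(2, 30),
       angular_velocity = filter_spec(2, 30),
       band_width = filter_spec(2, 48))
}

#' Zero-phase Butterworth low-pass
#'
#' Applies the filter forward and backward (zero phase lag, doubled effective
#' order), with odd end extension to limit edge transients.
#'
#' @param x signal samples (finite; NA/NaN raises an error naming the first
#'   offending index)
#' @param spec a [filter_spec()]
#' @param sample_rate_hz sampling rate in Hz
#' @return filtered signal, same length as `x`
#' @export
zero_phase_lowpass <- function(x, spec = filter_spec(), sample_rate_hz) {
  stopifnot(inherits(spec, "filter_spec"))
  bad <- which(!is.finite(x))
  if (length(bad))
    stop("non-finite value in input at index ", bad[1])
  if (length(x) <= 3 * spec$order)
    stop("signal too short for order-", spec$order, " filtering")
  ba <- butter_lowpass(spec$order, spec$cutoff_hz, sample_rate_hz)
  .filtfilt(ba$b, ba$a, x)
}

#' Differentiate bow inclination into angular velocity
#'
#' Central differences scaled by the sample rate (one-sided at the ends),
#' followed by the pipeline's zero-phase 30 Hz low-pass.
#'
#' @param x inclination samples (degrees); at least 3 samples
#' @param sample_rate_hz sampling rate in Hz
#' @param spec low-pass applied after differencing; `NULL` to skip
#' @return angular velocity in degrees/s
#' @export
differentiate <- function(x, sample_rate_hz, spec = filter_spec(2, 30)) {
  n <- length(x)
  if (n < 3) stop("need at least 3 samples to differentiate")
  d <- c(x[2] - x[1], (x[3:n] - x[1:(n - 2)]) / 2, x[n] - x[n - 1]) *
    sample_rate_hz
  if (is.null(spec)) d else zero_phase_lowpass(d, spec, sample_rate_hz)
}
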