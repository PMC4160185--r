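# Minimal DSP kernel: Butterworth low-pass design (bilinear transform),
# zero-phase forward-backward IIR filtering, FFT analytic signal, unwrapping.
# Kept free of external dependencies; validated in tests against the analytic
# Butterworth magnitude response and analytic-signal identities.

# polynomial coefficients (highest order first) from complex roots
.poly_from_roots <- function(r) {
  p <- 1
  for (rt in r) p <- c(p, 0) - c(0, p) * rt
  p
}

#' Butterworth low-pass coefficients
#'
#' Digital low-pass Butterworth filter via the bilinear transform with
#' frequency pre-warping. Returns transfer-function coefficients normalized
#' so that `a[1] == 1` and the DC gain is exactly 1.
#'
#' @param order filter order (>= 1)
#' @param cutoff_hz -3 dB cutoff frequency in Hz, must be below Nyquist
#' @param sample_rate_hz sampling rate in Hz
#' @return list with numerator `b` and denominator `a`
#' @keywords internal
butter_lowpass <- function(order, cutoff_hz, sample_rate_hz) {
  stopifnot(order >= 1, cutoff_hz > 0)
  if (cutoff_hz >= sample_rate_hz / 2)
    stop("cutoff_hz (", cutoff_hz, ") must be below the Nyquist frequency (",
         sample_rate_hz / 2, ")")
  n <- as.integer(order)
  # analog prototype poles on the unit circle, left half-plane
  k <- seq_len(n)
  p <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  warped <- 2 * sample_rate_hz * tan(pi * cutoff_hz / sample_rate_hz)
  p <- warped * p
  fs2 <- 2 * sample_rate_hz
  z_poles <- (fs2 + p) / (fs2 - p)
  a <- Re(.poly_from_roots(z_poles))
  b <- Re(.poly_from_roots(rep(-1 + 0i, n)))  # n zeros at z = -1
  # unity gain at DC (z = 1)
  b <- b * sum(a) / sum(b)
  list(b = b / a[1], a = a / a[1])
}

# direct-form IIR filter, zero initial conditions
.iir_filter <- function(b, a, x) {
  nb <- length(b)
  xp <- c(rep(0, nb - 1), x)
  v <- as.numeric(stats::filter(xp, b, method = "convolution", sides = 1))
  v <- v[nb:length(xp)]
  if (length(a) > 1) {
    y <- stats::filter(v, -a[-1], method = "recursive")
    as.numeric(y)
  } else v
}

# forward-backward filtering with odd (point-reflected) end extension,
# padding of 3 x (filter length) samples as in common filtfilt practice
.filtfilt <- function(b, a, x) {
  n <- length(x)
  pad <- min(n - 1, 3 * max(length(a), length(b)))
  if (pad > 0) {
    pre <- 2 * x[1] - x[seq(pad + 1, 2)]
    post <- 2 * x[n] - x[seq(n - 1, n - pad)]
    xe <- c(pre, x, post)
  } else xe <- x
  # filter relative to the starting level: with unity DC gain this equals
  # steady-state initial conditions for the step component and removes the
  # startup transient on offset signals
  run <- function(z) .iir_filter(b, a, z - z[1]) + z[1]
  y <- run(xe)
  y <- rev(run(rev(y)))
  y[(pad + 1):(pad + n)]
}

#' Analytic signal via the FFT
#'
#' @param x real-valued signal
#' @return complex vector, the analytic signal of `x`
#' @keywords internal
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    if (n > 2) h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    if (n > 1) h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

#' Unwrap a phase sequence
#'
#' Removes jumps larger than `pi` between adjacent samples by adding
#' multiples of `2*pi`.
#'
#' @param p phase in radians
#' @return unwrapped phase in radians
#' @keywords internal
unwrap_phase <- function(p) {
  if (length(p) < 2) return(p)
  dp <- diff(p)
  corr <- -2 * pi * round(dp / (2 * pi))
  corr[abs(dp) <= pi] <- 0
  p + c(0, cumsum(corr))
}
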