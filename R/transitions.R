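# Bow-change detection and per-transition feature extraction: both relative
# phase estimates (Hilbert-based, time-domain), both normalized-range
# estimates (amplitude-based, time-domain), inclination offset and context
# indices. Features that cannot be computed are emitted as missing with a
# reason code, never silently dropped.

# all zero-crossing times of y(t), sub-sample by linear interpolation;
# exact-zero runs contribute one event when the flanking signs differ or the
# run touches a series boundary
.zero_crossings <- function(t, y) {
  n <- length(y)
  s <- sign(y)
  i <- which(s[-n] * s[-1] < 0)
  times <- t[i] + y[i] / (y[i] - y[i + 1]) * (t[i + 1] - t[i])
  r <- rle(s == 0)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (k in which(r$values)) {
    a <- starts[k]; b <- ends[k]
    before <- if (a > 1) s[a - 1] else 0
    after <- if (b < n) s[b + 1] else 0
    if (before == 0 && after == 0) next
    if (before * after <= 0) times <- c(times, t[a])
  }
  sort(times)
}

.interp <- function(t, y, xout) stats::approx(t, y, xout = xout, rule = 2)$y

#' Detect bow changes as zero crossings of bow velocity
#'
#' Each sign change of the (filtered) bow-velocity signal is one bow change;
#' the crossing time is obtained sub-sample by linear interpolation between
#' the bracketing samples. An exactly-zero sample yields an event at that
#' sample's time. Direction follows the sign convention down-bow = positive:
#' a crossing into negative velocity is `down_to_up`.
#'
#' @param velocity bow-velocity samples (low-pass filtered upstream)
#' @param sample_rate_hz sampling rate in Hz
#' @param time optional time vector (defaults to a zero-based uniform grid)
#' @return data.frame with columns `index`, `t_bc`, `direction`; zero rows if
#'   the signal never crosses zero
#' @export
detect_bow_changes <- function(velocity, sample_rate_hz, time = NULL) {
  n <- length(velocity)
  t <- if (is.null(time)) (0:(n - 1)) / sample_rate_hz else time
  tc <- .zero_crossings(t, velocity)
  if (!length(tc))
    return(data.frame(index = integer(0), t_bc = numeric(0),
                      direction = character(0)))
  dir <- vapply(tc, function(e) {
    j <- which(t > e + 1e-12 & velocity != 0)
    if (length(j)) {
      if (velocity[j[1]] < 0) "down_to_up" else "up_to_down"
    } else {
      k <- which(t < e - 1e-12 & velocity != 0)
      if (velocity[k[length(k)]] > 0) "down_to_up" else "up_to_down"
    }
  }, character(1))
  data.frame(index = seq_along(tc), t_bc = tc, direction = dir)
}

#' Discard the first and last beat of a selection
#'
#' Only stable coordination behavior is analyzed: the first and the last beat
#' (`notes_per_beat` bow changes each) of every selection are dropped.
#'
#' @param events data.frame of bow changes (see [detect_bow_changes()])
#' @param notes_per_beat sixteenth notes per beat (default 4)
#' @return the trimmed events, original `index` preserved
#' @export
trim_selection <- function(events, notes_per_beat = 4) {
  n <- nrow(events)
  if (n <= 2 * notes_per_beat)
    stop("too few events (", n, ") to discard the first and last beat")
  out <- events[(notes_per_beat + 1):(n - notes_per_beat), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Local cycle duration at a bow change
#'
#' Duration of the full velocity cycle centered on a transition: the time
#' between the two same-direction bow changes bracketing it. At segment edges
#' the nearest available full cycle is used instead.
#'
#' @param events data.frame of bow changes
#' @param i row index of the event of interest
#' @return seconds
#' @export
cycle_duration <- function(events, i) {
  t <- events$t_bc
  n <- length(t)
  if (n < 3)
    stop("need at least 3 bow changes to measure a full cycle")
  if (i > 1 && i < n) t[i + 1] - t[i - 1]
  else if (i == 1) t[3] - t[1]
  else t[n] - t[n - 2]
}

#' Time of the string-crossing center belonging to a bow change
#'
#' Sub-sample time at which bow inclination intersects the band center,
#' paired with the bow change as the nearest crossing. If the nearest
#' crossing is farther than `max_pair_frac` of the cycle away (e.g. the
#' non-crossing bow changes of the figure-of-eight, or an inclination offset
#' keeping the movement outside the center), the feature is missing (`NA`).
#'
#' @param inclination inclination samples (degrees)
#' @param sample_rate_hz sampling rate
#' @param band_center band-center inclination (scalar or per-sample vector)
#' @param t_bc bow-change time (seconds)
#' @param cycle_dur local cycle duration (seconds)
#' @param time optional time vector
#' @param max_pair_frac pairing window as a fraction of the cycle (default
#'   1/4: beyond a quarter cycle the crossing belongs to another transition)
#' @return seconds, or `NA` if no crossing belongs to this transition
#' @export
crossing_center_time <- function(inclination, sample_rate_hz, band_center,
                                 t_bc, cycle_dur, time = NULL,
                                 max_pair_frac = 0.25) {
  n <- length(inclination)
  t <- if (is.null(time)) (0:(n - 1)) / sample_rate_hz else time
  cr <- .zero_crossings(t, inclination - band_center)
  if (!length(cr)) return(NA_real_)
  j <- which.min(abs(cr - t_bc))
  if (abs(cr[j] - t_bc) > max_pair_frac * cycle_dur) return(NA_real_)
  cr[j]
}

#' Time-domain relative phase
#'
#' Time difference between the bow change and the intersection with the
#' string-crossing center, normalized by the cycle duration and expressed in
#' degrees: `360 * (t_bc - t_center) / cycle_dur`. Positive when the center
#' crossing precedes the bow change, i.e. when bow inclination leads.
#'
#' @param t_bc bow-change time (seconds)
#' @param t_center band-center crossing time (seconds)
#' @param cycle_dur cycle duration (seconds, > 0)
#' @return degrees
#' @export
time_domain_phase <- function(t_bc, t_center, cycle_dur) {
  stopifnot(all(cycle_dur > 0))
  360 * (t_bc - t_center) / cycle_dur
}

#' Duration of a string-crossing transition
#'
#' Sub-sample time spent inside the string-crossing band (|inclination -
#' center| < half-width) for the traversal containing `t_center`. Missing if
#' there is no traversal (no `t_center`), if the band is wider than the
#' inclination extent (the movement never leaves the band), or if the
#' traversal touches the edge of the recording.
#'
#' @param inclination inclination samples (degrees)
#' @param sample_rate_hz sampling rate
#' @param band_center scalar or per-sample band center (degrees)
#' @param band_halfwidth scalar or per-sample band half-width (degrees)
#' @param t_center crossing-center time from [crossing_center_time()]
#' @param time optional time vector
#' @return seconds, or `NA`
#' @export
transition_duration <- function(inclination, sample_rate_hz, band_center,
                                band_halfwidth, t_center, time = NULL) {
  if (is.na(t_center)) return(NA_real_)
  n <- length(inclination)
  t <- if (is.null(time)) (0:(n - 1)) / sample_rate_hz else time
  h <- abs(inclination - band_center) - band_halfwidth   # < 0 inside the band
  j <- which.min(abs(t - t_center))
  if (h[j] >= 0) return(NA_real_)
  a <- j
  while (a > 1 && h[a - 1] < 0) a <- a - 1
  b <- j
  while (b < n && h[b + 1] < 0) b <- b + 1
  if (a == 1 || b == n) return(NA_real_)   # open traversal or band too wide
  entry <- t[a - 1] + h[a - 1] / (h[a - 1] - h[a]) * (t[a] - t[a - 1])
  exit <- t[b] + h[b] / (h[b] - h[b + 1]) * (t[b + 1] - t[b])
  exit - entry
}

#' Time-domain normalized range
#'
#' Inverts the sinusoidal crossing-time relation: a sinusoidal inclination of
#' period `cycle_dur` spends `cycle_dur * asin(r) / pi` inside a band of
#' normalized range `r`, so `r_t = sin(pi * transition_dur / cycle_dur)`.
#'
#' @param transition_dur transition duration (seconds), in `[0, cycle_dur/2]`
#' @param cycle_dur duration of the *inclination* cycle (seconds)
#' @return dimensionless, in `[0, 1]`
#' @export
time_domain_range <- function(transition_dur, cycle_dur) {
  if (is.na(transition_dur)) return(NA_real_)
  stopifnot(cycle_dur > 0)
  if (transition_dur < 0 || transition_dur > cycle_dur / 2 + 1e-12)
    stop("transition duration outside [0, cycle/2]: inconsistent with the sinusoidal model")
  sin(pi * transition_dur / cycle_dur)
}

#' Peak-to-peak inclination extent around a bow change
#'
#' Absolute difference between the inclination values at the nearest local
#' extrema flanking the bow change (the peak before and the peak after).
#'
#' @param inclination inclination samples (degrees, smoothed upstream)
#' @param sample_rate_hz sampling rate
#' @param t_bc bow-change time (seconds)
#' @param time optional time vector
#' @return degrees, or `NA` when a flanking extremum is missing (segment edge
#'   or monotone segment)
#' @export
peak_to_peak_extent <- function(inclination, sample_rate_hz, t_bc, time = NULL) {
  n <- length(inclination)
  t <- if (is.null(time)) (0:(n - 1)) / sample_rate_hz else time
  d <- diff(inclination)
  ext <- which(d[-length(d)] * d[-1] < 0) + 1
  if (!length(ext)) return(NA_real_)
  te <- t[ext]
  before <- ext[te < t_bc]
  after <- ext[te > t_bc]
  if (!length(before) || !length(after)) return(NA_real_)
  abs(inclination[after[1]] - inclination[before[length(before)]])
}

#' Amplitude-based normalized range
#'
#' Width of the string-crossing range at the crossing-center time divided by
#' the peak-to-peak inclination extent. Not defined for the figure-of-eight
#' pattern, where the peak-to-peak extent spans two different string
#' crossings; in that case `NA` is returned.
#'
#' @param width_at_t_center full band width (2 x half-width) at `t_center`,
#'   degrees
#' @param extent peak-to-peak inclination extent, degrees (> 0)
#' @param pattern "CW", "ACW" or "Fo8"
#' @return dimensionless, or `NA` for Fo8 or a missing extent
#' @export
amplitude_normalized_range <- function(width_at_t_center, extent,
                                       pattern = "CW") {
  if (identical(pattern, "Fo8")) return(NA_real_)
  if (is.na(width_at_t_center) || is.na(extent)) return(NA_real_)
  if (extent == 0) stop("zero peak-to-peak extent")
  width_at_t_center / extent
}

#' Inclination offset at a bow change
#'
#' Average of the inclination values at the current and the preceding bow
#' change, relative to the band center. Missing for the first event of a
#' segment.
#'
#' @param inclination inclination samples (degrees)
#' @param sample_rate_hz sampling rate
#' @param t_bc current bow-change time
#' @param t_bc_prev preceding bow-change time, or `NA`
#' @param band_center scalar or per-sample band center
#' @param time optional time vector
#' @return degrees, or `NA`
#' @export
inclination_offset <- function(inclination, sample_rate_hz, t_bc, t_bc_prev,
                               band_center, time = NULL) {
  if (is.na(t_bc_prev)) return(NA_real_)
  n <- length(inclination)
  t <- if (is.null(time)) (0:(n - 1)) / sample_rate_hz else time
  ctr <- if (length(band_center) > 1) .interp(t, band_center, t_bc) else band_center
  (.interp(t, inclination, t_bc) + .interp(t, inclination, t_bc_prev)) / 2 - ctr
}

#' Extract the full per-transition feature table
#'
#' Runs the complete analysis pipeline on one bowing series: zero-phase
#' filtering (velocity 30 Hz, band width 48 Hz), differentiation of
#' inclination into angular velocity (30 Hz), Hilbert-based continuous
#' relative phase, bow-change detection, first/last-beat trimming, and all
#' per-transition features. For the figure-of-eight, the time-domain
#' normalized range is normalized by the inclination cycle (twice the
#' velocity cycle) while both phase estimates use the velocity cycle.
#'
#' @param series a `bowing_series`
#' @param trim discard the first and last beat (default TRUE)
#' @param notes_per_beat sixteenth notes per beat (default 4)
#' @param filters named list of [filter_spec()] as in [default_filters()]
#' @param max_pair_frac crossing/bow-change pairing window, fraction of cycle
#' @return data.frame, one row per retained bow change: context (`index`,
#'   `t_bc`, `direction`, `transition_id`, `bar`, `beat`, `sub_beat`,
#'   `cycle_duration`), features (`delta_phi_hilbert_deg`, `t_center`,
#'   `delta_phi_time_deg`, `transition_duration`, `r_time`,
#'   `peak_to_peak_extent_deg`, `r_amp`, `theta_offset_deg`), reason codes
#'   (`phi_t_reason`, `r_amp_reason`) and condition metadata columns
#' @export
extract_features <- function(series, trim = TRUE, notes_per_beat = 4,
                             filters = default_filters(),
                             max_pair_frac = 0.25) {
  stopifnot(inherits(series, "bowing_series"))
  fs <- series$sample_rate_hz
  pattern <- series$metadata$pattern
  if (is.null(pattern)) pattern <- "CW"
  t <- series$time

  vel_f <- zero_phase_lowpass(series$velocity, filters$velocity, fs)
  incl_f <- zero_phase_lowpass(series$inclination, filters$velocity, fs)
  band_f <- zero_phase_lowpass(series$band_halfwidth, filters$band_width, fs)
  angvel <- differentiate(series$inclination, fs, filters$angular_velocity)

  rel <- relative_phase(continuous_phase(vel_f, fs),
                        continuous_phase(angvel, fs), pattern)

  events <- detect_bow_changes(vel_f, fs, time = t)
  if (nrow(events) < 3)
    stop("fewer than 3 bow changes detected; nothing to analyze")

  center <- series$band_center
  ctr_at <- function(x) if (length(center) > 1) .interp(t, center, x) else center[1]
  crossings <- .zero_crossings(t, incl_f - center)

  n_ev <- nrow(events)
  cyc <- vapply(seq_len(n_ev), function(i) cycle_duration(events, i), numeric(1))
  t_bc <- events$t_bc
  dphi_h <- phase_at(rel, t_bc)

  t_c <- rep(NA_real_, n_ev)
  for (i in seq_len(n_ev)) {
    if (length(crossings)) {
      j <- which.min(abs(crossings - t_bc[i]))
      if (abs(crossings[j] - t_bc[i]) <= max_pair_frac * cyc[i])
        t_c[i] <- crossings[j]
    }
  }
  phi_t_reason <- ifelse(is.na(t_c), "no_crossing", NA_character_)
  dphi_t <- ifelse(is.na(t_c), NA_real_, 360 * (t_bc - t_c) / cyc)

  cyc_incl <- if (pattern == "Fo8") 2 * cyc else cyc
  dur <- vapply(seq_len(n_ev), function(i)
    transition_duration(incl_f, fs, center, band_f, t_c[i], time = t),
    numeric(1))
  r_t <- rep(NA_real_, n_ev)
  ok <- !is.na(dur) & dur <= cyc_incl / 2 + 1e-12
  r_t[ok] <- sin(pi * dur[ok] / cyc_incl[ok])

  p2p <- vapply(t_bc, function(x)
    peak_to_peak_extent(incl_f, fs, x, time = t), numeric(1))
  width_tc <- ifelse(is.na(t_c), NA_real_, 2 * .interp(t, band_f, t_c))
  if (pattern == "Fo8") {
    r_amp <- rep(NA_real_, n_ev)
    r_amp_reason <- rep("fo8_undefined", n_ev)
  } else {
    r_amp <- width_tc / p2p
    r_amp_reason <- ifelse(is.na(r_amp),
                           ifelse(is.na(p2p), "no_extent", "no_crossing"),
                           NA_character_)
  }

  t_prev <- c(NA_real_, t_bc[-n_ev])
  theta_off <- vapply(seq_len(n_ev), function(i)
    inclination_offset(incl_f, fs, t_bc[i], t_prev[i], center, time = t),
    numeric(1))

  idx <- events$index
  trans_per_cycle <- if (pattern == "Fo8") 4L else 2L
  out <- data.frame(
    index = idx,
    t_bc = t_bc,
    direction = events$direction,
    transition_id = ((idx - 1L) %% trans_per_cycle) + 1L,
    bar = ((idx - 1L) %/% 12L) + 1L,
    beat = (((idx - 1L) %% 12L) %/% notes_per_beat) + 1L,
    sub_beat = ((idx - 1L) %% notes_per_beat) + 1L,
    cycle_duration = cyc,
    delta_phi_hilbert_deg = dphi_h,
    t_center = t_c,
    delta_phi_time_deg = dphi_t,
    transition_duration = dur,
    r_time = r_t,
    peak_to_peak_extent_deg = p2p,
    r_amp = r_amp,
    theta_offset_deg = theta_off,
    phi_t_reason = phi_t_reason,
    r_amp_reason = r_amp_reason,
    stringsAsFactors = FALSE
  )
  if (trim) out <- trim_selection(out, notes_per_beat)
  for (nm in names(series$metadata)) {
    v <- series$metadata[[nm]]
    if (length(v) == 1 && is.atomic(v)) out[[nm]] <- v
  }
  rownames(out) <- NULL
  out
}
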