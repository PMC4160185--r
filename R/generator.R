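# Forward simulator for the simplified coordination model of fast repetitive
# bowing patterns: quasi-sinusoidal bow velocity and bow inclination with a
# configurable relative phase, a finite string-crossing band, constant total
# bow force, per-cycle phase jitter and additive measurement noise.

#' Note and movement rate arithmetic
#'
#' Patterns are notated in sixteenth notes, so the note rate is
#' `4 * tempo_bpm / 60` notes per second. Circular patterns (CW/ACW) complete
#' one movement cycle every two notes (one down- plus one up-bow), so the
#' movement frequency is half the note rate; the figure-of-eight inclination
#' movement is half as fast again.
#'
#' @param tempo_bpm quarter-note beats per minute
#' @return notes per second
#' @examples
#' note_rate(92)            # 6.1333... notes/s
#' note_rate(92) / 2        # circular movement frequency, Hz
#' @export
note_rate <- function(tempo_bpm) 4 * tempo_bpm / 60

#' @rdname note_rate
#' @param pattern one of "CW", "ACW", "Fo8"
#' @return movement (stroke) frequency of bow velocity in Hz
#' @export
stroke_frequency <- function(tempo_bpm, pattern = "CW") {
  note_rate(tempo_bpm) / 2
}

#' Noise level for a target signal-to-noise ratio
#'
#' Standard deviation of white Gaussian noise giving the requested SNR for a
#' sinusoid of amplitude `amplitude` (signal RMS = amplitude / sqrt(2)).
#'
#' @param amplitude sinusoid amplitude
#' @param snr_db signal-to-noise ratio in dB
#' @export
snr_noise_sd <- function(amplitude, snr_db) {
  amplitude / sqrt(2) / 10^(snr_db / 20)
}

#' Configuration of the bowing-pattern generator
#'
#' Collects every parameter of the coordination model needed to synthesize one
#' performance sequence. Defaults describe a comfortable fast-forte circular
#' pattern: 92 bpm, relative phase 15 degrees, normalized range 0.32,
#' inclination extent 10 degrees peak to peak, bow-velocity amplitude 0.8 m/s
#' and 0.9 N total bow force.
#'
#' @param pattern "CW" (clockwise), "ACW" (anti-clockwise) or "Fo8"
#'   (figure-of-eight, 2:1 frequency relation of velocity to inclination)
#' @param tempo_bpm quarter-note beats per minute
#' @param sample_rate_hz sampling rate; must exceed twice the highest movement
#'   frequency
#' @param n_bars number of 12-sixteenth-note bars to synthesize
#' @param delta_phi_deg ground-truth relative phase in degrees, positive when
#'   bow inclination leads bow velocity (band-center crossing precedes the bow
#'   change)
#' @param r_norm ground-truth normalized string-crossing range in [0, 1); the
#'   band half-width is derived as `r_norm * incl_peak_to_peak_deg / 2`
#' @param velocity_amp bow-velocity amplitude in m/s (down-bow positive)
#' @param incl_peak_to_peak_deg inclination extent, degrees peak to peak
#' @param incl_offset_deg offset of the inclination oscillation center from
#'   the band center, degrees
#' @param force_total_n constant total bow force in newtons
#' @param incl_shape "sinusoidal", or "triangular_rounded" (linearly changing
#'   inclination with smoothed inversions, the slow-tempo figure-of-eight
#'   realism)
#' @param tri_smooth_frac Gaussian smoothing width for the rounded triangle,
#'   as a fraction of the inclination period (default 0.05)
#' @param noise_sd additive white-noise standard deviation per channel; a
#'   single number (applied to velocity and inclination in their own units) or
#'   a named vector with any of `velocity`, `inclination`, `force`, `band`
#' @param cycle_jitter_sd_deg per-half-cycle Gaussian jitter of the
#'   inclination phase, degrees
#' @param offset_jitter_sd_deg per-cycle Gaussian wander of the inclination
#'   center, degrees (slow drift, piecewise linear)
#' @param band_center_deg inclination of the string-crossing center
#' @param seed integer seed; identical seed and config give a bit-identical
#'   series
#' @return object of class `bowing_config`
#' @export
bowing_config <- function(pattern = c("CW", "ACW", "Fo8"),
                          tempo_bpm = 92,
                          sample_rate_hz = 240,
                          n_bars = 4,
                          delta_phi_deg = 15,
                          r_norm = 0.32,
                          velocity_amp = 0.8,
                          incl_peak_to_peak_deg = 10,
                          incl_offset_deg = 0,
                          force_total_n = 0.9,
                          incl_shape = c("sinusoidal", "triangular_rounded"),
                          tri_smooth_frac = 0.05,
                          noise_sd = 0,
                          cycle_jitter_sd_deg = 0,
                          offset_jitter_sd_deg = 0,
                          band_center_deg = 0,
                          seed = 1L) {
  pattern <- match.arg(pattern)
  incl_shape <- match.arg(incl_shape)
  if (!is.numeric(r_norm) || r_norm < 0 || r_norm >= 1)
    stop("r_norm must lie in [0, 1)")
  if (n_bars < 1) stop("n_bars must be >= 1")
  f_v <- stroke_frequency(tempo_bpm, pattern)
  if (sample_rate_hz <= 2 * f_v)
    stop("sample_rate_hz must exceed twice the movement frequency (",
         2 * f_v, " Hz)")
  ns <- c(velocity = 0, inclination = 0, force = 0, band = 0)
  if (length(noise_sd) == 1 && is.null(names(noise_sd))) {
    ns[c("velocity", "inclination")] <- noise_sd
  } else {
    bad <- setdiff(names(noise_sd), names(ns))
    if (length(bad)) stop("unknown noise channel(s): ", paste(bad, collapse = ", "))
    ns[names(noise_sd)] <- noise_sd
  }
  structure(list(
    pattern = pattern, tempo_bpm = tempo_bpm, sample_rate_hz = sample_rate_hz,
    n_bars = n_bars, delta_phi_deg = delta_phi_deg, r_norm = r_norm,
    velocity_amp = velocity_amp, incl_peak_to_peak_deg = incl_peak_to_peak_deg,
    incl_offset_deg = incl_offset_deg, force_total_n = force_total_n,
    incl_shape = incl_shape, tri_smooth_frac = tri_smooth_frac,
    noise_sd = ns, cycle_jitter_sd_deg = cycle_jitter_sd_deg,
    offset_jitter_sd_deg = offset_jitter_sd_deg,
    band_center_deg = band_center_deg, seed = as.integer(seed)
  ), class = "bowing_config")
}

# triangle wave phase-aligned with sin(x), range [-1, 1]
.triangle <- function(x) (2 / pi) * asin(sin(x))

# Gaussian smoothing with odd end extension; sd in samples
.gauss_smooth <- function(y, sd_samples) {
  if (sd_samples <= 0) return(y)
  m <- ceiling(4 * sd_samples)
  k <- exp(-0.5 * ((-m:m) / sd_samples)^2)
  k <- k / sum(k)
  n <- length(y)
  pre <- 2 * y[1] - y[seq(min(m + 1, n), 2)]
  post <- 2 * y[n] - y[seq(n - 1, max(n - m, 1))]
  ye <- c(pre, y, post)
  out <- as.numeric(stats::filter(ye, k, method = "convolution", sides = 2))
  out[(length(pre) + 1):(length(pre) + n)]
}

# piecewise-linear random modulation anchored every `anchor_dt` seconds
.pw_linear_jitter <- function(t, anchor_dt, sd) {
  if (sd <= 0) return(numeric(length(t)))
  anchors <- seq(min(t) - anchor_dt, max(t) + anchor_dt, by = anchor_dt)
  vals <- stats::rnorm(length(anchors), 0, sd)
  stats::approx(anchors, vals, xout = t, rule = 2)$y
}

#' Generate one bowing-pattern time series
#'
#' Forward-simulates the coordination model. Bow velocity is a sinusoid at the
#' stroke frequency (note rate / 2). Bow inclination oscillates at the same
#' frequency for circular patterns and at half that frequency for the
#' figure-of-eight, phase-advanced so that the band-center crossing precedes
#' the velocity zero crossing by `delta_phi_deg` (expressed in degrees of the
#' velocity cycle). Total bow force is constant and the string-crossing band
#' half-width is `r_norm * incl_peak_to_peak_deg / 2`, so the configured
#' `r_norm` is exactly the amplitude-based normalized range in the noise-free
#' case.
#'
#' @param config a [bowing_config()]
#' @param metadata optional named list of condition descriptors stored with
#'   the series (participant id, dynamic level, string combination, ...)
#' @return object of class `bowing_series`: list with `time`, `velocity`,
#'   `inclination`, `force_total`, `band_halfwidth`, `band_center` (vectors on
#'   a uniform grid), `sample_rate_hz`, `metadata` and the generating `config`
#' @examples
#' ts <- generate_pattern(bowing_config(tempo_bpm = 92, delta_phi_deg = 15))
#' range(ts$velocity)
#' @export
generate_pattern <- function(config, metadata = list()) {
  stopifnot(inherits(config, "bowing_config"))
  set.seed(config$seed)
  fs <- config$sample_rate_hz
  nr <- note_rate(config$tempo_bpm)
  f_v <- nr / 2
  f_th <- if (config$pattern == "Fo8") f_v / 2 else f_v
  dur <- config$n_bars * 12 / nr
  n <- round(dur * fs)
  t <- (0:(n - 1)) / fs

  # inclination phase lead, in degrees of the *inclination* cycle:
  # for Fo8 the configured velocity-cycle phase corresponds to half the
  # inclination-cycle angle (2:1 frequency relation)
  psi_deg <- if (config$pattern == "Fo8") config$delta_phi_deg / 2 else config$delta_phi_deg
  sgn <- if (config$pattern == "ACW") -1 else 1

  jitter_rad <- .pw_linear_jitter(t, 1 / (2 * f_v),
                                  config$cycle_jitter_sd_deg * pi / 180)
  phase_th <- 2 * pi * f_th * t + psi_deg * pi / 180 + jitter_rad

  amp_th <- config$incl_peak_to_peak_deg / 2
  shape <- switch(config$incl_shape,
    sinusoidal = sin(phase_th),
    triangular_rounded = .gauss_smooth(.triangle(phase_th),
                                       config$tri_smooth_frac * fs / f_th))
  offset_wander <- .pw_linear_jitter(t, 1 / f_v, config$offset_jitter_sd_deg)
  inclination <- config$band_center_deg + config$incl_offset_deg +
    offset_wander + sgn * amp_th * shape

  velocity <- config$velocity_amp * sin(2 * pi * f_v * t)
  force_total <- rep(config$force_total_n, n)
  halfwidth <- rep(config$r_norm * config$incl_peak_to_peak_deg / 2, n)

  ns <- config$noise_sd
  if (ns[["velocity"]] > 0) velocity <- velocity + stats::rnorm(n, 0, ns[["velocity"]])
  if (ns[["inclination"]] > 0) inclination <- inclination + stats::rnorm(n, 0, ns[["inclination"]])
  if (ns[["force"]] > 0) force_total <- force_total + stats::rnorm(n, 0, ns[["force"]])
  if (ns[["band"]] > 0) halfwidth <- pmax(0, halfwidth + stats::rnorm(n, 0, ns[["band"]]))

  meta <- utils::modifyList(list(pattern = config$pattern,
                                 tempo_bpm = config$tempo_bpm), metadata)
  structure(list(
    time = t, velocity = velocity, inclination = inclination,
    force_total = force_total, band_halfwidth = halfwidth,
    band_center = rep(config$band_center_deg, n),
    sample_rate_hz = fs, metadata = meta, config = config
  ), class = "bowing_series")
}

#' @export
print.bowing_series <- function(x, ...) {
  cat("<bowing_series> ", x$metadata$pattern, " at ", x$metadata$tempo_bpm,
      " bpm, ", length(x$time), " samples @ ", x$sample_rate_hz, " Hz (",
      sprintf("%.2f", max(x$time)), " s)\n", sep = "")
  invisible(x)
}

#' Cross-fade bow force across the string-crossing band
#'
#' Splits the constant total bow force between the two strings as a function
#' of the normalized band coordinate `u = (inclination - band_center) /
#' band_halfwidth`. Outside the band all force is on one string; inside it the
#' force is partitioned monotonically, linearly in `u` by default or with a
#' raised-cosine law. A zero band width produces a step transfer at the band
#' center. The two channels sum to the total force at every sample.
#'
#' @param series a `bowing_series`
#' @param law "linear" or "raised_cosine"
#' @return data.frame with `force_upper` (higher-pitched string, larger
#'   inclination) and `force_lower`
#' @export
crossfade_forces <- function(series, law = c("linear", "raised_cosine")) {
  stopifnot(inherits(series, "bowing_series"))
  law <- match.arg(law)
  dev <- series$inclination - series$band_center
  w <- series$band_halfwidth
  u <- ifelse(w > 0, dev / w, ifelse(dev >= 0, Inf, -Inf))
  u <- pmax(-1, pmin(1, u))
  frac <- switch(law,
    linear = (u + 1) / 2,
    raised_cosine = (1 + sin(pi * u / 2)) / 2)
  data.frame(force_upper = frac * series$force_total,
             force_lower = (1 - frac) * series$force_total)
}

#' The controlled-condition grid
#'
#' Enumerates the 20 controlled conditions: two dynamic-level blocks (forte
#' and piano; CW and Fo8, each in two string transpositions, played between
#' 92 and 112 bpm without metronome) and four tempo blocks (58, 72, 92 and
#' 112 bpm with metronome; CW, ACW and Fo8 with a fixed string combination
#' per pattern).
#'
#' @return data.frame with columns `block`, `tempo_bpm`, `tempo_label`,
#'   `dynamic`, `pattern`, `strings`
#' @export
frbp_conditions <- function() {
  dyn <- expand.grid(dynamic = c("forte", "piano"),
                     pattern = c("CW", "Fo8"),
                     transposition = 1:2,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  dyn$strings <- ifelse(dyn$pattern == "CW",
                        c("E-A", "A-D")[dyn$transposition],
                        c("E-A-D", "A-D-G")[dyn$transposition])
  dyn$block <- "dynamic_level"
  dyn$tempo_bpm <- 102          # played between 92 and 112 bpm, no metronome
  dyn$tempo_label <- "92-112"
  tem <- expand.grid(tempo_bpm = c(58, 72, 92, 112),
                     pattern = c("CW", "ACW", "Fo8"),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tem$strings <- c(CW = "E-A", ACW = "A-D", Fo8 = "E-A-D")[tem$pattern]
  tem$block <- "tempo"
  tem$dynamic <- "forte"
  tem$tempo_label <- as.character(tem$tempo_bpm)
  cols <- c("block", "tempo_bpm", "tempo_label", "dynamic", "pattern", "strings")
  rbind(dyn[cols], tem[cols])
}

#' Generate a full protocol sequence for one condition
#'
#' Six seamlessly repeated 12-note bars (72 sixteenth notes). The dynamic
#' level is realized through force-coupled band width: the band half-width is
#' proportional to total bow force (`w = k * F`, with `k` fixed by the forte
#' preset), and the piano preset halves bow force, band width and velocity
#' amplitude, reproducing a factor-two width difference between forte and
#' piano.
#'
#' @param condition one row of [frbp_conditions()] (data.frame or list), or a
#'   condition label matched against that grid
#' @param config a [bowing_config()] used as template; pattern, tempo and
#'   dynamic-level fields are overridden by the condition
#' @return a `bowing_series` with populated metadata
#' @export
generate_protocol_sequence <- function(condition, config = bowing_config()) {
  if (is.character(condition)) {
    grid <- frbp_conditions()
    key <- paste(grid$block, grid$pattern, grid$tempo_label, grid$dynamic,
                 grid$strings, sep = "/")
    i <- match(condition, key)
    if (is.na(i)) stop("unknown condition label: ", condition)
    condition <- grid[i, ]
  }
  condition <- as.list(condition)
  req <- c("pattern", "tempo_bpm", "dynamic", "strings")
  if (!all(req %in% names(condition)))
    stop("condition must provide: ", paste(req, collapse = ", "))
  if (!condition$pattern %in% c("CW", "ACW", "Fo8"))
    stop("unknown pattern: ", condition$pattern)

  cfg <- config
  cfg$pattern <- condition$pattern
  cfg$tempo_bpm <- condition$tempo_bpm
  cfg$n_bars <- 6
  if (identical(condition$dynamic, "piano")) {
    cfg$force_total_n <- cfg$force_total_n / 2
    cfg$velocity_amp <- cfg$velocity_amp * 0.6
    cfg$r_norm <- cfg$r_norm / 2   # w = k * F with k from the forte preset
  }
  # revalidate through the constructor
  cfg <- do.call(bowing_config, unclass(cfg))
  generate_pattern(cfg, metadata = condition)
}

#' Write / read a bowing time series as annotated CSV
#'
#' Plain CSV with columns `time`, `velocity`, `inclination`, `force_total`,
#' `band_halfwidth`, `band_center`, preceded by commented (`#`) header lines
#' carrying the sample rate and condition metadata.
#'
#' @param series a `bowing_series`
#' @param path file path
#' @export
write_bowing_csv <- function(series, path) {
  stopifnot(inherits(series, "bowing_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# sample_rate_hz: ", series$sample_rate_hz), con)
  for (nm in names(series$metadata))
    writeLines(paste0("# ", nm, ": ", series$metadata[[nm]]), con)
  df <- data.frame(time = series$time, velocity = series$velocity,
                   inclination = series$inclination,
                   force_total = series$force_total,
                   band_halfwidth = series$band_halfwidth,
                   band_center = series$band_center)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bowing_csv
#' @return `read_bowing_csv`: the reconstructed `bowing_series` (without the
#'   generating config)
#' @export
read_bowing_csv <- function(path) {
  lines <- readLines(path, n = 64)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^#\\s*", "", h)
    key <- sub(":.*$", "", kv)
    val <- sub("^[^:]*:\\s*", "", kv)
    num <- suppressWarnings(as.numeric(val))
    meta[[key]] <- if (!is.na(num)) num else val
  }
  df <- utils::read.csv(path, comment.char = "#")
  fs <- meta$sample_rate_hz
  if (is.null(fs)) fs <- 1 / stats::median(diff(df$time))
  meta$sample_rate_hz <- NULL
  structure(list(time = df$time, velocity = df$velocity,
                 inclination = df$inclination, force_total = df$force_total,
                 band_halfwidth = df$band_halfwidth,
                 band_center = df$band_center,
                 sample_rate_hz = fs, metadata = meta, config = NULL),
            class = "bowing_series")
}
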