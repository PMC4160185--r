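fs <- 240

test_that("bow changes sit at the roots of the velocity signal", {
  t <- seq(0, 2, by = 1 / fs)
  ev <- detect_bow_changes(sin(2 * pi * 3.05 * t), fs, time = t)
  half <- 1 / (2 * 3.05)
  expected <- seq(0, 2, by = half)
  expected <- expected[expected <= max(t)]
  expect_equal(nrow(ev), length(expected))
  # sub-sample accuracy against the analytic roots
  expect_lt(max(abs(ev$t_bc - expected)), 1 / (10 * fs))
  # alternating directions, first stroke is a down-bow
  expect_true(all(ev$direction == rep(c("up_to_down", "down_to_up"),
                                      length.out = nrow(ev))))
  # no crossings -> empty list; exact zero sample -> event at that time
  expect_equal(nrow(detect_bow_changes(rep(1, 50), fs)), 0)
  ev0 <- detect_bow_changes(c(-2, -1, 0, 1, 2), 1, time = 0:4)
  expect_equal(ev0$t_bc, 2)
})

test_that("first/last-beat trimming follows the selection rule", {
  ev <- data.frame(index = 1:72, t_bc = (1:72) / 6,
                   direction = rep(c("a", "b"), 36))
  expect_equal(nrow(trim_selection(ev)), 64)
  expect_equal(trim_selection(ev)$index[1], 5)
  ev9 <- ev[1:9, ]
  expect_equal(nrow(trim_selection(ev9)), 1)
  expect_error(trim_selection(ev[1:8, ]), "too few")
})

test_that("cycle duration uses the bracketing same-direction bow changes", {
  ts <- make_series(tempo_bpm = 92, n_bars = 2)
  ev <- detect_bow_changes(ts$velocity, fs)
  T_true <- 1 / (note_rate(92) / 2)
  expect_equal(cycle_duration(ev, 5), T_true, tolerance = 1e-4)
  expect_equal(cycle_duration(ev, 1), T_true, tolerance = 1e-4)   # edge fallback
  expect_equal(cycle_duration(ev, nrow(ev)), T_true, tolerance = 1e-4)
  expect_error(cycle_duration(ev[1:2, ], 1), "at least 3")
  # jittered cycles vary per event
  tj <- make_series(tempo_bpm = 92, n_bars = 4, cycle_jitter_sd_deg = 3, seed = 2)
  evj <- detect_bow_changes(zero_phase_lowpass(tj$velocity, filter_spec(2, 30), fs), fs)
  Tj <- vapply(seq_len(nrow(evj)), function(i) cycle_duration(evj, i), numeric(1))
  expect_gt(stats::sd(Tj), 0)
})

test_that("crossing-center timing matches the sinusoidal model", {
  # T = 0.5 s (60 bpm), delta_phi = 15 deg -> t_bc - t_c = 15/360 * 0.5
  ts <- make_series(tempo_bpm = 60, delta_phi_deg = 15, n_bars = 2)
  ev <- detect_bow_changes(ts$velocity, fs)
  i <- 6
  tc <- crossing_center_time(ts$inclination, fs, ts$band_center[1],
                             ev$t_bc[i], 0.5)
  expect_equal(ev$t_bc[i] - tc, 15 / 360 * 0.5, tolerance = 1e-4)
  expect_equal(time_domain_phase(ev$t_bc[i], tc, 0.5), 15, tolerance = 0.1)
  # zero phase: centers coincide with bow changes
  t0 <- make_series(tempo_bpm = 60, delta_phi_deg = 0, n_bars = 2)
  e0 <- detect_bow_changes(t0$velocity, fs)
  tc0 <- crossing_center_time(t0$inclination, fs, 0, e0$t_bc[6], 0.5)
  expect_lt(abs(tc0 - e0$t_bc[6]), 1 / fs)
  # inclination never reaching the center -> missing
  toff <- make_series(tempo_bpm = 60, incl_offset_deg = 8, n_bars = 2)
  expect_true(is.na(crossing_center_time(toff$inclination, fs, 0,
                                         e0$t_bc[6], 0.5)))
})

test_that("time-domain phase is plain normalized-time arithmetic", {
  expect_equal(time_domain_phase(1, 1, 0.5), 0)
  expect_equal(time_domain_phase(1.0208333, 1, 0.5), 15, tolerance = 1e-4)
  expect_error(time_domain_phase(1, 1, 0))
})

test_that("transition duration matches the closed-form crossing time", {
  # sinusoidal inclination, r = 0.5: time in band = T * asin(0.5) / pi = T/6
  T_cyc <- 0.5
  t <- seq(0, 4, by = 1 / 2400)
  th <- 5 * sin(2 * pi * t / T_cyc)
  dur <- transition_duration(th, 2400, 0, 0.5 * 5, t_center = 1, time = t)
  expect_equal(dur, T_cyc / 6, tolerance = 1e-4)
  expect_equal(time_domain_range(dur, T_cyc), 0.5, tolerance = 1e-3)
  # r -> 0: duration -> 0
  dsmall <- transition_duration(th, 2400, 0, 0.01 * 5, t_center = 1, time = t)
  expect_lt(dsmall, 0.01)
  # band wider than the extent -> missing
  expect_true(is.na(transition_duration(th, 2400, 0, 10, t_center = 1,
                                        time = t)))
})

test_that("time-domain range follows the inverse sinusoidal relation", {
  expect_equal(time_domain_range(0.5 / 6, 0.5), 0.5)
  expect_equal(time_domain_range(0, 0.5), 0)
  expect_equal(time_domain_range(0.25, 0.5), 1)
  expect_error(time_domain_range(0.3, 0.5), "sinusoidal")
  expect_true(is.na(time_domain_range(NA, 0.5)))
})

test_that("peak-to-peak extent and amplitude-based range", {
  t <- seq(0, 3, by = 1 / fs)
  th <- 5 * sin(2 * pi * 2 * t)
  expect_equal(peak_to_peak_extent(th, fs, t_bc = 1.5, time = t), 10,
               tolerance = 0.01 * 10)
  # monotone segment has no flanking extrema
  expect_true(is.na(peak_to_peak_extent(th[1:40], fs, t_bc = 0.05,
                                        time = t[1:40])))
  expect_equal(amplitude_normalized_range(3, 10), 0.3)
  expect_true(is.na(amplitude_normalized_range(3, 10, pattern = "Fo8")))
  expect_error(amplitude_normalized_range(3, 0), "zero")
  # per-event extent tracks the local cycle under amplitude jitter: compare
  # against the generator's inclination envelope cycle by cycle
  tsj <- make_series(n_bars = 4, cycle_jitter_sd_deg = 4, seed = 9)
  f <- extract_features(tsj)
  expect_gt(stats::sd(f$peak_to_peak_extent_deg), 0)
  expect_lt(max(abs(f$peak_to_peak_extent_deg - 10)), 2)
})

test_that("inclination offset averages the flanking bow-change values", {
  ts <- make_series(incl_offset_deg = -2, n_bars = 2)
  f <- extract_features(ts)
  expect_equal(mean(f$theta_offset_deg, na.rm = TRUE), -2, tolerance = 0.2)
  t0 <- make_series(incl_offset_deg = 0, n_bars = 2)
  f0 <- extract_features(t0)
  expect_lt(abs(mean(f0$theta_offset_deg, na.rm = TRUE)), 0.1)
  # first event of a segment has no predecessor
  ev <- detect_bow_changes(ts$velocity, fs)
  expect_true(is.na(inclination_offset(ts$inclination, fs, ev$t_bc[1],
                                       NA, 0)))
})

test_that("noise-free feature table recovers all configured parameters", {
  # headline: CW, 92 bpm, 24 cycles, delta_phi 15, r 0.32
  f <- extract_features(make_series(tempo_bpm = 92, n_bars = 4,
                                    delta_phi_deg = 15, r_norm = 0.32))
  expect_true(mean(f$delta_phi_hilbert_deg) > 14.8 &&
              mean(f$delta_phi_hilbert_deg) < 15.2)
  expect_true(mean(f$delta_phi_time_deg, na.rm = TRUE) > 14.8 &&
              mean(f$delta_phi_time_deg, na.rm = TRUE) < 15.2)
  expect_true(mean(f$r_amp, na.rm = TRUE) > 0.315 &&
              mean(f$r_amp, na.rm = TRUE) < 0.325)
  expect_true(mean(f$r_time, na.rm = TRUE) > 0.315 &&
              mean(f$r_time, na.rm = TRUE) < 0.325)
  # the two range estimates coincide under the sinusoidal model
  expect_lt(abs(mean(f$r_amp, na.rm = TRUE) - mean(f$r_time, na.rm = TRUE)),
            1e-3)
})

test_that("Fo8 features respect the pattern's structure", {
  f <- extract_features(make_series(pattern = "Fo8", tempo_bpm = 92,
                                    n_bars = 4, delta_phi_deg = 15,
                                    r_norm = 0.32))
  # r_amp undefined with a reason code
  expect_true(all(is.na(f$r_amp)))
  expect_true(all(f$r_amp_reason == "fo8_undefined"))
  # only the two crossing transitions per pattern cycle carry a
  # time-domain phase; the other two are flagged
  expect_equal(sum(f$phi_t_reason == "no_crossing", na.rm = TRUE),
               sum(is.na(f$delta_phi_time_deg)))
  expect_gt(sum(is.na(f$delta_phi_time_deg)), 0)
  expect_equal(sort(unique(f$transition_id)), 1:4)
  # both estimators recover the truth on crossing transitions
  expect_equal(mean(f$delta_phi_time_deg, na.rm = TRUE), 15, tolerance = 0.2)
  expect_equal(mean(f$r_time, na.rm = TRUE), 0.32, tolerance = 0.005)
})

test_that("time-domain phase variance inflates at high tempo under offset wander", {
  # fixed angular wander of the inclination center; inclination amplitude
  # shrinks with tempo (movement amplitudes are constrained at speed), so
  # the time error maps onto a larger phase error at the shorter cycle
  sd_ratio <- function(bpm, p2p) {
    f <- extract_features(make_series(tempo_bpm = bpm, n_bars = 6,
                                      incl_peak_to_peak_deg = p2p,
                                      offset_jitter_sd_deg = 0.5, seed = 7))
    stats::sd(f$delta_phi_time_deg, na.rm = TRUE) /
      stats::sd(f$delta_phi_hilbert_deg)
  }
  expect_gt(sd_ratio(112, 7), sd_ratio(58, 14))
})
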