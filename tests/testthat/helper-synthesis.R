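# shared fixtures: all synthetic, generated in code

make_series <- function(...) generate_pattern(bowing_config(...))

# feature means for one configuration, noise-free by default
feature_means <- function(..., cols = c("delta_phi_hilbert_deg",
                                        "delta_phi_time_deg",
                                        "r_amp", "r_time")) {
  f <- extract_features(make_series(...))
  vapply(cols, function(cc) mean(f[[cc]], na.rm = TRUE), numeric(1))
}

# noise levels matching a target SNR for the default amplitudes
snr_noise <- function(cfg_amp_v = 0.8, cfg_p2p = 10, snr_db = 30) {
  c(velocity = snr_noise_sd(cfg_amp_v, snr_db),
    inclination = snr_noise_sd(cfg_p2p / 2, snr_db))
}

# least-squares amplitude and phase of a sinusoid at frequency f in x(t)
fit_sinusoid <- function(t, x, f) {
  X <- cbind(sin(2 * pi * f * t), cos(2 * pi * f * t))
  cf <- stats::lm.fit(X, x)$coefficients
  list(amplitude = sqrt(sum(cf^2)), phase_deg = atan2(cf[2], cf[1]) * 180 / pi)
}
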