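# Shared fixtures, built in code.

default_cfg <- pipeline_config()

# a seeded random recording for round-trip checks
random_recording <- function(n = 400, seed = 42, units = "g") {
  set.seed(seed)
  scale <- if (units == "g") 0.5 else 500
  triaxial_recording(rnorm(n, sd = scale), rnorm(n, sd = scale),
                     rnorm(n, sd = scale) + if (units == "g") 1 else 980.665,
                     sampling_rate_hz = 200, units = units,
                     meta = test_meta(subject_id = "RT01", cohort = "patient",
                                      hand = "left", test_item = "rest_3_17",
                                      phase = "pre_insertion",
                                      clinician_score = 2L,
                                      clinician_score_crt = 3L))
}

# acc_series holding a pure sinusoid, amplitude in cm/s^2
sinusoid_acc <- function(freq_hz, amplitude, fs = 200, duration_s = 10,
                         provenance = "filtered_norm", phase = 0) {
  t <- (seq_len(round(fs * duration_s)) - 1) / fs
  acc_series(amplitude * sin(2 * pi * freq_hz * t + phase), fs, provenance)
}

# amplitude of a (near-)sinusoidal series from its RMS over a trimmed
# central region -- robust to edge transients and sample-grid peak misses
rms_amplitude <- function(x, trim_frac = 0.1) {
  n <- length(x)
  i <- seq.int(floor(n * trim_frac) + 1, ceiling(n * (1 - trim_frac)))
  sqrt(2 * mean(x[i]^2))
}

# closed-form two-pass digital Butterworth gain, written out independently
# of the package helper (bilinear transform with prewarping)
oracle_butter_gain2 <- function(f, fc, fs, order = 2, type = "low") {
  r <- tan(pi * f / fs) / tan(pi * fc / fs)
  if (type == "high") r <- 1 / r
  1 / (1 + r^(2 * order))  # two-pass amplitude gain = single-pass |H|^2
}

# feature_set built directly, for scoring-logic tests that need exact
# measure values without running the signal chain
make_features <- function(pauc, amplitude, test_item = "rest_3_17",
                          per_second = NULL,
                          meta = test_meta(test_item = if (test_item == "kinetic_3_16") "kinetic_3_16" else if (test_item == "postural_3_15") "postural_3_15" else "rest_3_17")) {
  structure(list(
    pauc_tremor = pauc, amplitude_cm = amplitude, n_peaks = NA_integer_,
    pauc_per_second = per_second, t_tremor_pct = NA_real_,
    test_item = test_item, meta = meta
  ), class = "feature_set")
}

# simulate + score one rest/postural recording; returns the score_report
simulate_and_score <- function(disp_pp_cm, item = "rest_3_17", seed = 1,
                               freq_hz = 5, noise_sd = 1,
                               burst_windows = NULL,
                               thresholds = default_thresholds(),
                               constancy = FALSE) {
  p <- simulation_params(tremor_freq_hz = freq_hz,
                         disp_peak_to_peak_cm = disp_pp_cm,
                         burst_windows_s = burst_windows,
                         noise_sd_cm_s2 = noise_sd, seed = seed)
  sim <- suppressWarnings(
    simulate_recording(p, default_cfg, test_meta(test_item = item)))
  feats <- compute_features(sim$recording, default_cfg)
  if (constancy) score_constancy(feats, thresholds)
  else score_amplitude_item(feats, thresholds)
}
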