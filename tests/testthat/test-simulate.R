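test_that("the simulator is deterministic given a seed", {
  p <- simulation_params(disp_peak_to_peak_cm = 1.5, noise_sd_cm_s2 = 1,
                         seed = 123)
  a <- simulate_recording(p, default_cfg)
  b <- simulate_recording(p, default_cfg)
  expect_identical(a$recording$ax, b$recording$ax)
  expect_identical(a$recording$az, b$recording$az)
  expect_identical(a$truth, b$truth)

  p2 <- simulation_params(disp_peak_to_peak_cm = 1.5, noise_sd_cm_s2 = 1,
                          seed = 124)
  expect_false(identical(simulate_recording(p2, default_cfg)$recording$ax,
                         a$recording$ax))
})

test_that("quiet input is pure gravity and yields zero band power", {
  p <- simulation_params(disp_peak_to_peak_cm = 0, noise_sd_cm_s2 = 0,
                         seed = 1)
  sim <- simulate_recording(p, default_cfg,
                            test_meta(test_item = "rest_3_17"))
  rec <- to_cm_s2(sim$recording, default_cfg)
  nm <- acceleration_norm(rec)
  expect_equal(nm$values, rep(980.665, 2000), tolerance = 1e-9)
  feats <- compute_features(sim$recording, default_cfg)
  expect_equal(feats$pauc_tremor, 0, tolerance = 1e-12)
  expect_identical(sim$truth$implied_table1_bin, 0L)
})

test_that("generated tremor double-integrates back to the requested displacement", {
  # closed-form consistency across the tremor band and the amplitude
  # range; at 6 Hz the top amplitude is capped at 10 cm so the implied
  # peak acceleration stays inside the recording format's +/-16 g bound
  for (f in c(4, 4.5, 5, 5.5, 6)) {
    for (D in c(0.2, 2, if (f < 6) 12 else 10)) {
      p <- simulation_params(tremor_freq_hz = f, disp_peak_to_peak_cm = D,
                             noise_sd_cm_s2 = 1, seed = 50)
      sim <- suppressWarnings(
        simulate_recording(p, default_cfg,
                           test_meta(test_item = "rest_3_17")))
      expect_equal(sim$truth$true_disp_amplitude_cm, D)
      pre <- preprocess_recording(sim$recording, default_cfg)
      core <- pre$disp$values[51:1950]  # exclude filter edge regions
      amp <- tremor_amplitude(displacement_series(core, 200, 1.2))
      expect_equal(as.numeric(amp), D, tolerance = 0.05,
                   label = sprintf("pipeline amplitude (f=%g, D=%g)", f, D))
    }
  }
})

test_that("burst schedules localize band power and set the truth fraction", {
  p <- simulation_params(disp_peak_to_peak_cm = 2,
                         burst_windows_s = list(c(1, 4)),
                         noise_sd_cm_s2 = 1, seed = 6)
  sim <- suppressWarnings(
    simulate_recording(p, default_cfg, test_meta(test_item = "rest_3_17")))
  expect_equal(sim$truth$true_t_tremor_pct, 30)

  per <- compute_features(sim$recording, default_cfg)$pauc_per_second
  hot <- per > 54
  # edge smearing may light up 3 to 5 segments, centred on seconds 2-4
  expect_gte(sum(hot), 3)
  expect_lte(sum(hot), 5)
  expect_true(all(hot[2:4]))
  expect_true(all(per[6:10] < 54))

  expect_error(
    simulation_params(burst_windows_s = list(c(1, 3), c(2, 5))),
    "disjoint")
  expect_error(simulation_params(burst_windows_s = list(c(3, 1))),
               "start < end")
})

test_that("tremor orthogonal to gravity is rectified by the vector norm", {
  # with the tremor axis perpendicular to gravity the norm linearization
  # breaks down: sqrt(g^2 + a^2) ~ g + a^2 / (2g), so the oscillation is
  # rectified (frequency doubled, amplitude collapsed); the default
  # gravity-aligned geometry avoids this
  D <- 2
  p_orth <- simulation_params(disp_peak_to_peak_cm = D,
                              tremor_axis = c(1, 0, 0),
                              noise_sd_cm_s2 = 0, seed = 3)
  sim <- suppressWarnings(
    simulate_recording(p_orth, default_cfg,
                       test_meta(test_item = "rest_3_17")))
  feats <- compute_features(sim$recording, default_cfg)
  expect_lt(feats$amplitude_cm, 0.25 * D)

  p_par <- simulation_params(disp_peak_to_peak_cm = D, noise_sd_cm_s2 = 0,
                             seed = 3)
  sim_par <- suppressWarnings(
    simulate_recording(p_par, default_cfg,
                       test_meta(test_item = "rest_3_17")))
  feats_par <- compute_features(sim_par$recording, default_cfg)
  expect_equal(feats_par$amplitude_cm, D, tolerance = 0.05)
})

test_that("the strict specific-force model rectifies supra-1g tremor", {
  # with the offset pinned to gravity, |g + a(t)| folds once the tremor
  # acceleration exceeds 1 g: the 4-6 Hz fundamental collapses and the
  # recovered amplitude saturates far below the true displacement
  D <- 5  # implies ~2.5 g tremor acceleration at 5 Hz
  p_strict <- simulation_params(disp_peak_to_peak_cm = D,
                                noise_sd_cm_s2 = 0, seed = 9,
                                offset_mode = "gravity")
  sim <- suppressWarnings(
    simulate_recording(p_strict, default_cfg,
                       test_meta(test_item = "rest_3_17")))
  amp_strict <- compute_features(sim$recording, default_cfg)$amplitude_cm
  expect_lt(amp_strict, 0.6 * D)

  # the linearizing offset transduces the same tremor faithfully
  p_lin <- simulation_params(disp_peak_to_peak_cm = D, noise_sd_cm_s2 = 0,
                             seed = 9)
  sim_lin <- suppressWarnings(
    simulate_recording(p_lin, default_cfg,
                       test_meta(test_item = "rest_3_17")))
  amp_lin <- compute_features(sim_lin$recording, default_cfg)$amplitude_cm
  expect_equal(amp_lin, D, tolerance = 0.05)

  # sub-1g tremor is identical under both modes
  p_small_a <- simulation_params(disp_peak_to_peak_cm = 1, seed = 4)
  p_small_b <- simulation_params(disp_peak_to_peak_cm = 1, seed = 4,
                                 offset_mode = "gravity")
  expect_identical(simulate_recording(p_small_a, default_cfg)$recording$az,
                   simulate_recording(p_small_b, default_cfg)$recording$az)
})

test_that("saturation emulation clips at the sensor range when enabled", {
  p <- simulation_params(disp_peak_to_peak_cm = 12, noise_sd_cm_s2 = 0,
                         seed = 1, clip_at_2g = TRUE)
  sim <- simulate_recording(p, default_cfg)
  expect_lte(max(abs(sim$recording$az)), 2)
  # without clipping the same tremor exceeds the range, with a warning
  p2 <- simulation_params(disp_peak_to_peak_cm = 12, noise_sd_cm_s2 = 0,
                          seed = 1)
  expect_warning(sim2 <- simulate_recording(p2, default_cfg), "sensor range")
  expect_gt(max(abs(sim2$recording$az)), 2)
})

test_that("cohort generation is reproducible and correctly sized", {
  co <- simulate_cohort(n_healthy = 3, n_patients = 0, seed = 5)
  expect_length(co$recordings, 9)  # three test items per healthy subject
  expect_true(all(co$truth$cohort == "healthy"))
  expect_true(all(co$truth$implied_table1_bin == 0))

  co2 <- simulate_cohort(n_healthy = 3, n_patients = 0, seed = 5)
  expect_identical(co$recordings[[1]]$ax, co2$recordings[[1]]$ax)
  expect_identical(co$truth, co2$truth)

  # healthy-only scoring with reference thresholds gives all zeros
  reports <- score_session(co$recordings, default_thresholds(), default_cfg)
  expect_true(all(vapply(reports, function(r) r$acc_score, integer(1)) == 0L))

  # patient bins carry the clinician proxy
  cp <- suppressWarnings(
    simulate_cohort(n_healthy = 0, bin_amplitudes_cm = c(0.5, 6),
                    reps_per_bin = 2, seed = 7))
  expect_length(cp$recordings, 4)
  expect_identical(cp$truth$clinician_proxy,
                   cp$truth$implied_table1_bin)
  expect_setequal(unique(cp$truth$implied_table1_bin), c(1L, 3L))
})
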