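test_that("g to cm/s^2 conversion is exact scalar multiplication", {
  rec <- triaxial_recording(c(1, 0, -2), c(0, 0, 0), c(0.5, 1, 1),
                            units = "g")
  conv <- to_cm_s2(rec, default_cfg)
  expect_identical(conv$units, "cm_s2")
  expect_equal(conv$ax, c(980.665, 0, -1961.33))
  # linearity against a scalar-multiply oracle on random samples
  set.seed(3)
  v <- rnorm(50)
  r2 <- to_cm_s2(triaxial_recording(v, v, v, units = "g"), default_cfg)
  expect_equal(r2$ay, v * 980.665, tolerance = 1e-12)
  # idempotence guard
  expect_warning(to_cm_s2(conv, default_cfg), "already in cm/s\\^2")
})

test_that("acceleration norm is the per-sample Euclidean magnitude", {
  rec <- triaxial_recording(c(3, 0), c(4, 0), c(0, 980.665),
                            units = "cm_s2")
  nm <- acceleration_norm(rec)
  expect_equal(nm$values, c(5, 980.665))

  set.seed(11)
  a <- matrix(rnorm(300, sd = 100), ncol = 3)
  rec <- triaxial_recording(a[, 1], a[, 2], a[, 3], units = "cm_s2")
  oracle <- vapply(seq_len(nrow(a)),
                   function(i) sqrt(sum(a[i, ]^2)), numeric(1))
  expect_equal(acceleration_norm(rec)$values, oracle, tolerance = 1e-12)

  expect_error(acceleration_norm(random_recording(units = "g")),
               "cm/s\\^2")
})

test_that("acceleration band filter rejects DC and matches the analytic response", {
  fs <- 200
  # constant (gravity offset): mean reduced below 1% of the input level
  const <- acc_series(rep(980.665, 2000), fs, "raw_norm")
  filt <- band_filter_acc(const, default_cfg)
  expect_lt(abs(mean(filt$values)), 0.01 * 980.665)

  # 5 Hz sinusoid at the passband center: amplitude preserved within 2%
  s5 <- sinusoid_acc(5, 1, provenance = "raw_norm")
  out <- band_filter_acc(s5, default_cfg)
  expect_equal(rms_amplitude(out$values), 1, tolerance = 0.02)

  # 40 Hz sinusoid: attenuation equals the two-pass 20 Hz low-pass gain.
  # the window covers whole cycles with zero-valued endpoints so the
  # reflection padding introduces no boundary kink into the tiny residual
  t40 <- (0:2000) / fs
  s40 <- acc_series(sin(2 * pi * 40 * t40), fs, "raw_norm")
  out40 <- band_filter_acc(s40, default_cfg)
  gain <- oracle_butter_gain2(40, 20, fs, order = 2, type = "low") *
    oracle_butter_gain2(40, 0.5, fs, order = 2, type = "high")
  # central 60% only: the 0.5 Hz high-pass edge transient decays slowly
  # and would otherwise swamp the strongly attenuated residual
  expect_equal(rms_amplitude(out40$values, trim_frac = 0.2), gain,
               tolerance = 0.05 * gain)

  expect_error(band_filter_acc(acc_series(rnorm(10), fs, "raw_norm"),
                               default_cfg),
               "too short")
})

test_that("centered trapezoidal integration matches closed forms", {
  fs <- 200
  # constant a integrates to a centered ramp of total rise a * t
  a <- 3
  v <- integrate_centered(rep(a, 2000), fs)
  expect_equal(v[2000] - v[1], a * 1999 / fs, tolerance = 1e-9)
  expect_equal(mean(v), 0, tolerance = 1e-12)

  # cos(2 pi f t) of amplitude A integrates to amplitude A / (2 pi f)
  t <- (0:1999) / fs
  A <- 2.5
  f <- 5
  vi <- integrate_centered(A * cos(2 * pi * f * t), fs)
  expect_equal(rms_amplitude(vi), A / (2 * pi * f), tolerance = 0.01)

  # output mean is always zero
  set.seed(5)
  for (k in 1:5) {
    x <- rnorm(300)
    y <- integrate_centered(x, fs)
    expect_lt(abs(mean(y)), 1e-9 * max(abs(y)))
  }
})

test_that("displacement recovers the double-integration closed form", {
  fs <- 200
  A <- 100  # cm/s^2
  f <- 5
  acc <- band_filter_acc(sinusoid_acc(f, A, provenance = "raw_norm"),
                         default_cfg)
  disp <- to_displacement(acc, "rest_3_17", default_cfg)
  expect_s3_class(disp, "displacement_series")
  expect_length(disp$values, 2000)
  expect_equal(disp$hp_cutoff_applied_hz, 1.2)
  expect_equal(rms_amplitude(disp$values), A / (2 * pi * f)^2,
               tolerance = 0.05)

  # 0.8 Hz component is suppressed at least as strongly as the two-pass
  # 1.2 Hz high-pass stop response predicts (double integration of the
  # band-filter residue adds further attenuation)
  acc08 <- band_filter_acc(sinusoid_acc(0.8, A, provenance = "raw_norm"),
                           default_cfg)
  d08 <- to_displacement(acc08, "rest_3_17", default_cfg)
  ideal_disp <- A / (2 * pi * 0.8)^2
  bound <- oracle_butter_gain2(0.8, 1.2, fs, type = "high") * ideal_disp
  expect_lt(rms_amplitude(d08$values), bound * 1.05)

  # kinetic tests use the 3 Hz cutoff: a 1.5 Hz voluntary-movement
  # component is attenuated per the 3 Hz two-pass response
  acc15 <- band_filter_acc(sinusoid_acc(1.5, A, provenance = "raw_norm"),
                           default_cfg)
  d15 <- to_displacement(acc15, "kinetic_3_16", default_cfg)
  expect_equal(d15$hp_cutoff_applied_hz, 3)
  bound15 <- oracle_butter_gain2(1.5, 3, fs, type = "high") *
    A / (2 * pi * 1.5)^2
  expect_lt(rms_amplitude(d15$values), bound15 * 1.10)
  # and the same component survives far better under the rest-test cutoff
  d15_rest <- to_displacement(acc15, "rest_3_17", default_cfg)
  expect_gt(rms_amplitude(d15_rest$values), 3 * rms_amplitude(d15$values))

  expect_error(to_displacement(acc, "unknown_item", default_cfg),
               "unknown test_item")
})

test_that("all filters are zero-phase: time reversal commutes with filtering", {
  set.seed(21)
  x <- acc_series(rnorm(2000, sd = 50), 200, "raw_norm")
  xr <- acc_series(rev(x$values), 200, "raw_norm")
  fwd <- band_filter_acc(x, default_cfg)$values
  revf <- band_filter_acc(xr, default_cfg)$values
  expect_equal(rev(revf), fwd, tolerance = 1e-9)
})

test_that("end-to-end displacement amplitude is recovered across the band", {
  # gravity-aligned tremor: pipeline peak-to-peak within 5% of truth,
  # first/last 0.25 s excluded as filter edge regions
  cfg <- default_cfg
  for (f in c(4, 6)) {
    for (D in c(0.5, 8)) {
      p <- simulation_params(tremor_freq_hz = f, disp_peak_to_peak_cm = D,
                             noise_sd_cm_s2 = 1, seed = 17)
      sim <- suppressWarnings(
        simulate_recording(p, cfg, test_meta(test_item = "rest_3_17")))
      pre <- preprocess_recording(sim$recording, cfg)
      core <- pre$disp$values[51:1950]
      amp <- tremor_amplitude(
        displacement_series(core, 200, pre$disp$hp_cutoff_applied_hz))
      expect_equal(as.numeric(amp), D, tolerance = 0.05,
                   label = sprintf("recovered amplitude (f=%g, D=%g)", f, D))
    }
  }
})
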