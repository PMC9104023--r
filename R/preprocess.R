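# Pre-processing: raw tri-axial acceleration -> filtered 1-D norm ->
# displacement trace.

#' 1-D acceleration series
#'
#' A single-channel acceleration signal in cm/s^2 with its sampling rate and
#' a provenance tag recording whether the band-pass chain has been applied.
#'
#' @param values Numeric vector, cm/s^2.
#' @param sampling_rate_hz Sampling rate, Hz.
#' @param provenance `"raw_norm"` or `"filtered_norm"`.
#' @return An object of class `acc_series`.
#' @export
acc_series <- function(values, sampling_rate_hz,
                       provenance = c("raw_norm", "filtered_norm")) {
  provenance <- match.arg(provenance)
  if (any(!is.finite(values))) stop("acc_series: non-finite values",
                                    call. = FALSE)
  structure(list(values = as.numeric(values),
                 sampling_rate_hz = sampling_rate_hz,
                 provenance = provenance),
            class = "acc_series")
}

#' Displacement series
#'
#' The displacement trace (cm) obtained by double integration of the
#' filtered acceleration norm, with the high-pass cutoff that was applied to
#' remove integration drift.
#'
#' @param values Numeric vector, cm.
#' @param sampling_rate_hz Sampling rate, Hz.
#' @param hp_cutoff_applied_hz The drift-removal high-pass cutoff, Hz.
#' @return An object of class `displacement_series`.
#' @export
displacement_series <- function(values, sampling_rate_hz,
                                hp_cutoff_applied_hz) {
  if (any(!is.finite(values))) stop("displacement_series: non-finite values",
                                    call. = FALSE)
  structure(list(values = as.numeric(values),
                 sampling_rate_hz = sampling_rate_hz,
                 hp_cutoff_applied_hz = hp_cutoff_applied_hz),
            class = "displacement_series")
}

#' Convert a recording from g units to cm/s^2
#'
#' Multiplies every sample by the gravity constant (980.665 cm/s^2 per g by
#' default) and updates the unit flag. Calling it on a recording already in
#' cm/s^2 is a no-op with a warning.
#'
#' @param rec A [triaxial_recording()].
#' @param config A [pipeline_config()].
#' @return The converted [triaxial_recording()].
#' @export
to_cm_s2 <- function(rec, config = pipeline_config()) {
  stopifnot(inherits(rec, "triaxial_recording"))
  if (rec$units == "cm_s2") {
    warning("recording already in cm/s^2; returning unchanged")
    return(rec)
  }
  g <- config$gravity_cm_s2
  triaxial_recording(rec$ax * g, rec$ay * g, rec$az * g,
                     sampling_rate_hz = rec$sampling_rate_hz,
                     units = "cm_s2", meta = rec$meta)
}

#' Acceleration vector norm
#'
#' Reduces the three axes to one series by taking the per-sample Euclidean
#' magnitude `sqrt(ax^2 + ay^2 + az^2)` (the resultant). Static gravity maps
#' to a constant offset that the subsequent 0.5 Hz high-pass removes.
#'
#' @param rec A [triaxial_recording()] in cm/s^2.
#' @return An [acc_series()] with provenance `"raw_norm"`.
#' @export
acceleration_norm <- function(rec) {
  stopifnot(inherits(rec, "triaxial_recording"))
  if (rec$units != "cm_s2") {
    stop("acceleration_norm expects cm/s^2 units; call to_cm_s2() first",
         call. = FALSE)
  }
  acc_series(sqrt(rec$ax^2 + rec$ay^2 + rec$az^2),
             sampling_rate_hz = rec$sampling_rate_hz,
             provenance = "raw_norm")
}

#' Band-limit the acceleration norm
#'
#' Applies, in sequence, a zero-phase 2nd-order high-pass at 0.5 Hz (removes
#' gravity and low-frequency noise) and a zero-phase 2nd-order low-pass at
#' 20 Hz (removes digital noise and higher harmonics). Both passes are
#' forward-backward, so phase is untouched and the effective magnitude
#' response is 4th order.
#'
#' @param acc An [acc_series()].
#' @param config A [pipeline_config()].
#' @return An [acc_series()] with provenance `"filtered_norm"`.
#' @export
band_filter_acc <- function(acc, config = pipeline_config()) {
  stopifnot(inherits(acc, "acc_series"))
  fs <- acc$sampling_rate_hz
  hp <- butter_highpass(config$accel_hp_cutoff_hz, fs, config$filter_order)
  lp <- butter_lowpass(config$accel_lp_cutoff_hz, fs, config$filter_order)
  y <- zero_phase_filter(hp$b, hp$a, acc$values)
  y <- zero_phase_filter(lp$b, lp$a, y)
  acc_series(y, sampling_rate_hz = fs, provenance = "filtered_norm")
}

#' Cumulative trapezoidal integral, mean-centered
#'
#' Integrates a series with the trapezoidal rule (dt = 1/rate) and subtracts
#' the mean of the result, correcting for the arbitrary constant introduced
#' by integration. Applied once to obtain velocity from acceleration and
#' once more for displacement.
#'
#' @param values Numeric vector.
#' @param sampling_rate_hz Sampling rate, Hz.
#' @return Numeric vector of the same length with zero mean.
#' @export
integrate_centered <- function(values, sampling_rate_hz) {
  if (length(values) < 2) stop("need at least 2 samples to integrate",
                               call. = FALSE)
  y <- pracma::cumtrapz(values)[, 1] / sampling_rate_hz
  y - mean(y)
}

#' Displacement trace from filtered acceleration
#'
#' Double-integrates the filtered acceleration norm (trapezoidal rule, each
#' stage mean-centered) and high-passes the result to suppress the
#' low-frequency trends that integration introduces: 1.2 Hz for postural and
#' rest tests, 3 Hz for kinetic tests, where the higher cutoff additionally
#' suppresses voluntary low-frequency arm movement.
#'
#' @param acc_filtered An [acc_series()] produced by [band_filter_acc()].
#' @param test_item Test item string (`"postural_3_15"`, `"kinetic_3_16"` or
#'   `"rest_3_17"`); selects the drift-removal cutoff.
#' @param config A [pipeline_config()].
#' @return A [displacement_series()] in cm.
#' @export
to_displacement <- function(acc_filtered, test_item,
                            config = pipeline_config()) {
  stopifnot(inherits(acc_filtered, "acc_series"))
  if (acc_filtered$provenance != "filtered_norm") {
    stop("to_displacement expects the output of band_filter_acc()",
         call. = FALSE)
  }
  if (!test_item %in% c("postural_3_15", "kinetic_3_16", "rest_3_17")) {
    stop("unknown test_item: ", test_item, call. = FALSE)
  }
  cutoff <- if (test_item == "kinetic_3_16") {
    config$kinetic_disp_hp_cutoff_hz
  } else {
    config$disp_hp_cutoff_hz
  }
  fs <- acc_filtered$sampling_rate_hz
  vel <- integrate_centered(acc_filtered$values, fs)
  disp <- pracma::cumtrapz(vel)[, 1] / fs
  hp <- butter_highpass(cutoff, fs, config$filter_order)
  disp <- zero_phase_filter(hp$b, hp$a, disp)
  displacement_series(disp, sampling_rate_hz = fs,
                      hp_cutoff_applied_hz = cutoff)
}

#' Full pre-processing chain for one recording
#'
#' Convenience wrapper: window the recording, convert g to cm/s^2 if needed,
#' take the vector norm, band-limit it, and derive the displacement trace.
#'
#' @param rec A [triaxial_recording()].
#' @param config A [pipeline_config()].
#' @return A list with elements `acc` (filtered [acc_series()]) and `disp`
#'   (a [displacement_series()]).
#' @export
preprocess_recording <- function(rec, config = pipeline_config()) {
  rec <- segment_to_test_window(rec, config)
  if (rec$units == "g") rec <- to_cm_s2(rec, config)
  acc <- band_filter_acc(acceleration_norm(rec), config)
  disp <- to_displacement(acc, rec$meta$test_item, config)
  list(acc = acc, disp = disp)
}
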