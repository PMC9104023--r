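#' Pipeline configuration
#'
#' Global settings for the accelerometry scoring pipeline: sampling rate,
#' test window, unit conversion, the 4-6 Hz Parkinsonian tremor band, and
#' the Butterworth filter cutoffs used at each stage.
#'
#' The defaults correspond to the standard measurement protocol: 200 Hz
#' tri-axial accelerometry over a 10-second test, acceleration band-limited
#' by a 0.5 Hz high-pass (removes gravity and low-frequency noise) and a
#' 20 Hz low-pass (removes digital noise and higher harmonics), and the
#' displacement trace high-passed at 1.2 Hz (3 Hz for kinetic tests, which
#' contain voluntary low-frequency arm movement). All filters are 2nd-order
#' designs applied forward-backward (zero phase), so the effective
#' magnitude response is 4th order.
#'
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param test_duration_s Duration of one tremor test in seconds.
#' @param gravity_cm_s2 Conversion constant from g units to cm/s^2.
#' @param band_low_hz,band_high_hz Tremor band edges in Hz.
#' @param accel_hp_cutoff_hz High-pass cutoff applied to the acceleration
#'   norm, Hz.
#' @param accel_lp_cutoff_hz Low-pass cutoff applied to the acceleration
#'   norm, Hz.
#' @param disp_hp_cutoff_hz High-pass cutoff applied to the displacement
#'   trace for postural and rest tests, Hz.
#' @param kinetic_disp_hp_cutoff_hz High-pass cutoff applied to the
#'   displacement trace for kinetic tests, Hz.
#' @param filter_order Order of each single-pass Butterworth design.
#'
#' @return An object of class `pipeline_config`.
#' @examples
#' cfg <- pipeline_config()
#' cfg$sampling_rate_hz * cfg$test_duration_s  # 2000 samples per test
#' @export
pipeline_config <- function(sampling_rate_hz = 200,
                            test_duration_s = 10,
                            gravity_cm_s2 = 980.665,
                            band_low_hz = 4,
                            band_high_hz = 6,
                            accel_hp_cutoff_hz = 0.5,
                            accel_lp_cutoff_hz = 20,
                            disp_hp_cutoff_hz = 1.2,
                            kinetic_disp_hp_cutoff_hz = 3,
                            filter_order = 2) {
  cfg <- list(
    sampling_rate_hz = sampling_rate_hz,
    test_duration_s = test_duration_s,
    gravity_cm_s2 = gravity_cm_s2,
    band_low_hz = band_low_hz,
    band_high_hz = band_high_hz,
    accel_hp_cutoff_hz = accel_hp_cutoff_hz,
    accel_lp_cutoff_hz = accel_lp_cutoff_hz,
    disp_hp_cutoff_hz = disp_hp_cutoff_hz,
    kinetic_disp_hp_cutoff_hz = kinetic_disp_hp_cutoff_hz,
    filter_order = as.integer(filter_order)
  )
  class(cfg) <- "pipeline_config"
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  nyquist <- cfg$sampling_rate_hz / 2
  num <- vapply(cfg, is.numeric, logical(1))
  if (!all(num)) {
    stop("pipeline_config: all fields must be numeric", call. = FALSE)
  }
  if (any(unlist(cfg[c(
    "sampling_rate_hz", "test_duration_s", "gravity_cm_s2",
    "band_low_hz", "band_high_hz", "accel_hp_cutoff_hz",
    "accel_lp_cutoff_hz", "disp_hp_cutoff_hz",
    "kinetic_disp_hp_cutoff_hz", "filter_order"
  )]) <= 0)) {
    stop("pipeline_config: all rates, cutoffs and durations must be > 0",
         call. = FALSE)
  }
  if (cfg$band_low_hz >= cfg$band_high_hz) {
    stop("pipeline_config: band_low_hz must be < band_high_hz", call. = FALSE)
  }
  if (!(cfg$accel_hp_cutoff_hz < cfg$accel_lp_cutoff_hz &&
        cfg$accel_lp_cutoff_hz < nyquist)) {
    stop("pipeline_config: need accel_hp_cutoff < accel_lp_cutoff < Nyquist",
         call. = FALSE)
  }
  n_samp <- cfg$test_duration_s * cfg$sampling_rate_hz
  if (abs(n_samp - round(n_samp)) > 1e-9 || n_samp < 1) {
    stop("pipeline_config: test_duration_s x sampling_rate_hz must be a ",
         "positive integer sample count", call. = FALSE)
  }
  cfg
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  cat(sprintf("  %g Hz, %g s window (%d samples)\n", x$sampling_rate_hz,
              x$test_duration_s, n_window_samples(x)))
  cat(sprintf("  tremor band %g-%g Hz\n", x$band_low_hz, x$band_high_hz))
  cat(sprintf("  acceleration filters: HP %g Hz, LP %g Hz (order %d, zero-phase)\n",
              x$accel_hp_cutoff_hz, x$accel_lp_cutoff_hz, x$filter_order))
  cat(sprintf("  displacement HP: %g Hz (kinetic: %g Hz)\n",
              x$disp_hp_cutoff_hz, x$kinetic_disp_hp_cutoff_hz))
  invisible(x)
}

# number of samples in one test window
n_window_samples <- function(cfg) {
  as.integer(round(cfg$test_duration_s * cfg$sampling_rate_hz))
}
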