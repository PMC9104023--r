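# Quantitative tremor measures: periodogram PSD, 4-6 Hz band power (PAUC),
# per-second PAUC, tremor time fraction, and peak-based amplitude.

#' One-sided periodogram PSD estimate
#'
#' Classical periodogram with a rectangular window and no detrending (the
#' 0.5 Hz high-pass already removes DC and slow trends): one-sided density
#' `|X(f)|^2 / (fs * N)` with interior bins doubled, so that the integral of
#' the PSD over frequency equals the mean square of the series (Parseval).
#'
#' @param acc An [acc_series()] (or numeric vector via `values`/`fs`).
#' @return A list of class `spectrum_psd` with `freqs` (Hz, 0..Nyquist) and
#'   `psd` ((cm/s^2)^2 per Hz).
#' @export
periodogram_psd <- function(acc) {
  if (inherits(acc, "acc_series")) {
    x <- acc$values
    fs <- acc$sampling_rate_hz
  } else {
    stop("periodogram_psd expects an acc_series", call. = FALSE)
  }
  n <- length(x)
  if (n < 2) stop("need at least 2 samples", call. = FALSE)
  xf <- stats::fft(x)
  nfreq <- floor(n / 2) + 1
  psd <- (Mod(xf[seq_len(nfreq)])^2) / (fs * n)
  # double the interior bins (one-sided convention); Nyquist bin exists and
  # is not doubled only when n is even
  last_single <- if (n %% 2 == 0) nfreq else nfreq + 1  # index not doubled
  dbl <- setdiff(seq_len(nfreq), c(1, last_single))
  psd[dbl] <- 2 * psd[dbl]
  structure(list(freqs = (seq_len(nfreq) - 1) * fs / n, psd = psd),
            class = "spectrum_psd")
}

#' Band power from a periodogram (PAUC)
#'
#' Trapezoidal integral of the PSD over all grid frequencies `f` with
#' `band_low <= f <= band_high`. For a 10-s window at 200 Hz the grid step
#' is 0.1 Hz and both 4.0 and 6.0 Hz are exact grid points; 1-s segments
#' have a 1 Hz grid, so the band reduces to the points 4, 5 and 6 Hz.
#'
#' @param spec A `spectrum_psd` from [periodogram_psd()].
#' @param config A [pipeline_config()] supplying the band edges.
#' @return Band power in (cm/s^2)^2, non-negative.
#' @export
pauc_band <- function(spec, config = pipeline_config()) {
  stopifnot(inherits(spec, "spectrum_psd"))
  lo <- config$band_low_hz
  hi <- config$band_high_hz
  if (lo < min(spec$freqs) - 1e-9 || hi > max(spec$freqs) + 1e-9) {
    stop(sprintf("band [%g, %g] Hz outside spectral range [%g, %g] Hz",
                 lo, hi, min(spec$freqs), max(spec$freqs)), call. = FALSE)
  }
  keep <- spec$freqs >= lo - 1e-9 & spec$freqs <= hi + 1e-9
  if (sum(keep) < 2) {
    stop("fewer than 2 grid frequencies in the tremor band", call. = FALSE)
  }
  pracma::trapz(spec$freqs[keep], spec$psd[keep])
}

#' Per-second band power of a rest test
#'
#' Cuts the window into non-overlapping 1-s segments (200 samples each at
#' defaults), computes the periodogram band power of each, and returns the
#' values in temporal order — ten values for a 10-s test.
#'
#' @param acc A filtered [acc_series()] covering the full test window.
#' @param config A [pipeline_config()].
#' @return Numeric vector of length `test_duration_s`, (cm/s^2)^2.
#' @export
pauc_per_second <- function(acc, config = pipeline_config()) {
  stopifnot(inherits(acc, "acc_series"))
  fs <- acc$sampling_rate_hz
  n_per <- as.integer(round(fs))
  n_seg <- as.integer(round(config$test_duration_s))
  if (length(acc$values) != n_per * n_seg) {
    stop(sprintf(
      "series length %d does not divide into %d whole 1-s segments of %d samples",
      length(acc$values), n_seg, n_per), call. = FALSE)
  }
  vapply(seq_len(n_seg), function(k) {
    seg <- acc$values[((k - 1) * n_per + 1):(k * n_per)]
    pauc_band(periodogram_psd(acc_series(seg, fs, "filtered_norm")), config)
  }, numeric(1))
}

# indices of local maxima; plateaus contribute their first sample
find_peaks <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  d <- diff(x)
  nz <- which(d != 0)
  if (length(nz) < 2) return(integer(0))
  s <- sign(d[nz])
  turn <- which(s[-length(s)] > 0 & s[-1] < 0)
  nz[turn] + 1L
}

#' Peak-based tremor amplitude
#'
#' Tremor amplitude in cm: twice the mean of the values at all local maxima
#' of the absolute displacement trace. For a pure sinusoid every peak of
#' |d(t)| equals the sinusoid amplitude, so the measure returns the
#' peak-to-peak displacement. No prominence or distance filtering is
#' applied: all peaks count. Returns 0 when no local maxima exist.
#'
#' @param disp A [displacement_series()].
#' @return Amplitude in cm, >= 0. The number of peaks found is attached as
#'   attribute `n_peaks` for diagnostics.
#' @export
tremor_amplitude <- function(disp) {
  stopifnot(inherits(disp, "displacement_series"))
  absd <- abs(disp$values)
  pk <- find_peaks(absd)
  amp <- if (length(pk) == 0) 0 else 2 * mean(absd[pk])
  attr(amp, "n_peaks") <- length(pk)
  amp
}

#' Tremor time fraction
#'
#' Percentage of 1-s segments whose band power exceeds (strictly) the
#' per-second constancy threshold: the constancy-of-rest-tremor measure
#' T_tremor. With 10 segments the result is a multiple of 10%.
#'
#' @param per_second Numeric vector from [pauc_per_second()].
#' @param crt_threshold Per-second band-power threshold, (cm/s^2)^2.
#' @return Percentage in \[0, 100\].
#' @export
tremor_time_fraction <- function(per_second, crt_threshold) {
  if (length(per_second) == 0) stop("empty per-second vector", call. = FALSE)
  if (crt_threshold < 0) stop("threshold must be >= 0", call. = FALSE)
  100 * sum(per_second > crt_threshold) / length(per_second)
}

#' Compute the feature set of one recording
#'
#' Runs the pre-processing chain and derives every quantitative measure for
#' the recording's test item: full-test band power (PAUC), peak-based
#' amplitude, and — for rest tests — the per-second band-power vector. The
#' tremor time fraction is threshold-dependent and is filled in when a
#' per-second threshold is supplied (otherwise `NA`).
#'
#' @param rec A [triaxial_recording()].
#' @param config A [pipeline_config()].
#' @param crt_threshold Optional per-second threshold used to derive
#'   `t_tremor_pct`.
#' @return An object of class `feature_set` with fields `pauc_tremor`,
#'   `amplitude_cm`, `pauc_per_second` (rest tests, else `NULL`),
#'   `t_tremor_pct`, `test_item` and `meta`.
#' @export
compute_features <- function(rec, config = pipeline_config(),
                             crt_threshold = NULL) {
  stopifnot(inherits(rec, "triaxial_recording"))
  pre <- preprocess_recording(rec, config)
  item <- rec$meta$test_item
  pauc <- pauc_band(periodogram_psd(pre$acc), config)
  amp <- tremor_amplitude(pre$disp)
  per_sec <- NULL
  tpct <- NA_real_
  if (item == "rest_3_17") {
    per_sec <- pauc_per_second(pre$acc, config)
    if (!is.null(crt_threshold)) {
      tpct <- tremor_time_fraction(per_sec, crt_threshold)
    }
  }
  structure(list(
    pauc_tremor = pauc,
    amplitude_cm = as.numeric(amp),
    n_peaks = attr(amp, "n_peaks"),
    pauc_per_second = per_sec,
    t_tremor_pct = tpct,
    test_item = item,
    meta = rec$meta
  ), class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %s\n", x$test_item))
  cat(sprintf("  PAUC 4-6 Hz: %.4g (cm/s^2)^2\n", x$pauc_tremor))
  cat(sprintf("  amplitude:   %.4g cm (%d peaks)\n", x$amplitude_cm,
              x$n_peaks))
  if (!is.null(x$pauc_per_second)) {
    cat("  per-second PAUC:", paste(sprintf("%.3g", x$pauc_per_second),
                                    collapse = " "), "\n")
  }
  if (!is.na(x$t_tremor_pct)) {
    cat(sprintf("  T_tremor: %g%%\n", x$t_tremor_pct))
  }
  invisible(x)
}
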