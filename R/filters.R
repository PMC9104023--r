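# Zero-phase IIR filtering.
#
# Butterworth coefficients come from signal::butter; the forward-backward
# application is implemented here with odd-reflection padding and
# steady-state initial conditions, so that a 10-s window with a large
# gravity offset enters the high-pass filter without a startup transient.

# direct-form II transposed IIR filter with explicit initial state
iir_filter <- function(b, a, x, zi = NULL) {
  b <- b / a[1]
  a <- a / a[1]
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  z <- if (is.null(zi)) rep(0, n - 1) else zi
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    xi <- x[i]
    yi <- b[1] * xi + z[1]
    if (n > 2) {
      for (k in seq_len(n - 2)) {
        z[k] <- b[k + 1] * xi + z[k + 1] - a[k + 1] * yi
      }
    }
    z[n - 1] <- b[n] * xi - a[n] * yi
    y[i] <- yi
  }
  y
}

# steady-state filter state for a unit step input: solving
# (I - A^T) zi = B with A the companion matrix of a.
# Scaling zi by the first input sample starts the filter in the state it
# would reach after an infinitely long run of that constant value.
iir_filter_zi <- function(b, a) {
  b <- b / a[1]
  a <- a / a[1]
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  m <- n - 1
  comp <- matrix(0, m, m)
  comp[1, ] <- -a[2:n]
  if (m > 1) comp[cbind(2:m, 1:(m - 1))] <- 1
  rhs <- b[2:n] - a[2:n] * b[1]
  solve(diag(m) - t(comp), rhs)
}

#' Zero-phase filtering of a numeric series
#'
#' Applies an IIR filter forward then backward in time, so the net phase
#' response is zero and the magnitude response is the square of the
#' single-pass response. The series is extended at both ends by odd
#' reflection (`2*x[1] - rev(x)` style), which preserves value and slope at
#' the boundary, and each pass starts from the steady-state initial
#' condition for its first sample. The padding is discarded before
#' returning, so length is preserved.
#'
#' @param b,a Filter numerator/denominator coefficients (e.g. from
#'   [signal::butter()]).
#' @param x Numeric series.
#' @param padlen Number of reflected samples at each end; defaults to
#'   `3 * (max(length(a), length(b)) - 1)` per filter pass, tripled for a
#'   generous margin on low cutoff frequencies.
#' @return Filtered series, same length as `x`.
#' @keywords internal
filtfilt_reflect <- function(b, a, x, padlen = NULL) {
  ntaps <- max(length(a), length(b))
  if (is.null(padlen)) padlen <- 9L * (ntaps - 1L)
  if (length(x) <= padlen) {
    stop(sprintf(
      "series too short for stable zero-phase filtering: %d samples, need > %d",
      length(x), padlen), call. = FALSE)
  }
  # odd reflection about the end values
  left <- 2 * x[1] - x[(padlen + 1):2]
  right <- 2 * x[length(x)] - x[(length(x) - 1):(length(x) - padlen)]
  ext <- c(left, x, right)
  zi <- iir_filter_zi(b, a)
  y <- iir_filter(b, a, ext, zi = zi * ext[1])
  y <- rev(iir_filter(b, a, rev(y), zi = zi * y[length(y)]))
  y[(padlen + 1):(padlen + length(x))]
}

# exactly time-symmetric zero-phase filter: the forward-then-backward and
# backward-then-forward applications share the same steady-state response
# but differ in their boundary transients; averaging the two makes
# filtering commute with time reversal identically and halves the edge
# transient amplitude
zero_phase_filter <- function(b, a, x, padlen = NULL) {
  fb <- filtfilt_reflect(b, a, x, padlen)
  bf <- rev(filtfilt_reflect(b, a, rev(x), padlen))
  (fb + bf) / 2
}

# Butterworth designs (normalized cutoff = f / Nyquist)
butter_highpass <- function(cutoff_hz, fs, order = 2) {
  flt <- signal::butter(order, cutoff_hz / (fs / 2), type = "high")
  list(b = flt$b, a = flt$a)
}

butter_lowpass <- function(cutoff_hz, fs, order = 2) {
  flt <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  list(b = flt$b, a = flt$a)
}

#' Analytic two-pass Butterworth magnitude response
#'
#' Closed-form gain of a zero-phase (forward-backward) application of a
#' digital Butterworth filter designed via the bilinear transform with
#' cutoff prewarping: the single-pass squared magnitude is
#' `1 / (1 + (tan(pi f / fs) / tan(pi fc / fs))^(2n))` for a low-pass (the
#' reciprocal frequency ratio for a high-pass), and the two-pass gain is
#' that squared magnitude. Used as an independent closed form in
#' validation.
#'
#' @param f Frequency at which to evaluate, Hz.
#' @param cutoff_hz Filter cutoff, Hz.
#' @param fs Sampling rate, Hz.
#' @param order Single-pass filter order.
#' @param type `"low"` or `"high"`.
#' @return Two-pass gain in (0, 1].
#' @keywords internal
butter2pass_gain <- function(f, cutoff_hz, fs, order = 2,
                             type = c("low", "high")) {
  type <- match.arg(type)
  wf <- tan(pi * f / fs)
  wc <- tan(pi * cutoff_hz / fs)
  ratio <- if (type == "low") wf / wc else wc / wf
  1 / (1 + ratio^(2 * order))  # single-pass |H|^2 = two-pass |H|
}
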