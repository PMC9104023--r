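# Healthy-cohort thresholds separating score 0 ("no tremor") from >= 1.

#' Threshold set for the four tremor tests
#'
#' Band-power thresholds (in (cm/s^2)^2) gating score 0 versus score >= 1:
#' one per amplitude test (postural, kinetic, rest) plus the per-second
#' threshold used for the constancy measure.
#'
#' @param postural,kinetic,rest Full-test PAUC thresholds, (cm/s^2)^2.
#' @param crt_per_second Per-second PAUC threshold for constancy,
#'   (cm/s^2)^2.
#' @param provenance `"reference"` (shipped constants from the original
#'   healthy-cohort calibration) or `"estimated"` (derived from data via
#'   [estimate_threshold_set()]).
#' @return An object of class `threshold_set`.
#' @export
threshold_set <- function(postural, kinetic, rest, crt_per_second,
                          provenance = c("estimated", "reference")) {
  provenance <- match.arg(provenance)
  vals <- c(postural = postural, kinetic = kinetic, rest = rest,
            crt_per_second = crt_per_second)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all four thresholds must be finite and > 0", call. = FALSE)
  }
  structure(c(as.list(vals), list(provenance = provenance)),
            class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf(
    "<threshold_set> (%s)\n  postural %g | kinetic %g | rest %g | CRT/s %g (cm/s^2)^2\n",
    x$provenance, x$postural, x$kinetic, x$rest, x$crt_per_second))
  invisible(x)
}

#' Reference thresholds from the original healthy-cohort calibration
#'
#' The published mean + 2 SD thresholds derived from a healthy control
#' cohort measured with the same 200 Hz finger-mounted protocol: postural
#' 271, kinetic 6237, rest 55, and per-second constancy 54, all in
#' (cm/s^2)^2. The spread across tests reflects muscle tension and arm
#' movement in each posture. These are shipped constants, not values this
#' package re-derives.
#'
#' @return A [threshold_set()] with provenance `"reference"`.
#' @export
default_thresholds <- function() {
  threshold_set(postural = 271, kinetic = 6237, rest = 55,
                crt_per_second = 54, provenance = "reference")
}

#' One-sample normality check for a threshold pool
#'
#' Kolmogorov-Smirnov-type test of the sample against a normal law with the
#' sample's own mean and SD, used to justify the mean + 2 SD threshold rule.
#' Because the parameters are estimated from the same sample, the classical
#' K-S p-value is anti-conservative; the Lilliefors correction
#' ([nortest::lillie.test()]) is therefore the default, with the classical
#' p-value available via `method = "classical"`.
#'
#' @param values Numeric sample, n >= 4.
#' @param alpha Significance level for the pass flag.
#' @param method `"lilliefors"` (default) or `"classical"`.
#' @return A list of class `normality_result`: `statistic` (max
#'   |ECDF - fitted normal CDF|), `p_value`, `n`, `passed`
#'   (`p_value > alpha`), `method`.
#' @export
ks_normality <- function(values, alpha = 0.05,
                         method = c("lilliefors", "classical")) {
  method <- match.arg(method)
  values <- as.numeric(values)
  if (length(values) < 4) stop("need n >= 4 for the normality check",
                               call. = FALSE)
  if (any(!is.finite(values))) stop("non-finite values", call. = FALSE)
  if (stats::sd(values) == 0) {
    stop("degenerate sample: zero variance", call. = FALSE)
  }
  if (method == "lilliefors" && length(values) < 5) {
    stop("the Lilliefors-corrected test needs n >= 5; ",
         "use method = \"classical\" for n = 4", call. = FALSE)
  }
  if (method == "lilliefors") {
    res <- nortest::lillie.test(values)
    stat <- unname(res$statistic)
    p <- res$p.value
  } else {
    res <- suppressWarnings(
      stats::ks.test(values, "pnorm", mean(values), stats::sd(values)))
    stat <- unname(res$statistic)
    p <- res$p.value
  }
  structure(list(statistic = stat, p_value = p, n = length(values),
                 passed = p > alpha, alpha = alpha, method = method),
            class = "normality_result")
}

#' @export
print.normality_result <- function(x, ...) {
  cat(sprintf("<normality_result> D = %.4f, p = %.4g (n = %d, %s): %s\n",
              x$statistic, x$p_value, x$n, x$method,
              if (x$passed) "consistent with normal" else "not normal"))
  invisible(x)
}

#' Mean + 2 SD threshold from a healthy pool
#'
#' In a normal population about 95% of values fall within two standard
#' deviations of the mean; the upper limit `mean + 2 * sd` (sample SD, n-1
#' denominator) is used as the band-power value separating natural 4-6 Hz
#' variation from tremor. If a normality result is supplied and failed, a
#' warning is emitted (the rule's normal-population rationale does not
#' apply).
#'
#' @param healthy_values Numeric pool of healthy band-power values, n >= 2.
#' @param normality Optional `normality_result` for the pool.
#' @return The threshold, a single number.
#' @export
estimate_threshold <- function(healthy_values, normality = NULL) {
  if (length(healthy_values) < 2) {
    stop("need at least 2 healthy values", call. = FALSE)
  }
  if (!is.null(normality) && !normality$passed) {
    warning("healthy pool failed the normality check; ",
            "the mean + 2 SD rule assumes a normal population")
  }
  mean(healthy_values) + 2 * stats::sd(healthy_values)
}

#' Threshold set from healthy-cohort feature sets
#'
#' Pools the full-test band power of each test item across all healthy
#' recordings (both hands pooled) and applies [estimate_threshold()] per
#' pool. The per-second constancy pool is the concatenation of all
#' per-second band-power values from healthy rest tests. Each pool is run
#' through the normality gate first.
#'
#' @param healthy_features List of `feature_set` objects from healthy
#'   recordings (rest-test features must carry `pauc_per_second`).
#' @param alpha Significance level for the normality gates.
#' @return A [threshold_set()] with provenance `"estimated"`; the four
#'   `normality_result`s are attached as attribute `normality`.
#' @export
estimate_threshold_set <- function(healthy_features, alpha = 0.05) {
  items <- vapply(healthy_features, function(f) f$test_item, character(1))
  pools <- list(
    postural = vapply(healthy_features[items == "postural_3_15"],
                      function(f) f$pauc_tremor, numeric(1)),
    kinetic = vapply(healthy_features[items == "kinetic_3_16"],
                     function(f) f$pauc_tremor, numeric(1)),
    rest = vapply(healthy_features[items == "rest_3_17"],
                  function(f) f$pauc_tremor, numeric(1)),
    crt_per_second = unlist(lapply(healthy_features[items == "rest_3_17"],
                                   function(f) f$pauc_per_second))
  )
  for (nm in names(pools)) {
    if (length(pools[[nm]]) == 0) {
      stop("empty healthy pool: ", nm, call. = FALSE)
    }
  }
  norm_res <- lapply(pools, function(p) {
    # the Lilliefors-corrected test needs n >= 5
    if (length(p) >= 5 && stats::sd(p) > 0) ks_normality(p, alpha) else NULL
  })
  ts <- threshold_set(
    postural = estimate_threshold(pools$postural, norm_res$postural),
    kinetic = estimate_threshold(pools$kinetic, norm_res$kinetic),
    rest = estimate_threshold(pools$rest, norm_res$rest),
    crt_per_second = estimate_threshold(pools$crt_per_second,
                                        norm_res$crt_per_second),
    provenance = "estimated"
  )
  attr(ts, "normality") <- norm_res
  ts
}

#' Write / read a threshold set as JSON
#'
#' @param thresholds A [threshold_set()].
#' @param path File path.
#' @return `path` (write) or a [threshold_set()] (read).
#' @export
write_thresholds <- function(thresholds, path) {
  stopifnot(inherits(thresholds, "threshold_set"))
  jsonlite::write_json(unclass(thresholds), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_thresholds
#' @export
read_thresholds <- function(path) {
  if (!file.exists(path)) stop("thresholds file not found: ", path,
                               call. = FALSE)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  threshold_set(x$postural, x$kinetic, x$rest, x$crt_per_second,
                provenance = x$provenance)
}
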