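# Mapping quantitative measures to objective MDS-UPDRS scores 0-4.
#
# Amplitude bins (items 3.15-3.17): 0 no tremor; 1 at most 1 cm; 2 more
# than 1 but less than 3 cm; 3 between 3 and 10 cm inclusive; 4 more than
# 10 cm. Constancy bins (item 3.18): 1 at most 25% of the time; 2 up to
# 50%; 3 up to 75%; 4 above 75%. A test whose 4-6 Hz band power is below
# its threshold always scores 0, whatever the amplitude or time fraction:
# amplitude outside the tremor band is not tremor.

score_report <- function(test_item, acc_score, features, threshold_used,
                         gate_passed) {
  structure(list(test_item = test_item, acc_score = as.integer(acc_score),
                 features = features, threshold_used = threshold_used,
                 gate_passed = gate_passed),
            class = "score_report")
}

#' @export
print.score_report <- function(x, ...) {
  cat(sprintf("<score_report> %s: score %d (gate %s, threshold %g)\n",
              x$test_item, x$acc_score,
              if (x$gate_passed) "passed" else "failed", x$threshold_used))
  invisible(x)
}

# amplitude (cm) -> score 1..4; boundary policy: <=1 -> 1; (1,3) -> 2;
# [3,10] -> 3; >10 -> 4
amplitude_to_score <- function(amplitude_cm) {
  if (amplitude_cm <= 1) 1L
  else if (amplitude_cm < 3) 2L
  else if (amplitude_cm <= 10) 3L
  else 4L
}

# time fraction (%) -> score 1..4: <=25 -> 1; (25,50] -> 2; (50,75] -> 3;
# >75 -> 4 (with 1-s bins the fraction is a multiple of 10, so the
# 25/26-style gaps in the printed criteria are unreachable)
constancy_to_score <- function(t_tremor_pct) {
  if (t_tremor_pct <= 25) 1L
  else if (t_tremor_pct <= 50) 2L
  else if (t_tremor_pct <= 75) 3L
  else 4L
}

#' Objective score for an amplitude item (3.15, 3.16 or 3.17)
#'
#' If the full-test 4-6 Hz band power is below the item's threshold, the
#' score is 0 ("no tremor"). Otherwise the score follows the clinical
#' amplitude bins: up to 1 cm scores 1, more than 1 but less than 3 cm
#' scores 2, 3 to 10 cm scores 3, above 10 cm scores 4.
#'
#' @param features A `feature_set` from [compute_features()].
#' @param thresholds A [threshold_set()].
#' @return A `score_report`.
#' @export
score_amplitude_item <- function(features, thresholds = default_thresholds()) {
  stopifnot(inherits(features, "feature_set"),
            inherits(thresholds, "threshold_set"))
  th <- switch(features$test_item,
    postural_3_15 = thresholds$postural,
    kinetic_3_16 = thresholds$kinetic,
    rest_3_17 = thresholds$rest,
    stop("unknown test item: ", features$test_item, call. = FALSE)
  )
  if (features$amplitude_cm < 0) {
    stop("negative amplitude is an invariant violation", call. = FALSE)
  }
  gate <- features$pauc_tremor >= th
  score <- if (!gate) 0L else amplitude_to_score(features$amplitude_cm)
  score_report(features$test_item, score, features, th, gate)
}

#' Objective constancy-of-rest-tremor score (item 3.18)
#'
#' A rest recording whose full-test band power is below the rest (3.17)
#' threshold scores 0. Otherwise the tremor time fraction is computed from
#' the per-second band powers against the per-second constancy threshold
#' and binned: up to 25% scores 1, up to 50% scores 2, up to 75% scores 3,
#' above 75% scores 4. A zero time fraction with a passed full-test gate
#' still scores 1 (0% is within "at most 25% of the time"); this signals an
#' inconsistency between the full-test and per-second thresholds and is
#' reported via a warning.
#'
#' @param features A rest-test `feature_set` carrying `pauc_per_second`.
#' @param thresholds A [threshold_set()].
#' @return A `score_report` with `test_item = "constancy_3_18"`.
#' @export
score_constancy <- function(features, thresholds = default_thresholds()) {
  stopifnot(inherits(features, "feature_set"),
            inherits(thresholds, "threshold_set"))
  if (is.null(features$pauc_per_second)) {
    stop("constancy scoring needs the per-second band-power vector ",
         "(rest tests only)", call. = FALSE)
  }
  gate <- features$pauc_tremor >= thresholds$rest
  if (!gate) {
    features$t_tremor_pct <- NA_real_
    return(score_report("constancy_3_18", 0L, features, thresholds$rest,
                        FALSE))
  }
  tpct <- tremor_time_fraction(features$pauc_per_second,
                               thresholds$crt_per_second)
  if (tpct == 0) {
    warning("full-test band power passed the rest gate but no single ",
            "second exceeds the per-second threshold; scoring 1")
  }
  features$t_tremor_pct <- tpct
  score_report("constancy_3_18", constancy_to_score(tpct), features,
               thresholds$rest, TRUE)
}

#' Score a full session of recordings
#'
#' Runs the end-to-end pipeline (window, convert, filter, integrate,
#' features, score) for every recording. Amplitude items map one-to-one;
#' each rest recording additionally yields a constancy (3.18) report, so a
#' session of postural + kinetic + rest recordings produces four reports.
#'
#' @param recordings List of [triaxial_recording()]s.
#' @param thresholds A [threshold_set()].
#' @param config A [pipeline_config()].
#' @return List of `score_report`s.
#' @export
score_session <- function(recordings, thresholds = default_thresholds(),
                          config = pipeline_config()) {
  reports <- list()
  for (rec in recordings) {
    feats <- tryCatch(
      compute_features(rec, config,
                       crt_threshold = thresholds$crt_per_second),
      error = function(e) {
        stop(sprintf("recording %s/%s/%s: %s", rec$meta$subject_id,
                     rec$meta$hand, rec$meta$test_item, conditionMessage(e)),
             call. = FALSE)
      })
    reports[[length(reports) + 1]] <- score_amplitude_item(feats, thresholds)
    if (rec$meta$test_item == "rest_3_17") {
      reports[[length(reports) + 1]] <- score_constancy(feats, thresholds)
    }
  }
  reports
}

#' Flatten score reports to a data frame
#'
#' One row per report with the columns a downstream agreement analysis
#' needs: subject, hand, item, objective score, the measures behind it, and
#' the clinician score carried in the recording metadata (the 3.18
#' clinician score for constancy reports).
#'
#' @param reports List of `score_report`s from [score_session()].
#' @return A data.frame.
#' @export
score_reports_to_df <- function(reports) {
  rows <- lapply(reports, function(r) {
    m <- r$features$meta
    clin <- if (r$test_item == "constancy_3_18") {
      m$clinician_score_crt
    } else {
      m$clinician_score
    }
    data.frame(
      subject = m$subject_id, cohort = m$cohort, hand = m$hand,
      phase = m$phase, item = r$test_item, acc_score = r$acc_score,
      clinician_score = clin,
      pauc_tremor = r$features$pauc_tremor,
      amplitude_cm = r$features$amplitude_cm,
      t_tremor_pct = r$features$t_tremor_pct,
      gate_passed = r$gate_passed,
      threshold_used = r$threshold_used,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
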