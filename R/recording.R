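#' Test metadata for a tremor recording
#'
#' Describes one MDS-UPDRS tremor test: who was measured, which hand, which
#' test item, and (optionally) the clinician's 0-4 rating. Rest recordings
#' may carry two clinician scores because a single rest-test recording is
#' rated both for amplitude (item 3.17) and constancy (item 3.18).
#'
#' @param subject_id Subject identifier string.
#' @param cohort `"healthy"` or `"patient"`.
#' @param hand `"left"` or `"right"`.
#' @param test_item One of `"postural_3_15"`, `"kinetic_3_16"`,
#'   `"rest_3_17"`.
#' @param phase Recording phase: `"pre_insertion"`, `"post_insertion"` or
#'   `"na"` (healthy controls and non-surgical sessions).
#' @param clinician_score Optional integer 0-4: the clinician rating for the
#'   recording's own item.
#' @param clinician_score_crt Optional integer 0-4: the clinician constancy
#'   (3.18) rating, meaningful only for rest recordings.
#' @return An object of class `test_meta`.
#' @export
test_meta <- function(subject_id = "anon",
                      cohort = c("healthy", "patient"),
                      hand = c("right", "left"),
                      test_item = c("rest_3_17", "postural_3_15", "kinetic_3_16"),
                      phase = c("na", "pre_insertion", "post_insertion"),
                      clinician_score = NA_integer_,
                      clinician_score_crt = NA_integer_) {
  cohort <- match.arg(cohort)
  hand <- match.arg(hand)
  test_item <- match.arg(test_item)
  phase <- match.arg(phase)
  for (s in list(clinician_score, clinician_score_crt)) {
    if (!is.na(s) && !(s %in% 0:4)) {
      stop("clinician scores must be integers in 0..4", call. = FALSE)
    }
  }
  structure(list(
    subject_id = as.character(subject_id), cohort = cohort, hand = hand,
    test_item = test_item, phase = phase,
    clinician_score = as.integer(clinician_score),
    clinician_score_crt = as.integer(clinician_score_crt)
  ), class = "test_meta")
}

#' Tri-axial accelerometer recording
#'
#' Container for one recording: three equal-length acceleration channels,
#' the sampling rate, a unit flag (`"g"` or `"cm_s2"`) and test metadata.
#' Raw sensor output is in g units over a +/-2 g range; a sanity bound of
#' |value| <= 16 g is enforced for g-unit data.
#'
#' @param ax,ay,az Numeric vectors, one per axis, equal length >= 2.
#' @param sampling_rate_hz Sampling rate, Hz.
#' @param units `"g"` or `"cm_s2"`.
#' @param meta A [test_meta()] object.
#' @return An object of class `triaxial_recording`.
#' @export
triaxial_recording <- function(ax, ay, az, sampling_rate_hz = 200,
                               units = c("g", "cm_s2"), meta = test_meta()) {
  units <- match.arg(units)
  n <- length(ax)
  if (length(ay) != n || length(az) != n) {
    stop("axis channels must have equal length", call. = FALSE)
  }
  if (n < 2) stop("recording must contain at least 2 samples", call. = FALSE)
  vals <- c(ax, ay, az)
  if (any(!is.finite(vals))) {
    stop("recording contains non-finite samples", call. = FALSE)
  }
  if (units == "g" && max(abs(vals)) > 16) {
    stop("g-unit samples exceed the +/-16 g sanity bound; ",
         "check the unit declaration", call. = FALSE)
  }
  if (!inherits(meta, "test_meta")) stop("meta must be a test_meta object",
                                         call. = FALSE)
  structure(list(
    ax = as.numeric(ax), ay = as.numeric(ay), az = as.numeric(az),
    sampling_rate_hz = sampling_rate_hz, units = units, meta = meta
  ), class = "triaxial_recording")
}

#' @export
print.triaxial_recording <- function(x, ...) {
  cat(sprintf("<triaxial_recording> %d samples @ %g Hz [%s]\n",
              length(x$ax), x$sampling_rate_hz, x$units))
  cat(sprintf("  subject %s (%s), %s hand, %s, phase %s\n",
              x$meta$subject_id, x$meta$cohort, x$meta$hand,
              x$meta$test_item, x$meta$phase))
  invisible(x)
}

#' @export
length.triaxial_recording <- function(x) length(x$ax)

# header fields serialized with a recording, in write order
.meta_fields <- c("subject_id", "cohort", "hand", "test_item", "phase",
                  "clinician_score", "clinician_score_crt")

#' Write a recording to delimited text
#'
#' One row per sample with columns `time_s, ax, ay, az`; metadata, units and
#' sampling rate embedded as `#`-prefixed `key: value` header lines. Values
#' are written with 17 significant digits so a write/read round trip is
#' value-exact.
#'
#' @param rec A [triaxial_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_recording()]
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "triaxial_recording"))
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir, call. = FALSE)
  meta <- rec$meta
  hdr <- c(
    "# tremorscore recording v1",
    sprintf("# units: %s", rec$units),
    sprintf("# sampling_rate_hz: %.17g", rec$sampling_rate_hz),
    vapply(.meta_fields, function(f) {
      sprintf("# %s: %s", f, as.character(meta[[f]]))
    }, character(1))
  )
  n <- length(rec$ax)
  t <- (seq_len(n) - 1) / rec$sampling_rate_hz
  body <- sprintf("%.17g,%.17g,%.17g,%.17g", t, rec$ax, rec$ay, rec$az)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(hdr, "time_s,ax,ay,az", body), con)
  invisible(path)
}

#' Read a recording from delimited text
#'
#' Parses the format written by [write_recording()]: `#`-prefixed header
#' lines declaring units, sampling rate and test metadata, followed by a
#' CSV body with columns `time_s, ax, ay, az`. The embedded sampling rate is
#' validated against the timestamp column (median sample interval must agree
#' within 1%).
#'
#' @param path Input file path.
#' @param config A [pipeline_config()] (used for validation context).
#' @return A [triaxial_recording()].
#' @export
read_recording <- function(path, config = pipeline_config()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  hdr_idx <- grep("^#", lines)
  if (length(hdr_idx) && !identical(hdr_idx, seq_along(hdr_idx))) {
    stop("header lines must precede the data body: ", path, call. = FALSE)
  }
  hdr <- lines[hdr_idx]
  kv <- regmatches(hdr, regexec("^#\\s*([a-z_0-9]+):\\s*(.*)$", hdr))
  fields <- list()
  for (m in kv) if (length(m) == 3) fields[[m[2]]] <- trimws(m[3])

  for (req in c("units", "sampling_rate_hz")) {
    if (is.null(fields[[req]])) {
      stop("recording header is missing required field '", req, "': ", path,
           call. = FALSE)
    }
  }
  if (!fields$units %in% c("g", "cm_s2")) {
    stop("unknown unit declaration '", fields$units, "'", call. = FALSE)
  }
  rate <- as.numeric(fields$sampling_rate_hz)

  body <- lines[-hdr_idx]
  if (length(hdr_idx) == 0) body <- lines
  if (length(body) < 2) stop("no data rows in ", path, call. = FALSE)
  cols <- strsplit(body[1], ",")[[1]]
  need <- c("time_s", "ax", "ay", "az")
  if (!all(need %in% cols)) {
    stop("missing column(s): ", paste(setdiff(need, cols), collapse = ", "),
         " in ", path, call. = FALSE)
  }
  dat <- utils::read.csv(text = paste(body, collapse = "\n"),
                         colClasses = "character")
  num <- lapply(need, function(cn) {
    v <- suppressWarnings(as.numeric(dat[[cn]]))
    bad <- which(is.na(v) & !dat[[cn]] %in% c("NA", ""))
    if (length(bad)) {
      stop(sprintf("non-numeric value in column '%s' at data row %d of %s",
                   cn, bad[1], path), call. = FALSE)
    }
    v
  })
  names(num) <- need

  # timestamps are authoritative for rate validation (no resampling)
  dts <- diff(num$time_s)
  med_dt <- stats::median(dts)
  if (med_dt <= 0 || abs(1 / med_dt - rate) / rate > 0.01) {
    stop(sprintf(
      "sampling-rate mismatch in %s: header says %g Hz, timestamps imply %g Hz",
      path, rate, 1 / med_dt), call. = FALSE)
  }

  pick <- function(f, default) if (is.null(fields[[f]])) default else fields[[f]]
  score_or_na <- function(f) {
    v <- fields[[f]]
    if (is.null(v) || v %in% c("NA", "")) NA_integer_ else as.integer(v)
  }
  meta <- test_meta(
    subject_id = pick("subject_id", "anon"),
    cohort = pick("cohort", "patient"),
    hand = pick("hand", "right"),
    test_item = pick("test_item", "rest_3_17"),
    phase = pick("phase", "na"),
    clinician_score = score_or_na("clinician_score"),
    clinician_score_crt = score_or_na("clinician_score_crt")
  )
  triaxial_recording(num$ax, num$ay, num$az, sampling_rate_hz = rate,
                     units = fields$units, meta = meta)
}

#' Trim a recording to the standard test window
#'
#' Tests last a fixed duration (10 s at defaults, i.e. 2000 samples at
#' 200 Hz); recordings that run long are trimmed to the window starting at
#' `offset_s` (default: the first 10 s).
#'
#' @param rec A [triaxial_recording()].
#' @param config A [pipeline_config()].
#' @param offset_s Start of the window within the recording, seconds.
#' @return A [triaxial_recording()] of exactly
#'   `test_duration_s * sampling_rate_hz` samples.
#' @export
segment_to_test_window <- function(rec, config = pipeline_config(),
                                   offset_s = 0) {
  stopifnot(inherits(rec, "triaxial_recording"))
  n_need <- n_window_samples(config)
  i0 <- as.integer(round(offset_s * rec$sampling_rate_hz)) + 1L
  i1 <- i0 + n_need - 1L
  if (i1 > length(rec$ax)) {
    stop(sprintf(
      "recording too short: need %d samples (window end), have %d (short by %d)",
      i1, length(rec$ax), i1 - length(rec$ax)), call. = FALSE)
  }
  idx <- i0:i1
  triaxial_recording(rec$ax[idx], rec$ay[idx], rec$az[idx],
                     sampling_rate_hz = rec$sampling_rate_hz,
                     units = rec$units, meta = rec$meta)
}
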