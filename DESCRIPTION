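Package: tremorscore
Title: Objective MDS-UPDRS Tremor Scores from Tri-Axial Finger Accelerometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts 10-second tri-axial accelerometer recordings of the
    MDS-UPDRS tremor tests (items 3.15-3.18: postural, kinetic and rest
    tremor amplitude, and constancy of rest tremor) into objective 0-4
    scores. Implements the full signal chain: unit conversion, vector-norm
    reduction, zero-phase Butterworth filtering, numerical double
    integration to displacement, periodogram band power in the 4-6 Hz
    Parkinsonian tremor band (PAUC), peak-based amplitude estimation,
    healthy-cohort mean + 2 SD thresholds, and the ordinal score mapping.
    Also provides the agreement statistics used to compare objective scores
    against clinician ratings (concordance, weighted kappa, RMSE/MAE,
    orthogonal-polynomial trend regression) and a synthetic tremor
    simulator with analytic ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    pracma,
    nortest,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
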