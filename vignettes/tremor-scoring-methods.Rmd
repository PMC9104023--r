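---
title: "Objective tremor scoring from finger accelerometry: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Objective tremor scoring from finger accelerometry: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tremorscore)
```

## The problem

The MDS-UPDRS rates hand tremor on four 0–4 ordinal items: postural
tremor (3.15), kinetic tremor (3.16), rest tremor amplitude (3.17) and
constancy of rest tremor (3.18). The amplitude items are judged by eye in
centimeters; constancy as the estimated fraction of time tremor is
present. That makes the ratings rater-dependent, which matters in
settings — such as intraoperative monitoring during DBS lead placement —
where treatment decisions hinge on small score changes.

`tremorscore` computes these four scores objectively from a 10-second
tri-axial accelerometer recording (200 Hz, sensor at the base of the
index finger). Parkinsonian tremor is dominant in the 4–6 Hz band, so
the central quantity is the band power of the acceleration signal in
that band, written PAUC (area under the periodogram PSD between 4 and
6 Hz, units (cm/s²)²).

## The signal chain

1. **Units and reduction to 1-D.** Raw samples in g are converted to
   cm/s² (× 980.665). The three axes are reduced to the per-sample
   Euclidean magnitude (the resultant). Static gravity becomes a
   constant offset.
2. **Band limiting.** A 2nd-order Butterworth high-pass at 0.5 Hz
   removes the gravity offset and slow drift; a 2nd-order low-pass at
   20 Hz removes digital noise and higher harmonics. Both are applied
   forward–backward (zero phase), so the effective magnitude response is
   4th-order and timing of peaks is preserved.
3. **Band power.** The one-sided periodogram (rectangular window, no
   detrending beyond the high-pass) is integrated by the trapezoidal
   rule over all grid frequencies in [4, 6] Hz. A 10-s window gives a
   0.1 Hz grid, so 4.0 and 6.0 Hz are exact grid points; 1-s segments
   give a 1 Hz grid (points 4, 5, 6 Hz).
4. **Displacement.** The filtered norm is integrated twice
   (cumulative trapezoid, each stage mean-centred), and the displacement
   high-passed at 1.2 Hz to remove integration drift — 3 Hz for kinetic
   tests, where voluntary low-frequency arm movement would otherwise
   dominate. Tremor amplitude is twice the mean of all local maxima of
   the absolute displacement: for a sinusoid this is the peak-to-peak
   displacement in cm, directly comparable to the clinical bins.
5. **Scoring.** A test whose full-window PAUC is below its
   healthy-cohort threshold scores 0, regardless of amplitude — power
   outside 4–6 Hz is movement, not tremor. Otherwise the amplitude maps
   through the clinical bins (≤1 cm → 1, <3 cm → 2, ≤10 cm → 3,
   >10 cm → 4). Constancy uses per-second PAUC values against a
   per-second threshold: the percentage of seconds above it maps through
   ≤25 → 1, ≤50 → 2, ≤75 → 3, >75 → 4, gated by the full-test rest
   threshold.

### Thresholds

The score 0 / score ≥ 1 boundary is the only part that needs data: the
natural 4–6 Hz band power of people without tremor. The rule is
mean + 2 SD of the healthy pool per test item, justified by a one-sample
normality check (Lilliefors-corrected by default, since the normal
parameters are estimated from the same sample; the classical p-value is
anti-conservative). The shipped reference constants are postural 271,
kinetic 6237, rest 55 and per-second 54 (cm/s²)²; their spread reflects
muscle tension and arm movement in each posture.
`estimate_threshold_set()` re-derives thresholds from any healthy
cohort. Note that mean + 2 SD is a one-sided bound: on a normal pool the
expected fraction below it is Φ(2) ≈ 97.7%, not 95%.

## Tunable parameters

| Parameter | Default | Why |
|---|---|---|
| `sampling_rate_hz` | 200 Hz | sensor protocol; Nyquist 100 Hz ≫ 20 Hz low-pass |
| `test_duration_s` | 10 s | clinical test length; 2000 samples, 0.1 Hz PSD grid |
| `band_low/high_hz` | 4–6 Hz | Parkinsonian tremor band |
| `accel_hp_cutoff_hz` | 0.5 Hz | removes gravity and slow noise without touching 4 Hz |
| `accel_lp_cutoff_hz` | 20 Hz | removes digital noise and high harmonics |
| `disp_hp_cutoff_hz` | 1.2 Hz | suppresses double-integration drift |
| `kinetic_disp_hp_cutoff_hz` | 3 Hz | additionally suppresses voluntary arm movement |
| `filter_order` | 2 per pass | 4th-order effective after the zero-phase double pass |

## Numerical choices

- **Zero-phase filtering.** Coefficients come from `signal::butter`;
  the forward–backward application is implemented in-package with
  odd-reflection padding (9 × the filter tap count) and steady-state
  initial conditions per pass, so a constant offset enters the high-pass
  without a startup transient. Because the forward-first and
  reverse-first orderings differ slightly in their boundary transients,
  both are computed and averaged: filtering then commutes exactly with
  time reversal and the edge transient is halved. Edge effects are
  still largest within roughly the first and last 0.25 s for strongly
  attenuated components; feature computation deliberately excludes
  nothing (the clinical window is the full 10 s), while validation
  checks measure amplitudes on the central region.
- **"Norm" reading.** The per-sample Euclidean magnitude is used; a
  windowed RMS interpretation would not yield a sample-rate series on
  which the filter/integration chain is defined.
- **Peaks.** All strict local maxima of |displacement| count, with no
  prominence or distance filter; plateaus contribute their first sample.
  The peak count is attached to the amplitude for diagnostics.
- **Boundaries.** Score bins close so that every printed inequality is
  preserved: amplitudes of exactly 3 or 10 cm score 3; a time fraction
  of exactly 25% scores 1. With 1-s segments the time fraction is a
  multiple of 10%, so the 25/26-style gaps in the printed criteria are
  unreachable. The band-power gate uses strict `<` for "below the
  threshold"; per-second detection uses strict `>` for "above".
- **Degenerate inputs.** Zero recordings yield zero PSD and score 0; a
  passed rest gate with no supra-threshold second scores 1 with a
  warning (it signals inconsistent full-test and per-second
  thresholds); zero-variance pools are rejected by the normality check.

## The synthetic tremor generator

No public recordings exist for this protocol, so validation rests on a
simulator with analytic ground truth. A displacement sinusoid
$d(t) = \tfrac{D}{2}\sin(2\pi f t)$ implies acceleration amplitude
$A = \tfrac{D}{2}(2\pi f)^2$; the generator emits exactly that
acceleration along the gravity axis, plus static offset, optional burst
envelopes (50 ms raised-cosine ramps, so constancy ground truth is
stable at 1-s resolution), optional slow drift and low-frequency
voluntary-movement components, and independent white noise per axis
(default SD 1 cm/s², a realistic broadband MEMS noise floor at this
bandwidth), all emitted in g units. Everything is deterministic given
the seed.

**The linearizing offset.** A norm is non-negative, so no 3-axis signal
can have Euclidean norm $g + A\sin(2\pi ft)$ once $A > g$ — and at 5 Hz,
$A$ reaches 1 g at only ≈2 cm peak-to-peak. Under the strict
specific-force model the norm $|g + a(t)|$ rectifies: the 4–6 Hz
fundamental collapses and a 5 cm tremor is recovered as ≈2 cm. Real
large tremors partly evade this through rotation and changing sensor
orientation, which the measurement model here does not include. The
generator therefore defaults to a static offset of
$\max(g, \max|a(t)|)$: for sub-1g tremor this is exactly gravity, and
in every case the offset is DC, removed unchanged by the 0.5 Hz
high-pass, leaving the band-limited norm an exact linear image of the
tremor acceleration at every clinical amplitude. `offset_mode =
"gravity"` keeps the strict specific-force model; a dedicated test
documents its rectification artifact, as does one for tremor orthogonal
to gravity. Sensor saturation at ±2 g is off by default (tremor above
~2 cm at 5 Hz already exceeds the range mathematically; clipping would
change scores in ways the scoring model does not describe) and can be
enabled for robustness studies.

**Healthy cohort model.** Healthy "natural variation" is gravity plus
axis noise plus a weak continuous oscillation at the 5 Hz band centre
whose band power is drawn per subject from a narrow log-normal (mean
150 / 3500 / 30 (cm/s²)² for postural / kinetic / rest, log-SD 0.15).
At the band centre the window holds whole cycles at both PSD
resolutions, so band power equals $A^2/2$ exactly and the pool moments
have a closed form — this is what lets tests compare estimated
thresholds against analytic values. The pool means are package choices
that reproduce the ordering and rough scale of the reference constants;
they are not fitted to them, and the shipped constants are used for
scoring, never re-derived.

## What the tests show — and what they do not

Validation covers: closed-form filter responses and integration;
Parseval consistency of the periodogram; exact amplitude recovery
(within 5%) across 4–6 Hz and 0.2–12 cm; burst localization at 1-s
resolution; threshold equivariance, Φ(2) coverage and recovery of
analytic pool moments; the full score mapping including boundaries and
gate dominance; ≥95% recovery of generator bin labels over a simulated
cohort; and agreement statistics against hand-computed oracles. Problem
sizes are the clinical ones throughout (2000-sample windows; 26-subject
healthy cohorts; 100-recording patient cohorts).

Synthetic tremor is a gravity-aligned sinusoid. Real tremor has
harmonics, frequency drift, re-emergence dynamics, rotational
components and posture changes, none of which are modelled — so
passing tests demonstrate correctness of the algorithm, not clinical
performance. Two physical limits are documented deliberately: the
Euclidean norm rectifies supra-1g tremor under the strict
specific-force model (see above), and the recording format's ±16 g
sanity bound caps representable tremor at about 11 cm peak-to-peak at
6 Hz (validation uses 10 cm there; at ≤5.5 Hz the full 12 cm range is
covered).

## Known limitations

- Thresholds transfer poorly across contexts: the reference constants
  come from non-intraoperative healthy controls.
- Kinetic tremor is the weakest item by construction: voluntary arm
  movement raises healthy band power, and its harmonics can enter the
  4–6 Hz band.
- All power in 4–6 Hz is attributed to tremor; no dominant-peak
  criterion is applied.
- Amplitude above ~2 cm relies on the linear-transduction idealization
  described above; strictly physical gravity-aligned recordings
  underestimate large amplitudes.

## A worked example

```{r example}
cfg <- pipeline_config()
p <- simulation_params(tremor_freq_hz = 5, disp_peak_to_peak_cm = 2,
                       noise_sd_cm_s2 = 1, seed = 1)
sim <- simulate_recording(p, cfg, test_meta(test_item = "rest_3_17"))
feats <- compute_features(sim$recording, cfg,
                          crt_threshold = default_thresholds()$crt_per_second)
feats
score_amplitude_item(feats, default_thresholds())
score_constancy(feats, default_thresholds())
```
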