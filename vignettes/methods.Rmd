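---
title: "Methods: from raw acceleration to stratified instrument agreement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from raw acceleration to stratified instrument agreement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(activagree)
```

This vignette is the package's account of its methods: the signal model,
the classifier, the questionnaire and adiposity scoring, the agreement
statistics, what the synthetic-cohort generator does and does not emulate,
and the numerical and design choices that were genuinely open.

## 1. Signal model and ENMO

Input is tri-axial acceleration in gravity units sampled at a nominal
60 Hz (the package validates the rate and refuses to resample; non-60 Hz
files error with a clear message). Movement intensity is summarised by
ENMO, the Euclidean norm of the acceleration vector minus one gravity,
negative values truncated to zero:

$$\mathrm{ENMO}(t) = \max\!\left(\sqrt{x_t^2 + y_t^2 + z_t^2} - 1,\; 0\right)$$

computed per sample and averaged over non-overlapping 1 s epochs, reported
in mg (1000 mg = 1 g). Truncation makes the metric zero for any static
posture with magnitude at or below 1 g, and rotation of the sensor frame
leaves it unchanged — both properties are asserted in the test suite to
numerical tolerance. A partially filled trailing second is dropped so the
epoch grid stays exact; timestamp gaps are carried as explicit gap
intervals, flagged on overlapping epochs and counted as missing time,
never interpolated. Unit handling is deliberately single-pointed: raw
files are in g and conversion to mg happens exactly once, at epoch
aggregation. Each epoch also retains its per-axis mean (g, encoding
orientation) and per-axis SD (mg), which is what lets later stages work
from epoch series alone.

## 2. Non-wear and completeness

The source protocol does not state its non-wear algorithm, so the package
adopts the rule that is standard practice for raw-acceleration devices
and, importantly, is testable by construction: any window of at least 60
minutes in which every axis keeps a standard deviation below 13 mg is
flagged non-wear. Both parameters are configuration, not constants.
Windowed SDs are pooled exactly from the per-epoch moments, so the result
equals the SD of the underlying samples. Two consequences are documented
rather than hidden: windows containing recorded gaps never qualify (gaps
are already missing time), and the pooled-SD rule can bleed a few minutes
into active margins around a long stationary block — bounded by the ratio
of the threshold to the active SD and covered by a test.

A recording is excluded when gap plus non-wear time exceeds 120 minutes
over the collection period, read strictly: exactly two hours of missing
data still passes. On a simulated 120-subject cohort with three subjects
given a 150-minute device-off block this reproduces an analytical sample
of 117.

## 3. Activity-type classification

The published analysis delegates its classifier to external work without
parameters, so this package substitutes a transparent decision tree over
window features and states its assumptions plainly. Features per 5 s
window (a whole-second multiple, configurable):

- **Gravity vector**: the per-window mean of each axis. A boxcar mean at
  the window scale is a ~0.1 Hz low-pass — far below any gait cadence —
  with no filter transient; the window length is the cut-off control.
- **Inclination**: angle between that vector and the device vertical
  (+z). The standing reference is 0° by default (device vertical aligned
  with gravity when upright) and configurable; real deployments would
  calibrate it per subject, which the package does not attempt.
- **Dominant frequency**: spectral peak of the window-detrended vector
  magnitude over a 0.5–5 Hz band, quantised to the FFT grid (0.2 Hz at
  5 s windows).
- **Periodicity**: the autocorrelation of the detrended magnitude at the
  dominant lag, normalised by lag-zero power and clamped to [0, 1].
  Because dominant frequencies are grid-quantised, only a handful of lags
  occur and the autocorrelation is evaluated just there.

The tree, all thresholds in `classifier_rules()`: non-wear passes
through; diary sleep intervals override everything worn; windows below
30 mg are sedentary if tilted more than 30° from the standing reference,
else standing; periodic windows (periodicity > 0.3) with cadence in
1.4–2.5 Hz and intensity 50–400 mg are walking; running requires either a
periodic cadence above 2.5 Hz or intensity above 400 mg; remaining
windows at or above the 70 mg MVPA cut-point are "other MVPA context";
any residue falls back on posture. The running rule deliberately demands
periodicity on its cadence branch: an aperiodic moderate-intensity window
has its dominant frequency drawn essentially uniformly over the search
band and would otherwise be called running about half the time.

MVPA flagging is independent of the type label: a worn epoch is MVPA iff
its ENMO is at or above the cut-point (70 mg default, inclusive — the
boundary strictness is not stated in the source and inclusive matches
common cut-point practice). Walking/MVPA overlap is allowed by default
since the two are reported as separate measures; hip-worn sitting versus
standing is separated only through posture tilt, and no real-world
validity is claimed for that separation beyond the simulator's generative
assumptions.

Daily summaries run 09:00–09:00, mirroring a protocol that initialises
recorders at 09:00 on day 1; the boundary hour is configurable since the
source's analysis-day definition is not explicit. Sleep handling follows
the diary: interval diaries label epochs sleep (excluded from sedentary
time); duration-only diaries subtract their minutes from that day's
sedentary total, floored at zero.

## 4. Questionnaire scoring and aggregation

Daily recall items (moderate, vigorous, walking, sitting minutes) are
scored without MET weighting: MVPA is moderate plus vigorous, walking
passes through, sitting becomes sedentary. Items must lie in [0, 1440];
days whose items total more than 1440 minutes are retained with a warning
rather than truncated — silently altering self-report data seemed worse
than tabulating it. Whether the source averaged or summed its three daily
questionnaires per subject is unstated; the package uses the mean over
recorded days for both instruments, for symmetry, with day-level pooling
behind a flag.

## 5. Adiposity categorisation

Three schemes, each ordinal normal/overweight/obese (BIA:
average/high/obese). The printed bands leave gaps (BMI 29.9→30, women's
%fat 25→26, WHR 0.84→0.85); the package closes them half-open so every
continuous value maps to exactly one category while agreeing with every
printed boundary: BMI < 25 / [25, 30) / ≥ 30; %fat for women < 26 /
[26, 36] / > 36 and for men < 21 / [21, 25] / > 25; WHR for women < 0.80
/ [0.80, 0.85) / ≥ 0.85 and for men < 0.90 / [0.90, 1.00) / ≥ 1.00.
Body-fat values below the printed "average" floor are classed average and
flagged — the study population excluded underweight adults, so such
values indicate a data-quality issue, not a band. Monotonicity and
totality of all three maps are property-tested.

## 6. Agreement statistics

The estimator fitted per stratum and measure combines exactly the
source's statistical toolkit: Spearman's rank correlation (Pearson
correlation of mid-ranks; ties get average ranks everywhere, including
ordinal category outcomes), its Fisher-z confidence interval
$\tanh(\mathrm{atanh}\,\rho \pm z_{crit}/\sqrt{n-3})$, the paired t-test
(two-sided throughout, no multiple-testing correction, as in the source),
and Bland–Altman limits of agreement: differences are questionnaire minus
accelerometer, limits are the mean difference ± 1.96 × the sample SD
(n − 1) of differences — 1.96 literally, not a quantile lookup. The
subject is the unit of analysis (3-day means per instrument). Degenerate
inputs are policy, not surprises: the scalar operations error on constant
vectors, n < 4 CIs or zero-variance differences, while the tabulated
estimator converts those to `NA` so one-subject strata still appear in
tables with their CI marked unavailable. Report tables round minutes to
integers and correlations to two decimals.

Two published-table features are explicitly out of scope and covered by
property tests instead: the empirical correlations of the observational
tables (the raw study data are unavailable), and the published stratum
CIs, which are several times narrower than the stated Fisher-z formula
permits at the stated stratum sizes — a test computes the interval at
ρ = 0.36, n = 37 and asserts the incompatibility. Likewise, a handful of
published mean-difference cells disagree with their own printed group
means by 1–8 min/day; only the internally consistent cells are used as
worked-example targets.

## 7. The synthetic cohort: what it emulates, and what it does not

`generate_cohort()` draws a study-like cohort with full ground truth. The
defaults are the study conditions: 117 subjects (120 when exercising the
completeness filter), 3 recording days from 09:00, 60 Hz, ~51/49 sex
split, age 44 ± 9 (24–60), height 177 ± 5 cm and weight 94 ± 8 kg from
truncated normals, category allocations 37/37/43 (BMI), 43/33/41 (BIA)
and 43/32/42 (WHR) scaled to the cohort size. Anthropometrics are drawn
pre-rounded to measurement precision and rejection-sampled on the scheme
under test so the emitted CSVs reproduce the targeted categories exactly;
percent body fat follows a standard height–weight–age–sex relation plus
noise, and waist follows a sex baseline shifted with BMI. Only summary
statistics are published, so per-group anthropometric targets are implied
by the category definitions rather than copied from a table.

Scheduled daily minutes of sedentary time, walking and MVPA are drawn per
subject from category-specific normal distributions calibrated to the
accelerometer columns of the published group-means table for the scheme
under test (one coupling table per scheme, applied independently — the
published differences vary by scheme). Days are scheduled in whole-minute
blocks: activity bouts interleaved with sitting and standing through the
waking period and a single sleep block (450 min target) before the next
09:00, recorded faithfully in the diary; when a heavy activity draw
overruns the day, sleep shrinks first. Whole-minute blocks align with the
5 s feature windows, which is one reason clean-cohort label accuracy is
essentially perfect — real data have ragged transitions the generator
does not emulate.

The raw-signal model per block: gravity at the type's inclination plus
white noise per axis (sleep 25 mg, sitting/standing 35 mg — quiet but
well above the 13 mg non-wear threshold, so worn rest is never mistaken
for device-off). Gait adds a cadence-locked waveform (fundamental plus
2nd and 3rd harmonics at 1 : 0.5 : 0.25, fixed by convention) on the
vertical axis. Walking uses a sustained dynamic offset at the target
intensity (55 mg default) plus a 35 mg oscillation, so the magnitude
never drops below 1 g, the mean ENMO equals the target exactly and
per-second epochs stay steady; running uses a rectified oscillation
scaled through the waveform's positive-part mean to hit its 500 mg
target. Generic moderate activity is aperiodic vertical noise scaled to
150 mg. Non-wear is exactly constant gravity. The walking default sits
below the 70 mg cut-point deliberately: cohorts whose accelerometer MVPA
minutes are fewer than their walking minutes are only possible if
ordinary walking is sub-cut-point at the hip, and the calibration tables
have exactly that structure; walking at higher intensities (the 150 mg
case) is exercised separately in tests. None of this is a gait
biomechanics model — harmonic ratios, inclinations and noise levels are
fixed conventions, and passing tests show the pipeline recovers this
generative family, not that it would classify free-living data equally
well.

Questionnaire reports are truth plus a category-specific mean shift plus
Gaussian day-level noise, floored at 0 and capped at 1440. Default shifts
are the questionnaire-minus-accelerometer group differences implied by
the published per-instrument means; default noise SDs are back-derived
from the published limits-of-agreement widths (subject-level diff SD =
width / (2 × 1.96), day-level = that × √3 since subjects are 3-day
means). The floor matters: for low-mean measures with generous noise
(walking and MVPA in some strata) clamping shifts realized group
differences upward by a few minutes — faithful to the floored model, and
the reason bias-recovery checks are designed on strata where the floor
never binds. Three resolutions trade fidelity for cost: `raw` (full 60 Hz
synthesis), `epoch` (per-second ENMO and axis-SD series drawn directly
from the per-type moments; used for wear/completeness plumbing), and
`daily` (schedule-level summaries; used for statistical calibration,
where the signal path adds nothing but runtime).

## 8. Problem sizes and numerical choices

Test and acceptance runs use: 12 subjects × 3 days at raw resolution for
classifier recovery (~3 million labelled epochs), 120 subjects at epoch
resolution for the completeness filter, 5000 subjects at daily resolution
for injected-bias recovery (±2 min/day on means, ±3 on limits, ≥3
Monte-Carlo SEs of slack at that n), 2000 replicates for Fisher-z
coverage (checked with Pearson r on bivariate-normal draws, where the
true correlation is the nominal 0.5; with Spearman's rho the target would
be (6/π)·asin(ρ/2) and the 1/√(n−3) SE slightly anticonservative), and
2000 subjects for default-calibration recovery. Seeds fix every stream:
one cohort seed derives per-subject-day substreams, so a single trace can
be regenerated byte-identically without materialising the cohort.
Tolerances follow the quantity: 1e−12 where an algebraic identity is
asserted (rank agreement, LoA width), 1e−9 for floating-point geometry
(rotation invariance), 0.1 mg for grid-level signal arithmetic, and
Monte-Carlo bands sized to ≥3 SEs elsewhere.

## 9. Known limitations

No device calibration, idle-sleep-mode imputation or resampling; no
accelerometer-based sleep detection (diaries are trusted); no
machine-learned classification; no MET-weighted or categorical IPAQ
scoring; no bout criteria for MVPA. The classifier's sitting/standing
separation rests on a posture assumption the simulator satisfies by
construction. The generator's anthropometric covariance is conventional,
not population-representative, and its reporting-bias model is linear in
truth with Gaussian noise — adequate for testing recovery machinery, not
a cognitive model of recall.
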