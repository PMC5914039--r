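# activagree

Agreement between raw-accelerometer and questionnaire measures of physical
activity and sedentary behaviour across adiposity groups.

## The problem

Free-living physical activity in overweight and obese adults is usually
assessed either by self-report (cheap, biased) or by body-worn
accelerometers (objective, but historically reduced to proprietary
"counts"). Modern devices expose the raw 60 Hz tri-axial signal, from which
a whole suite of measures can be derived with open methods: movement
intensity via **ENMO** (Euclidean Norm Minus One,
`max(sqrt(x² + y² + z²) − 1, 0)` in g, averaged over 1 s epochs and
expressed in mg), **MVPA** minutes via a cut-point (≥ 70 mg at the hip),
and **activity types** (lying/sitting, standing, walking, running) via
signature features of the raw signal — posture inclination, cadence and
periodicity. How well daily self-report (a modified IPAQ short form,
recalled each evening) agrees with these accelerometer measures — and how
that agreement shifts when subjects are grouped as normal/overweight/obese
by BMI, bioimpedance %body fat (BIA) or waist-to-hip ratio (WHR) — is a
method-comparison question this package makes fully reproducible.

`activagree` implements the complete pipeline:

- **Signal processing** — `read_raw_csv()`, `compute_enmo()`,
  `detect_nonwear()` (stationary-window rule: ≥ 60 min with per-axis SD
  < 13 mg), `assess_completeness()` (exclude > 120 missing minutes).
- **Classification** — `flag_mvpa()` (ENMO ≥ 70 mg, inclusive),
  `extract_features()`, `classify_types()` (transparent decision tree),
  diary-sleep subtraction, `summarize_day()` (09:00–09:00 analysis days).
- **Questionnaire** — `score_ipaq_daily()`: MVPA = moderate + vigorous
  minutes, sitting → sedentary, no MET weighting.
- **Adiposity** — `adiposity_profile()` with `categorize_bmi()` (< 25 /
  25–30 / ≥ 30 kg/m²), `categorize_bia()` (sex-specific bands) and
  `categorize_whr()` (sex-specific central-adiposity bands).
- **Comparison statistics** — the core estimator `agreement()`: Spearman's
  ρ with a Fisher-z confidence interval
  (`tanh(atanh(ρ) ± z_crit/√(n−3))`), the paired t-test, and Bland–Altman
  limits of agreement (mean difference ± 1.96 SD of paired differences),
  with `print()`, `summary()`, `coef()`, `confint()` and a Bland–Altman
  `plot()` method; `stratified_agreement()` tabulates it per stratum, and
  `adiposity_association_table()` correlates each instrument with the
  ordinal adiposity category.
- **Synthetic cohorts** — `generate_cohort()` produces raw signals, epoch
  series or daily summaries with known ground truth, category allocations,
  activity–adiposity coupling and calibrated adiposity-dependent reporting
  bias, so every stage is testable without field data.
- **Orchestration** — `run_pipeline()` plus a CLI wrapper in
  `inst/scripts/run_pipeline.R`.

## Worked example

Simulate a study-like cohort (117 subjects, 3 days, daily resolution) and
compare the instruments under the BMI grouping:

```r
library(activagree)

cohort <- generate_cohort(sim_config(n_subjects = 117, seed = 1))
summaries <- rbind(cohort$daily_acc, score_ipaq_daily(cohort$questionnaires))
tab <- stratified_agreement(summaries, cohort$profiles, scheme = "bmi")
print(tab[tab$measure == "sedentary", ])
#>  scheme    stratum   measure   n  rho ci_low ci_high mean_diff sd_diff loa_low loa_high t_stat  p_value
#>     bmi        all sedentary 117 0.76   0.67    0.83      -158    90.3    -335       19 -18.93 2.80e-37
#>     bmi     normal sedentary  37 0.69   0.47    0.83      -131    78.7    -285       24 -10.09 4.94e-12
#>     bmi overweight sedentary  37 0.45   0.15    0.68      -160    99.6    -355       35  -9.77 1.14e-11
#>     bmi      obese sedentary  43 0.53   0.28    0.72      -180    86.8    -350      -10 -13.60 5.59e-17
```

Obese subjects under-report sedentary time by about 180 min/day relative
to the accelerometer in this draw (the generator's calibrated bias for
that stratum is −195), with Bland–Altman limits of agreement spanning
roughly −350 to −10 min/day; the `rho` column gives the Spearman
correlation between the instruments in each stratum with its Fisher-z 95%
CI. A single comparison can also be examined as a fitted object:

```r
q <- with(subset(summaries, instrument == "questionnaire"),
          tapply(sedentary_min, subject_id, mean))
a <- with(subset(summaries, instrument == "accelerometer"),
          tapply(sedentary_min, subject_id, mean))
fit <- agreement(q, a, measure = "sedentary")
print(fit)
#> Method agreement: sedentary (n = 117)
#>   Spearman rho 0.76 (95% CI 0.67, 0.83)
#>   Mean difference -158.04 min/day (LoA -335.01 to 18.93)
#>   Paired t = -18.93, df = 116, p = 2.8e-37
plot(fit)     # Bland-Altman plot with mean difference and limits
```

The raw-signal path works the same way from CSV traces
(`read_raw_csv()` → `compute_enmo()` → `extract_features()` →
`classify_types()` → `summarize_day()`), or end to end via
`run_pipeline()`.

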