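---
title: "Measuring office activity and space use: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring office activity and space use: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(officeactivity)
```

## The measurement model

The package analyses a two-arm workplace natural experiment: one office is
renovated into an activity-based-working layout with height-adjustable
desks, control offices are left unchanged, and every participant is measured
in a pre phase and a post phase. Two instruments are modelled.

**Worn accelerometer.** The device reports one MET (metabolic equivalent)
value per 60-second epoch while worn during waking hours. Epochs are
classified by standard cut-points: sedentary behavior (SB) at MET ≤ 1.5,
light-intensity physical activity (LPA) above 1.5 and below 3.0, and
moderate-to-vigorous activity (MVPA) at MET ≥ 3.0. A MET of exactly 0 is the
no-signal sentinel: the device detected nothing. Long no-signal runs mean
the device was off; short ones occur during motionless sitting, which is why
non-wear is a *run-length* decision, not a per-epoch one.

**Fixed cameras.** Person detections over the office floor plan, reduced to
floor-meter coordinates, are attributed to labelled zones (aisles and
workstation areas) and counted per 15-minute slot of a 10:00–17:00 recording
day. The count of detections per zone per slot — the "detectable number of
persons per 15 min" — is the unit of the space-utilization analysis.

## Accelerometry processing rules

| rule | value | notes |
|---|---|---|
| epoch length | 60 s | fixed; the generator and readers enforce it |
| non-wear | ≥ 20 consecutive no-signal min | runs never span midnight; days are the analysis unit |
| valid day | ≥ 600 min (10 h) all-day wear | weekends are excluded entirely |
| valid participant | ≥ 4 valid weekdays per working week | `week_rule = "overall"` applies the count to the phase instead |
| prolonged SB | ≥ 30 consecutive SB min | any non-SB epoch breaks a bout; no interruption tolerance |
| working window | 8:40–17:20, half-open | 520 min = 8.67 h |
| normalization | observed / wearing × 520 | per day, then averaged across valid days |

Several of these rules required decisions the conventions leave open:

- **Cut-point boundaries.** The LPA band is quoted in the field as
  "1.6–3.0 METs" next to "MVPA ≥ 3.0". We resolve the overlap in favour of
  the explicit inequality: exactly 3.0 is MVPA, and the LPA interval is the
  open-ended (1.5, 3.0). Device output is continuous, so values in
  (1.5, 1.6) occur and must classify somewhere; they are LPA.
- **Wear-time zeros.** A no-signal epoch inside a short (< 20 min) zero run
  stays wear time. Such epochs count as SB in day summaries — they are
  below the sedentary threshold by definition — which preserves the exact
  partition SB + LPA + MVPA = wear minutes that the downstream identity
  checks rely on.
- **Window membership** is decided by the epoch's start timestamp, with
  half-open intervals everywhere (`[start, end)`), so windows and slots
  partition time without double counting.
- **Per-day normalization, then averaging.** Normalizing each day and
  averaging across days weights days equally; pooling epochs first would
  weight days by wear time. Daily normalization also makes the
  SB + total PA = 520 identity hold participant-by-participant, not just in
  aggregate.
- **Degenerate inputs.** A day with zero working-hours wear cannot be
  normalized; such days are already invalid (< 10 h all-day wear) and only
  reachable through hand-built input, where `normalize_to_working_hours()`
  raises an error rather than returning an infinity.

## The synthetic cohort

Raw epoch-level accelerometer data from workplace studies are essentially
never deposited, so the generator is a first-class, tested component, not a
fixture. Its defaults are the study conditions the analysis targets:

- 29 control and 13 renovation participants, 10 measurement weekdays (two
  working weeks) per phase;
- waking wear window 07:00–22:00 (900 min), giving all-day wear around
  875 min after one expected 25-min device-off gap per day (Poisson count of
  gaps, fixed length, uniform placement) — the magnitude reported for
  cohorts of this kind;
- a working-hours composition of SB 346.8 / LPA 130.4 / MVPA 42.8
  min/working-hours. These sum to exactly 520, so the composition *is* the
  normalized target and the pipeline's normalization recovers the configured
  means regardless of where wear gaps fall;
- a renovation effect of 25 min/working-hours moved from SB to LPA in the
  renovation arm's post phase only (`effect_sb_change`), matching the
  per-workday magnitude this kind of renovation is reported to achieve;
- between-participant SD 26 min as a random intercept on SB (traded against
  LPA so the composition stays closed), *shared across phases* — the design
  is repeated measures, and without a stable intercept the pre/post change
  would be far noisier than real cohorts show; and day-to-day SD 25 min.

Within a day, per-epoch intensity states are drawn from a three-state Markov
chain that redraws from the target composition with probability
`1 - bout_persistence` (default 0.85) and otherwise keeps its state. The
stationary distribution equals the target composition, so expected category
minutes match the configured means exactly, while the geometric run lengths
give sedentary bouts long enough for prolonged-SB detection to be a
meaningful test — i.i.d. draws would make 30-min bouts vanishingly rare.
The chain adds sampling variance of its own (about ±27 min/day on SB at the
default persistence); combined with the configured day-to-day SD, the
between-participant SD of phase means lands near 28 min, matching the
dispersion such cohorts report.

What the generator does *not* emulate: device-specific MET estimation error,
posture misclassification (sitting vs standing still), diurnal structure
(lunch breaks, commutes), weekend behavior, participant dropout, or
correlation between activity and office attendance. Tests passing on this
cohort demonstrate that the *processing* is correct under the stated
statistical structure, not that the instrument itself is unbiased.

MET values are drawn uniformly within each category band (SB 1.0–1.5,
LPA 1.6–2.9, MVPA 3.0–6.0); only the category matters downstream.

## Space utilization

Zones are simple closed polygons in floor meters with a category, an area
and an integer priority. Assignment includes boundaries; overlapping zones
resolve by priority (workstations above aisles, since desk areas sit inside
aisle-adjacent regions on real plans), then lexicographically by label so
results cannot depend on row order. Detection counts are per record: the
person-count semantics of a frame-sampled detector are under-specified, so
the package defines utilization operationally as detection records per
slot. The detector's frame-sampling rate is deliberately not modelled — the
per-slot Poisson intensity is a free parameter, and comparisons across
configurations are only meaningful at a fixed intensity scale.

Missing data (a camera lost for a day, a recording that starts late) are
handled by excluding absent cells and reporting per-space cell counts —
never by imputation. Dispersion of per-space means is computed over
day × slot cells by default; across-day and across-slot alternatives are
available because published tables rarely state which was used.

## The split-plot ANOVA

Both analyses share one design: a between-subjects factor (group, or space)
and a within-subjects factor (phase, or 28 time slots). The classical
decomposition splits the total sum of squares into a between-subjects
stratum — between effect tested against subject-within-group error — and a
within-subjects stratum — within effect and interaction tested against the
subject × within residual. The implementation computes the stratum sums
directly from cell means; for designs that are complete within subjects
(unequal group sizes allowed — they remain proportional and hence
orthogonal) this is exact, and the test suite verifies it against `aov()`
error strata and against hand-computed sums on a worked design.

Choices worth stating:

- **Subjects missing a within level are dropped listwise** with a warning;
  the classical decomposition requires completeness.
- **No sphericity correction** is applied. With two within levels sphericity
  is trivially satisfied; with the 28-slot video design it is not, and the
  result carries a `sphericity_note` flag instead of a silent correction.
- **The video "subject"** is the day-within-space unit: each recording day
  of a zone contributes one 28-slot series. This is an assumption — day
  could also be crossed with space — and is recorded in output metadata by
  construction of the unit identifier.
- **Area covariate.** Zone area is constant within zone, so with the zone as
  the between factor the covariate is partially aliased: it is estimable
  only with ≥ 3 zones (one between df is spent on the slope). The pipeline
  fits the area-adjusted model where estimable and falls back to the
  unadjusted model with an explanatory note otherwise — mirroring how a
  two-zone pre-renovation aisle analysis cannot support an area covariate.
  The adjustment itself is sequential ANCOVA on subject means (covariate
  first), which removes the covariate sum of squares from the
  between-subjects error before the between effect is tested; the within
  stratum is untouched because a subject-constant covariate carries no
  within-subject information.
- **Post hoc family.** Contrasts are gated on a significant interaction
  (α = 0.05) and default to the paired pre-vs-post contrast within each
  group — the family published tables report — with Bonferroni adjustment
  `min(1, p × m)`. Between-group contrasts at each phase are available via
  `family = "both"`, enlarging `m` accordingly.
- **Baseline tests** use the equal-variance t (the convention when nothing
  further is stated) and Pearson chi-square without continuity correction,
  which reproduces published baseline p-values for count margins of this
  size.

## Interfaces

The package is driven from R: `run_pipeline()` orchestrates
simulate → accel → video → anova → report with a single seeded
configuration, step-level logging of dropped records and excluded
participants, and an MD5 manifest for reproducibility checks, and
`scripts/acceptance.R` provides a command-line entry for regenerating the
headline estimate. A fuller shell CLI was considered and rejected: the
audience for this kind of analysis works in R, and every pipeline stage is
an exported, documented function.

## Problem sizes in the test suite

The suite checks run-detection against a brute-force enumeration oracle on
1000 random series, zone assignment against an even–odd ray-casting oracle
on 10,000 random points, the interaction's type-I error on 5000 simulated
null designs (12 subjects each), and p-uniformity of the between effect on
2000 null replicates; parameter-recovery checks use the default cohort
(42 participants × 2 phases × 10 days of 900 epochs). These sizes were
chosen so Monte-Carlo error is small relative to the tolerances tested
(3 standard errors throughout) while the whole suite stays interactive.

## Known limitations

- Non-wear detection uses the no-signal sentinel only; devices that emit
  low non-zero noise while unworn would need mapping at read time.
- The prolonged-SB definition tolerates no interruptions; conventions that
  allow 1–2 min breaks would need a windowed variant.
- The split-plot ANOVA is the classical least-squares decomposition;
  unbalanced *within*-subject data call for a mixed-effects (REML) model,
  which is out of scope here.
- The 28-slot video ANOVA ignores serial correlation between adjacent slots
  beyond what the subject stratum absorbs; its p-values should be read as
  descriptive.
- No multiplicity correction is applied across the metric family (SB,
  prolonged SB, total PA, LPA, MVPA × two windows); each metric is tested
  at α = 0.05 as published analyses of this design do.
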