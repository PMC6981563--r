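# officeactivity

Tools for analysing how an office renovation changes what workers do with
their bodies and their floor space. The package targets the natural-experiment
design used in workplace-health research: a renovated office (activity-based
working layout with height-adjustable desks) compared against unrenovated
control offices, with behavior measured by worn accelerometers before and
after the renovation, and space usage measured by fixed-camera person
detections over the floor plan.

It covers three stages:

1. **Accelerometry** — 60-s MET epoch series are filtered for non-wear time
   (runs of ≥ 20 min below the detectable intensity), classified into
   sedentary behavior (SB, ≤ 1.5 METs), light-intensity activity (LPA,
   1.6–3.0 METs) and moderate-to-vigorous activity (MVPA, ≥ 3.0 METs),
   scanned for prolonged sedentary bouts (≥ 30 consecutive minutes), windowed
   to the standard workday (8:40–17:20) and summarized per day and per phase.
   Days with < 10 h wear are invalid; participants need ≥ 4 valid weekdays
   per working week. Working-hours durations are normalized to
   min/working-hours:

   `min/working-hours = observed duration / wearing time × 520 min (8.67 h)`

   so SB + total PA ≡ 520 for every participant-day.
2. **Space utilization** — person detections (floor-meter coordinates) are
   assigned to labelled floor-plan zones (GeoJSON polygons with category and
   priority) and tallied into half-open 15-min slots over the 10:00–17:00
   recording window (28 slots/day), then summarized as the detectable number
   of persons per 15 min per space.
3. **Statistics** — a hand-implemented classical split-plot
   (mixed repeated-measures) ANOVA: between-subjects factor (group or space)
   tested against subject-within-group error, within-subjects factor (phase
   or time slot) and interaction tested against the subject × within
   residual; a covariate-adjusted variant for the space analysis (zone area);
   Bonferroni-adjusted paired pre/post contrasts gated on a significant
   interaction; and baseline group comparisons (equal-variance t,
   uncorrected Pearson chi-square).

Because raw epoch and video data of such studies are rarely shareable, the
package ships seeded generators (`simulate_cohort()`, `simulate_entry_exit()`,
`office_plan()`, `simulate_detections()`) that reproduce the statistical
structure the analysis assumes — Markov-chain bout structure within days,
stable participant intercepts across phases, a configurable SB-to-LPA
renovation effect, and Poisson zone occupancy — so the entire pipeline runs
and is tested end-to-end without any external data.

## Worked example

```r
library(officeactivity)

cfg    <- accel_sim_config(seed = 42)          # 29 control / 13 renovation
cohort <- simulate_cohort(cfg)                 # 60-s MET epochs, two phases
days   <- summarize_day(cohort)                # wear/SB/LPA/MVPA per day
phases <- summarize_phase(days, simulate_entry_exit(cfg, mean_hours = 7))

phases$phase <- factor(phases$phase, levels = c("pre", "post"))
fit <- mixed_anova(phases, "sb_norm", "participant_id", "group", "phase")
fit
#> split-plot ANOVA: 42 subjects
#>         effect    ss df   ms      f        p
#>        between  5915  1 5915  3.230 0.079869
#>  subject_error 73261 40 1832     NA       NA
#>         within  1022  1 1022  6.814 0.012667
#>    interaction  1777  1 1777 11.850 0.001365
#>   within_error  5999 40  150     NA       NA

bonferroni_posthoc(fit)
#>      contrast      level estimate     t df   p_raw   p_adj m
#> 1 pre vs post    control    0.817 0.281 28 0.78060 1.00000 2
#> 2 pre vs post renovation   20.716 3.605 12 0.00361 0.00722 2
```

The group × phase interaction on normalized working-hours sedentary time is
significant (p = 0.0014): sedentary time fell in the renovation arm. The
gated Bonferroni contrasts localize the change — a 20.7 min/working-hours
reduction in the renovation group (adjusted p = 0.007) and no change in the
controls. The generating model planted a 25-min SB-to-LPA shift in the
renovation arm's post phase; the recovered 20.7 min is within Monte-Carlo
error of that target.

`run_pipeline()` drives all stages (simulate → accel → video → anova →
report) from one `pipeline_config()`, writing CSV/JSON/PNG artifacts and a
manifest of MD5 hashes that is identical across runs with the same seed.

## Vignette

`vignettes/office-activity-methods.Rmd` describes the measurement model, the
synthetic-data generator and its calibration, the split-plot decomposition,
the numerical conventions (boundary cut-points, half-open windows, tie
breaks) and known limitations.
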