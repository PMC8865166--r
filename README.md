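# drivecr

Event-locked cardiac and speed responses to driving hazards.

`drivecr` is an R package for psychophysiologists and human-factors
researchers who study how drivers anticipate and react to hazardous
traffic events. It implements the full analysis chain from raw
electrocardiogram (ECG) and vehicle-speed recordings with cue/event
markers to the inferential statistics of a within-subject
hazard-predictability design, together with a seedable synthetic
driving-session simulator so that the whole chain can be validated
against known ground truth when raw participant data are unavailable.

## The analysis

A session consists of two 10-minute drives on the same simulated route:
Trip 1 (control) and Trip 2 (experimental), with three hazard
conditions — **U** (unpredictable: the warning cue is invisible), **P**
(predictable: a cue precedes the hazard) and **PF** (predictable and
familiar: cue and hazard were already encountered in Trip 1).

The cardiac chain follows the standard event-related cardiac response
(ECR) workflow:

1. band-pass filter the ECG between 2 and 40 Hz (zero-phase, 4th-order
   Butterworth);
2. detect R peaks automatically (Pan–Tompkins-style derivative →
   squaring → 150 ms integration → adaptive threshold, 250 ms
   refractory period) and repair misplaced or missing triggers;
3. convert R–R intervals to instantaneous heart rate,
   `RRI_n = r_n − r_{n−1}`, `HR_n = 60 / RRI_n` (RRI in seconds, HR in
   bpm), with the rate assigned to the interval's closing beat;
4. resample the beat-wise rate every 0.5 s with a natural cubic spline,
   from −0.5 s up to 4.5 s (U, P) or 7.5 s (PF) around each cue and
   event onset;
5. express each epoch as heart-rate change,
   `HRC(t) = HR(t) − HR(t₀)`, where `t₀ = −0.5 s` is the pre-onset
   baseline sample.

Speed traces (10 Hz) go through the same epoching with linear
interpolation. Statistics mirror the design:

* **2 × k repeated-measures ANOVA** per condition × window × channel
  (condition-type × time-point, both within subject), with Mauchly's
  sphericity test, Greenhouse–Geisser-corrected degrees of freedom and
  partial eta squared;
* **Bonferroni-corrected paired post hocs** at each time point;
* **orthogonal polynomial contrasts** (linear/quadratic/cubic) on the
  postcue heart-rate window of the cued conditions — a quadratic trend
  is the signature of the biphasic anticipatory response: a freezing
  deceleration (ECR1) followed by a fight-or-flight acceleration
  (ECR2);
* **paired AUC comparisons** (signed trapezoidal area of the change
  curve) between experimental and control drives within high- and
  low-perceived-stress groups, formed by the 2.5 median split of 1–5
  Likert stress ratings, with Cohen's *d* for paired data.

## Worked example

Simulate a cohort the size of the study design (34 enrolled, 5
motion-sickness and 2 bad-ECG exclusions), run the pipeline and inspect
the results (short 90 s trips keep the example fast; `render_ecg =
FALSE` epochs from the simulator's ground-truth beats instead of
running the detector):

```r
library(drivecr)

cfg <- pipeline_config(
  seed = 42, out_dir = "demo_out",
  n_participants = 34,
  exclusions = list(motion_sickness = 5, bad_ecg = 2),
  session = session_config(trip_duration_s = 90,
                           cue_onsets_s = c(U = 18, P = 42, PF = 66)),
  render_ecg = FALSE, verbose = FALSE
)
report <- run_pipeline(cfg)
report
#> <run_report> drivecr 0.1.0, seed 42
#>   participants: 34 enrolled, 7 excluded, 27 analysed
#>   epochs: 8424 rows; outputs in demo_out

fit <- report$results$anova
fit[fit$condition == "P" & fit$window == "postcue" & fit$channel == "hr",
    c("effect", "statistic", "gg_epsilon", "p_reported", "partial_eta_sq")]
#>        effect statistic gg_epsilon p_reported partial_eta_sq
#> 1        type     0.473       1.00   4.98e-01         0.0179
#> 2        time    16.522       0.42   4.69e-10         0.3886
#> 3 interaction    21.796       0.50   1.86e-14         0.4560

report_tables(report$results)$trends
#>   condition condition_type     trend      t df  p_value
#> 1         P   experimental    linear   9.00 26 1.82e-09
#> 2         P   experimental quadratic  -2.50 26 1.91e-02
#> 3         P   experimental     cubic  -9.87 26 2.77e-10
#> 4        PF   experimental    linear   7.39 26 7.50e-08
#> ...
```

The 27 analysed participants reconcile with 34 enrolled minus 7
excluded. The significant condition-type × time interaction says the
experimental drive's heart-rate time course differs from the matched
control passage, with Greenhouse–Geisser correction applied because the
spline-resampled change scores are strongly non-spherical (ε ≈ 0.4–0.5).
The significant quadratic trend for the cued conditions is the biphasic
deceleration-then-acceleration anticipation pattern injected by the
simulator. `epochs.tsv`, `auc.tsv`, `anova_results.tsv`,
`contrasts.tsv`, `posthoc.tsv` and `paired_auc.tsv` are written under
`out_dir`.

A thin command-line wrapper ships in `inst/scripts/run_pipeline.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/run_pipeline.R", package="drivecr"))')" \
  --seed 7 --participants 12 --out run7 --no-plots
```

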