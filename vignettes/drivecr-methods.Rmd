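---
title: "Methods: event-locked cardiac and speed analysis in drivecr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: event-locked cardiac and speed analysis in drivecr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`drivecr` analyses stimulus-locked cardiac and speed responses in a
two-drive, three-condition hazard-predictability design. This vignette
documents the model, the tunable parameters, the synthetic-data
generator, the numerical choices, and the limits of what the test suite
can and cannot establish about real recordings.

## The measurement model

Heart rate is only observable at heartbeats. From detected R-peak times
$r_n$ the package forms R–R intervals $RRI_n = r_n - r_{n-1}$ (seconds)
and instantaneous heart rate $HR_n = 60 / RRI_n$ (beats per minute).
The printed unit convention for these equations is sometimes stated in
milliseconds; `drivecr` uses $60 / RRI_{\mathrm{seconds}}$ throughout,
the only reading that yields bpm. Each rate value is attached to the
*closing* beat of its interval — the moment at which the interval
becomes known; whether the knot belongs at the closing beat or the
interval midpoint is not fixed by convention, and closing-beat is this
package's documented choice.

A natural cubic spline through the (beat time, bpm) knots is evaluated
every 0.5 s. Epochs run from $-0.5$ s to $4.5$ s around cue and event
onsets for the U and P conditions and to $7.5$ s for PF; the window
ends follow from the 10 and 16 post-baseline time levels of the
design's time factor. The sample at $-0.5$ s is the baseline
$HR(t_0)$, and heart-rate change is $HRC(t) = HR(t) - HR(t_0)$, so
every epoch is exactly zero at $-0.5$ s. The "last half-second before
onset" baseline is read as the single interpolated sample at $-0.5$ s,
not a mean over $[-0.5, 0)$ — consistent with defining $HR(t_0)$ as
the heart rate at the window's beginning. Speed (10 Hz) uses the same
epoching with linear interpolation; at a 0.5 s output grid the 10 Hz
trace is dense enough that spline refinement would change nothing
material.

## Inference

Each condition × window × channel is tested with a 2 (condition type) ×
k (time) within-subject ANOVA, every effect against its own
subject-interaction error term. Sphericity is assessed with Mauchly's
W (Box's chi-square approximation with the second-order correction
term), and Greenhouse–Geisser $\varepsilon$ — computed from the
covariance of the per-effect within-subject scores, bounded in
$[1/(k-1), 1]$ — multiplies both degrees of freedom. Corrected and
uncorrected p values are always stored; the reported p applies the
correction when Mauchly's p < .05, matching the convention of
correcting "when there is a sphericity violation". Note that
baseline-referenced, spline-resampled change scores are *always*
strongly non-spherical in practice (neighbouring grid points share
spline knots and every point shares the baseline term), so the
corrected path is the one that effectively runs.

Polynomial contrasts use orthonormal weights built by Gram–Schmidt on
$\{1, t, t^2, t^3\}$ over the k equally spaced post-baseline points.
The baseline point is excluded: it is identically zero by construction
and would distort orthogonality. The sign convention makes a positive
quadratic score a U-shape; the biphasic
deceleration-then-acceleration signature loads on the quadratic
(typically with additional linear and cubic components when the
acceleration lobe sits mid-window rather than at the window end). The
contrasts are computed for the cued conditions in the postcue
heart-rate window only — P experimental, and PF experimental *and*
control, because PF's cue is present in the control drive too.

Paired AUC comparisons use the signed trapezoidal integral of the
change curve from 0 to the window end (the forced-zero baseline point
is excluded so it cannot dilute the summary). Cohen's d uses the
paired-data denominator, $d = \bar{\Delta} / s_\Delta$, giving the
identity $t = d\sqrt{n}$; the pooled-SD alternative is a plausible
reading of published tables but the paired form is this package's
documented assumption. Bonferroni post hocs multiply each time point's
paired-t p value by the number of points in its window — the family
that matches per-figure annotation of significant time points; no
correction is applied across conditions or windows. A degenerate
paired test (zero-variance, non-zero mean differences) reports
$d = \pm\infty$ and $p = 0$ as explicit sentinels rather than NaN.

## The synthetic-session generator

The generator exists so that every stage has a ground truth. Its
defaults are the study conditions: 500 Hz ECG, 10 Hz speed, 10-minute
trips, cue durations of 4.41 s (P) and 7.24 s (PF) with the U cue
invisible, event durations of 1.83 / 3.01 / 3.73 s (U / P / PF), and a
1–5 Likert stress rating for U and P only. Where the design implies but
does not print a value, the package chooses once:

* **Cue→event gaps** are free parameters (`cue_event_gap_s`). Defaults
  are 4.5 s (U, P) and 7.5 s (PF) so that each postcue analysis window
  ends at event onset and does not overlap the event-locked response.
* **Baseline heart rate** 75 bpm with between-participant SD 7 bpm;
  beat-to-beat rate noise SD 2.5 bpm and a 0.25 Hz respiratory
  sinus-arrhythmia sinusoid of 2 bpm with per-participant random phase
  (a common phase would bias grand-mean curves).
* **Templates**: the evoked response is a pair of compact raised-cosine
  lobes (deceleration then acceleration), continuous, zero for
  $t \le 0$ and vanishing past the acceleration lobe. The P postcue
  default is $-5$ bpm at 1 s and $+6$ bpm at 3 s with `lobe_width`
  0.5 s. PF's first exposure in Trip 1 carries the same template at
  60 % amplitude, since a familiar-event control drive already contains
  the cue and hazard.
* **Ratings**: high-stress participants draw uniformly from {3, 4, 5},
  low-stress from {1, 2}, straddling the 2.5 split.
* **Speed**: 70 km/h cruising with a 12 km/h event-locked deceleration
  (0.5 s lag, 2 s ramp).

Beat trains are generated by inverting the instantaneous rate: the next
interval solves $RRI = 60 / \mathrm{rate}(t + RRI)$ by fixed-point
iteration and is clamped to [0.3, 2.0] s. Evaluating the rate at the
interval's *closing* beat makes the scheme exact in the constant-rate
limit and keeps $HR_n$ equal to the model rate at the knot time, so
the noise-free round trip through the analysis reproduces
baseline + template at beat times to well under 0.5 bpm. ECG waveforms
render each beat as a fixed P-QRS-T sum of Gaussian bumps (R apex
snapped to the sample grid, R ≥ 3× any other wave) plus broadband
noise. Participants flagged `bad_ecg` have their waveform corrupted
with electrode-dropout windows and motion spikes so that the automated
beat correction itself condemns the record; `motion_sickness`
participants represent non-completers. One global seed fans out to
per-participant substreams keyed by participant index, so a
participant's session is invariant to cohort size and ordering.

## What the simulator does and does not emulate

It emulates the features the pipeline is sensitive to: beat-level rate
dynamics, event-locked biphasic modulation, detector-exercising ECG
morphology and noise, dropout-style artifacts, matched-route control
passages, exclusion bookkeeping and stress subpopulations. It does not
emulate realistic 12-lead morphology, arrhythmias, respiration beyond a
single sinusoid, non-stationary HRV, or driving dynamics beyond a
parametric speed dip. Green tests therefore certify the *pipeline* —
signal chain, epoching, statistics — under controlled conditions; they
do not certify detector performance on pathological clinical ECG.

## Numerical choices and known limits

* **Filter**: the band is a design constant (2–40 Hz); order-4
  Butterworth applied forward–backward (zero phase) preserves R-peak
  timing. The 250 ms detector refractory caps detectable rate at
  240 bpm, far above driving heart rates.
* **Beat correction**: intervals > 1.8× (or < 0.4×) a 9-interval
  running median are treated as missed beats (filled by evenly spaced
  insertion) or false triggers (weaker apex removed); each inserted or
  removed beat is one edit, and a record whose edits exceed 20 % of its
  intervals is condemned as `bad_ecg`. The thresholds are deliberately
  conservative and exposed as arguments; they automate what is
  classically a visual check.
* **No extrapolation**: the spline refuses grids outside its knots;
  epochs that are not fully covered are marked missing and the
  participant is dropped from both members of the affected
  experimental/control pair (complete-case at the matrix level, no
  imputation).
* **Discretization limit of template recovery**: with beats ~0.8 s
  apart, a natural cubic spline cannot fully resolve template lobes
  whose curvature lives at the ~1 s scale. Noise-free simulation shows
  a systematic undershoot of about 0.9 bpm at the +6 bpm acceleration
  peak and ~0.5 bpm near lobe edges. Grand-mean recovery is therefore
  validated against the *expected beat-sampled, spline-discretized*
  curve (plus a correlation > 0.95 with the raw template); recovery of
  the raw template at every grid point to within 3× the Monte-Carlo
  standard error of a 200-participant cohort is not attainable at the
  acceleration peak, and the corresponding acceptance check documents
  this rather than hiding it.
* **Type-I calibration**: on null cohorts (n = 27, 2 × 10) the
  GG-corrected interaction test is, as expected for a strongly
  non-spherical covariance (ε ≈ 0.5), close to but slightly below the
  nominal 5 % level; the calibration study in the test suite runs 1000
  cohorts.
* **GG gating**: Huynh–Feldt is deliberately not implemented; only the
  Greenhouse–Geisser correction is named by the analysis convention
  this package follows.

## Problem sizes used by the tests and acceptance script

Simulated sessions in tests use 90 s trips (the epoching is locked to
markers, so trip length beyond the last epoch is immaterial); detector
fidelity uses three 2-minute 500 Hz records at 10 % noise; the type-I
study uses 1000 null cohorts of 27 participants; template recovery
uses one 200-participant cohort; quadratic-contrast power uses 50
cohorts of 27. The full test suite runs in a few minutes on one CPU.

## Limitations

Respiration is simulated but never removed — respiratory influences on
the 0.5 s heart-rate grid are treated as noise, as in the analysis
convention this package implements. The automated beat correction is a
stand-in for expert visual inspection and is only as good as its local
median heuristics. The paired/pooled ambiguity of published Cohen's d
values, and the spline-knot placement, are resolved by documented
choices rather than by evidence.
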