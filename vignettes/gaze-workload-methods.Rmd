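---
title: "Methods: gaze characterization and workload metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gaze characterization and workload metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazechar)
```

## What this package models

Eye-gaze trackers are used as control interfaces for assistive devices:
gaze position on a screen drives a cursor, activates dwell buttons, or
steers a wheelchair. Designing such interfaces requires knowing, per
user, (i) which regions of the screen they can reach comfortably, (ii)
how small a dwell-activated button can be, (iii) how their smooth
pursuit differs between deliberate control and passive watching, and
(iv) how mentally taxing the interaction is. `gazechar` implements an
offline, fully testable version of this characterization stack: three
screen-based tasks (free-viewing *painting*, dwell-target *focus*,
moving-target *tracking*), a velocity-threshold eye-movement event
detector, task metrics, and physiological workload metrics (change in
pupil diameter, heart rate, ultra-short-term RMSSD) with agreement
statistics (ICC, Bland–Altman, banded DTW).

Because no recordings ship with the package, a synthetic-data module
generates labeled sessions. The generators are first-class, tested
code: every downstream stage is validated against the ground truth they
emit.

## Geometry

All angular quantities are degrees of visual angle (DVA). The default
`screen_geometry()` is the study setup: a 1600 × 900 px display with a
55.9 cm diagonal viewed from 60 cm. A pixel *extent* converts through
the exact chord formula `2·atan(px·pitch / (2·d))`; *rates* and *path
lengths*, which are limits of infinitesimal steps, convert through the
angular resolution at the screen centre (`px_to_dva(1) ≈ 0.0291`
DVA/px). The package always derives this constant from the geometry
rather than hard-coding it. Screen coordinates are 0-based, x
rightward, y downward, origin top-left. The scene-camera to screen
transform is a four-point DLT homography, exact on its defining
corners.

## The synthetic session generator

`simulate_gaze()` produces stimulus-locked gaze with per-sample labels:

* **Fixational jitter** is a mean-reverting AR(1) process (default
  stationary SD 0.3 DVA, lag-1 coefficient 0.97 at 100 Hz, a ~0.3 s
  drift time constant). Real tracker noise and ocular drift are
  temporally correlated; white noise at 100 Hz would imply physically
  impossible sub-sample velocities.
* **Saccades** are constant-velocity jumps at 300 DVA/s after a 150 ms
  latency — enough structure to exercise a velocity-threshold detector,
  deliberately not a main-sequence profile.
* **Pursuit** follows the target displacement at `pursuit_gain`
  (default 1) times the target velocity.
* **Dropouts** are per-sample Bernoulli losses (default 2%). Ground
  truth keeps the latent oculomotor state for losses up to 75 ms (the
  blink-gap scale) and labels longer losses `gap`; a 10 ms tracker
  dropout does not change what the eye was doing.

The focus simulation runs the dwell/timeout logic *online* — the next
target appears the moment the previous one is selected (2 s continuous
dwell) or times out (10 s) — so target success genuinely depends on
jitter relative to target size, reproducing the qualitative
size–success relationship. The schedule generator balances 60 targets
over the size set {2, …, 7} DVA (the set itself is configuration; it
spans the transition from hard to easy dwell). Tracking trajectories
are random piecewise-linear paths (segments ≥ 5 DVA) traversed at a
constant 15 DVA/s; 24 targets by default. Painting interleaves
fixations (0.3–1 s), saccades, and slow steering pursuits (6–12 DVA/s)
over the whole screen for 5 minutes.

`simulate_pupil()` adds `gain·w(t)` (default 0.5 mm per unit workload)
to a baseline diameter plus slow AR(1) wander, with blink gaps
(> 75 ms holes in the time base) and injected size/dilation-speed
outliers, all recorded for oracle use. `simulate_rr()` draws
`RR = baseline − slope·w(t) + ε` with the jitter SD set so the
generating RMSSD equals `rmssd_baseline − rmssd_slope·w` (for iid
jitter, RMSSD = σ√2); defaults (800 ms baseline, −100 ms slope, RMSSD
40 → 15 ms) model a moderate workload response in a resting adult.
Ectopic beats are a 45% shortening plus compensatory lengthening.

What the generators do **not** model: main-sequence saccade dynamics,
post-saccadic oscillations, blinks in the gaze channel, head movement,
calibration drift, and clinical-population effects. Passing tests
therefore demonstrate internal consistency of the pipeline under
plausible signal structure, not performance on any particular patient
recording.

## Event detection

`detect_events()` implements the adaptive velocity-threshold family:

1. Positions are converted to angular coordinates and differentiated
   with a Savitzky–Golay filter (`sg_window = 7` samples, order 2).
   Invalid gaps ≤ 75 ms are linearly interpolated first; longer gaps
   become `gap` events.
2. The saccade threshold iterates `PT ← mean(v ≤ PT) + 6·sd(v ≤ PT)`
   from 300 DVA/s until the update changes by < 1 DVA/s (inclusive
   comparison; a zero-variance input converges to its mean). In
   `detect_events()` the threshold is floored at the pursuit threshold:
   on noise-free data the iteration collapses toward zero, and a
   "saccade" slower than a pursuit is a contradiction.
3. Saccade candidates (`v ≥ PT`, duration ≥ 10 ms) are trimmed to the
   half-peak crossing of their velocity profile. The SG derivative
   kernel is symmetric, so it smears a velocity step symmetrically and
   the half-amplitude crossing localizes the true saccade edge; without
   this refinement each saccade is padded by roughly half a filter
   window on each side.
4. Each intersaccadic segment is detrended, mirror-padded and low-pass
   filtered in *position* (Butterworth, 4 Hz, zero-phase), and the
   filtered speed is recomputed. Runs with speed ≥ `pursuit_vel_dva_s`
   lasting ≥ 40 ms become pursuits, grown outward by hysteresis down to
   half the threshold to recover the filter's onset/offset ramps;
   remaining runs ≥ 40 ms become fixations. The detrend/pad step
   matters: zero-phase filtering with zero initial conditions rings at
   segment edges on non-zero-mean input.
5. Sub-minimum fragments merge into the neighbouring event with the
   closer median velocity; exact ties keep the preceding neighbour, for
   determinism. Events always partition the timeline.

**Pursuit threshold.** The default is 6 DVA/s. At 100 Hz with 0.3 DVA
correlated jitter, the low-pass-filtered drift speed has a 99th
percentile near 5 DVA/s, so the 1–2 DVA/s thresholds used with
high-rate laboratory data would misclassify fixations wholesale. The
tasks in this package elicit pursuit at 6–15 DVA/s, comfortably above
the floor. Validated against generator ground truth, these defaults
give ≥ 0.96 sample agreement on all three 5-minute tasks (≥ 0.99 on
noise-free sessions); the parameters remain fully config-exposed.

## Task metrics

**Coverage displacement.** Valid samples are binned into 100 × 100 px
cells (remainder cells at the right/bottom edges count as cells). With
`c` = total samples / number of cells, the per-cell index is
`clip(n/c − 1, −1, +1)`: 0 at uniform coverage, −1 where the cell has
no gaze data, +1 saturation at twice the uniform count. Pre-clipping
values sum to zero by construction. The fixation heatmap bins fixation
centroids and divides by the maximum cell, so its maximum is exactly 1.

**Focus scoring.** A dwell clock starts when gaze enters the target
disc and completion is declared at `entry time + 2 s` (a continuous
time, not a sample count, so a locked-on trial reports exactly 2.0 s
and a never-acquired trial times out at exactly 10.0 s). Gaze leaving
the disc — or invalid samples — for longer than a 100 ms grace gap
resets the clock; the grace tolerates tracker dropouts and is
config-exposed because the original tolerance is not stated. Full
reset is the default (`dwell_reset_policy = "full"`); a `"pause"`
policy that retains accrued dwell is available. Scoring uses raw gaze,
not detected fixations, matching the task's real-time behaviour.

**Success curve.** The per-size median success counts are fitted with
the asymptotic exponential `y(s) = a − b·e^{−c·s}` (`c ≥ 0`) by
Levenberg–Marquardt, starting from `a = max(y)`, `b = a − min(y)`,
`c = 1` with up to 20 jittered restarts; exactly constant input
short-circuits to `b = 0`. The plateau onset is where the first
derivative `b·c·e^{−c·s}` drops below 1 per DVA.

**Pursuit comparison.** Pursuit durations and amplitudes from two
conditions are compared with the package's Mann–Whitney U test,
reported per measure with condition medians.

## Workload metrics

Pupil cleaning applies three rules in order: the feasible 1.5–9 mm
range; dilation-speed outliers above `median + 16·MAD` of the max
adjacent-sample speed (MAD unscaled); and removal of samples within
50 ms of gaps longer than 75 ms. Removed samples become invalid but
stay on the timeline. The baseline is the mean cleaned diameter over
the 2 s before the first task (≥ 50% valid required); per-task
re-baselining is available since pupil baselines drift over a session.

CPD is the *fractional* change `(mean − baseline)/baseline` by default
(`cpd_mode = "absolute"` gives mm); the source convention is ambiguous
and the fractional form is dimensionless and comparable across
participants. HR uses the identity `HR·RR = 60000` per beat. RR
artifacts are flagged automatically at > 30% deviation from an 11-beat
running median — a stand-in for device-assisted manual editing, not a
reproduction of it. RMSSD uses successive differences that never span
a flagged beat and requires ≥ 3 unflagged beats.

Rolling metrics use left-aligned 10 s windows stepped by 5 s ("50%
overlap"); windows under 50% valid yield `NA` rather than biased
values. For cross-metric agreement, metrics are min–max normalized
within participant after negating RMSSD (which falls as workload
rises).

## Agreement statistics

* **ICC(3,1)**, the single-rater two-way fixed-effects *consistency*
  form: `(MSR − MSE)/(MSR + (k−1)·MSE)`. Invariant to rater offsets;
  confidence intervals are not computed. Subjects are tasks, raters
  are metrics.
* **Bland–Altman**: bias ± 1.96·sd limits (sample SD), with the
  fraction of differences inside the limits (inclusive).
* **DTW** with absolute-difference cost, steps {(1,0),(0,1),(1,1)},
  and a Sakoe–Chiba band of half-width `ceil(0.2·max(n, m))` on the
  scaled diagonal (`|i·m − j·n| ≤ w·max(n, m)`, symmetric in the
  arguments). Similarity is `1 − distance/path length` (path length in
  nodes): inputs in [0, 1] bound each local cost by 1, so similarity
  lies in [0, 1] and equals 1 iff the aligned series match exactly. A
  summed-lengths denominator is available. Backtracking prefers the
  diagonal step on ties.
* **Mann–Whitney U** with midranks; `U = min(U1, U2)`. The two-sided
  p-value is exact by complete enumeration for `n1 + n2 ≤ 20` (correct
  under ties) and otherwise uses the tie-corrected normal
  approximation with continuity correction, which is calibrated to
  within ±0.02 of the 5% level in simulation.

## Numerical choices and degenerate inputs

The threshold iteration uses ≤ (inclusive); fragment merging and DTW
backtracking break ties toward the earlier/diagonal option; the
homography is solved by SVD with unit normalization; smoothing windows
shrink at stream boundaries rather than padding. Degenerate inputs
(constant rating matrices, constant metrics, all-removed pupil
streams, empty coverage input, infeasible DTW bands) raise classed
errors rather than returning numbers.

## Problem sizes in the test suite

The shipped tests validate the detector on 5-minute sessions at 100 Hz
(~30 000 samples), Bland–Altman coverage on 10 000 simulated pairs,
Mann–Whitney calibration on 2 000 null replicates, and the workload
direction-recovery property on 50 replicate 2-minute sessions —
desk-scale sizes chosen so the full suite runs in well under a minute
while keeping Monte-Carlo error far below the tested tolerances.

## Limitations

Participant-level findings (screen-region preferences, the 4–5 DVA
button-size thresholds, metric-agreement magnitudes) depend on real
recordings and are out of scope here; the package reproduces the
*machinery* and its self-contained constants, with direction-only
checks for the workload relations. The detector is validated on the
generator's signal structure; real data with post-saccadic
oscillations, blinks, or head motion will need parameter adjustment
through `detector_params()`.
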