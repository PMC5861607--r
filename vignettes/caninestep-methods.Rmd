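---
title: "Collar pedometry for dogs: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Collar pedometry for dogs: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caninestep)
```

## The problem

A collar-mounted tri-axial accelerometer senses the vertical undulation of
a walking dog's centre of mass: each footfall of a leg pair produces one
oscillation of the dorso-ventral (back-to-belly) acceleration around the
1 g gravity level. From that signal the package counts steps and estimates
distance walked, and validates both against video-annotated steps and GPS
tracks. Everything operates on tibbles and composes with the pipe.

The pipeline has four stages, each usable on its own:

1. **Orientation correction** — collars rotate on the neck, so the sensor
   axes drift away from the anatomical ones.
2. **Step detection** — adaptive zero-line, falling-flank zero-crossings,
   cadence gating, windowed shuffle rejection.
3. **Distance** — an inverted-pendulum model converts each step's
   acceleration "bounce" to a length; GPS tracks provide the reference via
   walk segmentation and haversine path length.
4. **Evaluation** — swing-phase matching (TP/FP/FN, PPV), Bland–Altman
   agreement, Pearson correlation, mean similarity.

## Orientation: a sagittal-plane Wahba problem

Gravity is the only reliable reference a collar sensor has. The trace is
low-passed with a zero-phase 4th-order Butterworth at
$\omega_c = 0.1\,$Hz, isolating the gravity/posture baseline. Baseline
samples whose norm lies within 0.2 g of the unit sphere, and whose
direction holds steady (within 10°) for at least 10 s, become candidate
gravity observations; shorter stable runs are treated as posture
transitions and excluded. The rotation is then the minimiser of the
least-squares alignment cost

$$J(\theta) = \tfrac12 \sum_k \lVert T(\theta)\,\hat w_k - e_z \rVert^2,
\qquad
T(\theta) = \begin{bmatrix} \cos\theta & 0 & \sin\theta \\ 0 & 1 & 0 \\
-\sin\theta & 0 & \cos\theta \end{bmatrix},$$

restricted to rotations about the sagittal plane — the collar is assumed
not to twist on itself. Restricted to this one-parameter family the
optimum is closed-form, $\theta^\* = \operatorname{atan2}(-\sum w_x,
\sum w_z)$; the test suite verifies it against a dense 3600-point grid
search of $J$. One global $\theta$ is estimated per trace: collar shift is
treated as piecewise-constant and the dominant correction applied, since
nothing in the data model identifies when a mid-walk re-correction is
warranted. Users who need per-segment correction can slice the trace and
orient each slice.

### Zero-phase filtering

The 0.1 Hz (and later 0.2 Hz) cutoffs sit at a normalized frequency of
0.002 at the 100 Hz sampling rate. Recursive direct-form Butterworth
realisations are numerically fragile there: we measured edge artifacts of
order 0.1–0.2 of the input amplitude in two standard forward–backward
implementations on a pure 3 Hz tone. `lowpass_zero_phase()` therefore
applies the exact bilinear-transform squared magnitude response (which is
precisely the response of ideal forward–backward filtering, with zero
phase) in the frequency domain, over an even-reflection extension of about
three filter time constants. DC gain is exactly 1, time-reversal symmetry
holds to machine precision, and boundary leakage decays within roughly
$1/\omega_c$ of the ends. Asymptotic claims about attenuation are
therefore asserted on the steady-state interior in the tests.

## Step detection

The corrected dorso-ventral axis is smoothed with a low-pass at 8 Hz and
its slow baseline — the component below 0.2 Hz, carrying gravity and
posture drift — is subtracted, leaving the step-band oscillation. Two
points deserve comment:

* **Baseline subtraction.** A literal 0.2 Hz low-pass would annihilate
  the 2–4 Hz steps it is meant to expose; the only physically consistent
  reading is that the low-pass *estimates the baseline*, which is then
  subtracted (equivalently, a zero-phase high-pass at 0.2 Hz). The
  literal low-pass output is available via
  `step_config(baseline_subtract = FALSE)` for comparison.
* **Smoothing.** Zero-crossing detectors jitter on wideband sensor noise:
  several spurious crossings can cluster around each true one. Smoothing
  to just above the step band (8 Hz; the 3.75 Hz band edge loses under
  0.3% amplitude) removes the sample-scale noise that causes this while
  leaving step timing essentially untouched.

The **adaptive zero-line** is recomputed over 20 s windows as the midpoint
between the maximal peak and minimal nadir, extended as a step function;
windows hop by half their length by default. A **candidate** is recorded
wherever the signal crosses the zero-line on the falling flank, with the
crossing time linearly interpolated between samples and the step's
$A_{max}$/$A_{min}$ taken as the extrema between the flanking rising
crossings.

**Cadence gating**: the valid step band defaults to 2.25–3.75 Hz, the
allometric stride-frequency law $269\,W^{-0.14}$ min$^{-1}$ evaluated at
the validation cohort's extreme masses (64 kg → 2.50 Hz, 11.3 kg →
3.19 Hz) widened by a safety margin for dogs outside that band.
`stride_frequency_hz()` lets users build weight-specific bands. A
candidate is unmarked iff its interval to the previous candidate lies in
$[1/f_{hi}, 1/f_{lo}]$; the first candidate is judged by its following
interval; a lone candidate has no interval evidence and is marked.

**Windowed rejection**: a 10-candidate window slides with stride one; a
window containing more than 3 marked candidates is rejected, and a
candidate counts as a step only if it is unmarked and lies in at least one
accepted window. Marked candidates never count, even inside accepted
windows — the stricter of the two available readings, chosen so isolated
off-cadence crossings cannot inflate counts. Bouts shorter than ten
candidates are judged by a single truncated window (with the same
absolute threshold) so short walks still register; dropping them would
zero-count any walk under ~4 s of candidates.

Two consequences of this design are worth knowing. Candidate windows that
straddle a rest/walk boundary mix genuine steps with noise crossings;
when the window still has three or fewer marked candidates, a noise
crossing whose spacing happens to fall in-band can slip through, so a
bout boundary typically contributes 0–3 spurious steps regardless of walk
length. And near the upper band edge, crossing-time jitter from in-band
noise can push an interval just below $1/f_{hi}$, costing isolated steps
for fast, low-bounce gaits. Both effects are visible in
`benchmark_suite()` output and bound the achievable PPV and detection
rate.

## Distance

Each leg pair is modelled as an inverted pendulum pivoting at its girdle
joint; the collar rides the vertical excursion of the centre of mass. The
per-step length is $h = \sqrt[4]{A_{max} - A_{min}}$ metres. The source
model states the extrema in m/s², but bounces of 0.1–1 g yield plausible
canine step lengths (0.56–1.0 m) only when the bounce is taken in g, so g
is the package default and `unit = "ms2"` is an explicit switch — the
relation is asserted, not derived, and its units are dimensionally
informal either way. Stride length is the sum of two consecutive steps,
so summing per-step lengths and summing per-stride lengths coincide;
`walk_distance_m()` sums steps.

GPS reference distance uses the haversine path length (Earth radius
6,371,000 m). `segment_walks()` extracts walks by a speed rule: points
moving between `v_min_kmh` (1 km/h) and `v_max_kmh` (12 km/h) form runs,
runs separated by gaps of at most 120 s are merged (signal dropouts, kerb
waits), and segments under 100 m are rejected. The speed bounds are this
package's documented defaults — chosen to span slow on-lead walking up to
brief trotting while excluding vehicle transport — and are fully
configurable; the 100 m floor is the validation study's rule.
Accelerometer and GPS streams are aligned by absolute timestamps only.

## The simulator

`simulate_trace()` generates collar traces with exact ground truth. A
walk segment produces $z = 1 + (b_k/2)\sin(2\pi f t)$ g — simple harmonic
bounce, one oscillation per step, per-step bounce $b_k \sim
N(\mu_b, \sigma_b)$ with amplitude switching at the zero-crossings so the
signal stays continuous — then rotates the whole segment by the inverse
sagittal transform of its collar offset and adds iid Gaussian sensor
noise per axis (default 0.02 g at 100 Hz). True step times are the
falling-flank crossings $(k + \tfrac12)/f$. Rest segments are gravity
plus noise; shuffle segments place falling crossings at log-uniform
intervals drawn from $[0.05, 0.25] \cup [0.5, 2.0]$ s, outside any
plausible step band by construction; posture shifts hold gravity tilted
within the sagittal plane.

What the simulator does *not* emulate: the dual-peak asymmetry of real
strides (thoracic and pelvic pairs are not separately modelled), gait
transitions, terrain and incline, head movements other than shuffles, and
GPS error. Passing tests therefore demonstrate correctness of the
algorithmic chain under the stated signal model, not field accuracy on
real dogs — the study's own field numbers (91% of 4695 annotated steps,
PPV 0.98) came from recordings that are not redistributable.

`benchmark_suite()` draws walks spanning 2.3–3.7 Hz and 50–500 steps,
bounce means of 0.2–0.6 g and collar offsets of ±40°, flanks them with
15 s rests (a standing dog, which also gives the orientation stage its
stable-gravity reference), and scores detections against truth intervals
of ±0.45 step periods. Suite-level detection rate and PPV are pooled
across walks, weighting by step count, the same way multi-subject field
studies pool their counts. With the default noise these sit near 0.99
pooled detection and 0.985–0.99 pooled PPV, with mean absolute distance
error under 1%; the test suite asserts the pooled detection ≥ 0.95,
pooled PPV ≥ 0.98 and mean |distance error| ≤ 5% at 50 walks under seed 1.

## Evaluation statistics

`match_steps()` implements one-to-one greedy matching: each annotated
swing phase takes the earliest unused prediction inside it; surplus
predictions — inside or outside intervals — are false positives. With no
predictions PPV is undefined (`NA`), never 0. `bland_altman()` uses the
sample (n−1) standard deviation, the critical difference is
$1.96\,\mathrm{sd}$, and swapping the series negates the mean difference
while preserving the critical difference. `mean_similarity()` averages
$1 - |gps - algo|/gps$ over walks as a percentage; a walk overestimated
by more than 100% contributes negatively and is not clipped unless
requested.

Applied to the packaged validation tables as printed, the stated
formulas give a Bland–Altman mean difference of 41.8 steps, r = 0.95,
and a mean similarity of 75.0%; the tests assert these recomputed
values. The tables' published companion text quotes partly different
headline numbers for these quantities, which are not reproducible from
the printed per-dog rows under any formula variant we tried; the package
treats the tables as ground truth.

## Numerical and degenerate-input choices

* Crossing ties (`dv` exactly on the zero-line) count on the falling side
  only; crossing times are linearly interpolated.
* A trace shorter than 30 s is rejected by the orientation stage (the
  baseline filter needs several time constants); a trace shorter than the
  20 s zero-line window is rejected by `preprocess_dv()`.
* Empty stable-segment lists raise "no stable gravity reference found"
  rather than silently skipping correction.
* `step_length_m()` returns 0 for a zero bounce and errors on
  $A_{max} < A_{min}$.
* All simulator randomness flows from one seed; the caller's RNG state is
  restored afterwards.

## Problem sizes

The shipped tests run the orientation oracle on 20 synthetic 40 s traces,
the detection benchmark on 50 walks of 50–500 steps, and the remaining
properties on 10–60 s traces; the full suite completes in about a minute
on a single core. Larger studies simply scale `benchmark_suite(n_runs)`.
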