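---
title: "Whole-foot clearance from a single IMU and a personalized shoe scan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-foot clearance from a single IMU and a personalized shoe scan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(footclear)
```

## The problem

Minimum toe clearance (MTC) — the lowest height of a single toe marker
during swing — is the conventional trip-risk metric in gait analysis, but
it describes one point on the foot. For impaired walking, especially
foot drop (weak dorsiflexion, common in multiple sclerosis and after
stroke), the part of the shoe that comes closest to the floor is often not
the toe marker: it can be the forefoot sole, or the lateral edge when the
foot is inverted. `footclear` generalizes clearance to the *whole shoe*:
every point of a personalized shoe-scan point cloud is propagated through
swing, and the per-stride **minimum foot clearance (mFC)** is the lowest
height reached by *any* point during forward swing. Negative mFC is
reported as-is: it means the rigid-body model says the shoe passed below
the floor plane, i.e. a scuff.

The measurement system is deliberately minimal: one foot-mounted IMU
(tri-axial accelerometer and gyroscope, nominally 128 Hz) and a one-off 3D
scan of the shoe with a mounting fixture that ties the scan frame to the
IMU frame. No cameras, no lab.

## The model, step by step

### Zero-velocity-update dead reckoning

During stance the foot is stationary, which gives drift-free anchors.
Stance samples are detected by thresholding the smoothed accelerometer and
gyroscope norms (`detect_zupt`; defaults 0.8 m/s² about standard gravity
and 0.3 rad/s, a 5-sample centered moving average); detected runs shorter
than 15 samples are deleted (`smooth_zupt`), removing spurious mid-swing
detections. Strides run from one stance-run start to the next
(`segment_strides`).

`reconstruct_pose` then integrates the strapdown equations between
anchors:

* initial orientation from the mean specific force over the first stance
  run (tilt only; heading is arbitrary and left at zero — clearance only
  depends on height);
* orientation propagated by rotation-vector integration of the gyroscope.
  Each gyro sample is treated as the mean angular rate over the *following*
  sample interval — the discretization exactly consistent with how the
  built-in simulator synthesizes angular rate from its pose sequence, so
  closed-loop tests isolate algorithmic error rather than quadrature
  mismatch;
* during stance-run interiors the tilt is relaxed toward the
  gravity-measured tilt with a complementary gain of 0.02 per sample. The
  first and last 3 samples of each run are excluded: stance detection is
  only transition-accurate to a few samples, and transition samples carry
  real acceleration that would be mistaken for tilt;
* world-frame velocity by trapezoidal integration of `R(k) f(k) + g`, reset
  to zero over every stance run; per stride, a constant world acceleration
  bias is fit by least squares to the velocity observed over the stride's
  terminal stance run and removed as a ramp, and the residual mean velocity
  over that run is removed as a step from the heel-strike sample onward
  (the impulsive velocity error of heel strike);
* position by trapezoidal integration. The zero height is re-initialized
  at every stance run: on level ground the foot returns to the same floor
  each stance, so any height accumulated across a stride is drift. Without
  this the per-stride height error compounds over a bout and a single
  trial-level floor height would be meaningless.

One further correction is needed because an accelerometer bias is
*indistinguishable* from an initial tilt error in the stance gravity
measurement, and a tilt of δ radians makes a walk of length L climb or
sink by δ·L — several millimetres per stride at realistic bias levels,
while leaving the terminal-run velocity drift near zero (so the ramp fit
cannot see it). The per-stride height drifts against horizontal
displacements observe the tilt directly; `reconstruct_pose` fits a small
re-leveling rotation to them by ridge least squares (ridge scaled to the
total horizontal path, so the cross-track component — unobservable on a
straight walk — is shrunk to zero) and reruns the integration once.

### Attaching the scan

The scan CSV gives the shoe points, toe/heel landmarks, an optional
toe-marker point, and the IMU fixture origin and axes. Points are stored
relative to the fixture origin, so the world position of point *i* at
sample *k* is

```
p_world_i(k) = p_IMU(k) + R(k) · R* · R_scan→IMU · p_scan_i
```

`R_scan→IMU` is the nearest proper rotation (orthogonal Procrustes) to the
unit-normalized fixture axes. `R*` is the **flat-foot correction**: small
errors in scan processing or fixture seating leave the reconstructed foot
tilted by up to several degrees during stance, which is fatal for a
clearance measure. At the first stance instant a support plane is fitted
flush against the bottom of the transformed sole (iterative contact-set
scheme: points within 3 mm of the lowest extent, total-least-squares
plane, re-select, at most 20 iterations, then translate so no point is
below); the minimal rotation taking its normal to vertical, conjugated
into the IMU frame at that instant, is `R*`, applied at every sample.
Corrections above 15° are rejected as calibration failures.

Finally the floor: the reconstruction pins heights to the IMU's initial
position, so the stance-phase sole sits below zero. The per-stride medians
of the stance lowest point are averaged into one trial-level vertical
offset (`compute_floor_offset`), subtracted from all heights.

### Clearance

With floor-referenced heights, `lowest_point_trace` gives LP(k), the
minimum height over the sole grid (restricted to sole points after
verifying every non-sole point lies above the sole's supporting plane —
equivalent and cheaper than scanning the whole cloud). The
**forward-swing window** of a stride runs from its maximum heel height to
its maximum toe height (first index on ties); windows where the toe peak
precedes the heel peak, or a peak falls in stance, are flagged invalid
rather than erroring — the definition is explicitly not guaranteed for
every gait pattern. mFC is the minimum of LP over the closed window.

Late swing — the final third of the window, computed with a ceiling so it
never reaches into the middle third — is where dorsiflexion should peak;
the scan-frame (x, y) locations of the late-swing lowest points, pooled
over strides, are smoothed into a normalized Gaussian density over the
sole grid (`sole_density_heatmap`; defaults 2 mm spacing, 10 mm
bandwidth, both exposed in the config — the density is a visualization
and these only set its granularity). `clearance_trend` adds an OLS slope
of mFC against stride start time with the exact t-test p-value, for
fatigue protocols such as the six-minute walk test; it is a simple linear
summary and makes no claim to reproduce any particular published test.

### Validation against motion capture

The toe-marker point of the scan can be compared with an optical-capture
trajectory of the physical toe marker. The reference is linearly
interpolated onto the IMU timebase (gap-adjacent samples stay gaps), a
single global lag is found by cross-correlation of the two height signals
(peak below 0.5 aborts with an alignment error), and swing-phase key
points are extracted from both: local maxima with topographic prominence
of at least 5 mm; two or more give MaxP1, the valley MinP, and MaxP2
(an M-shaped swing), exactly one gives MaxP2 only. Strides where the two
sources disagree on shape class are excluded and counted.

Per-key-point differences (reconstruction − reference, mm) go into a
random-intercept model, stride nested in participant, fit by REML with
`nlme::lme` — repeated key points per stride and strides per participant
violate the independence that classic Bland–Altman limits assume. The
bias is the fixed intercept and the 95% limits of agreement are
`bias ± 1.96·√(σ²_participant + σ²_stride + σ²_residual)`. We read the
"±8 mm" interval of this design as limits of agreement (bias ± 1.96
total SD) rather than a confidence interval of the bias: with ~150 key
points a bias CI would be far narrower than the total spread, and the
nested-variance construction is what the mixed-model approach exists for.
Zero-variance input returns collapsed limits exactly; singular fits fall
back to method-of-moments variance components with a warning. The reported
R² is the squared Pearson correlation of the paired heights, and is
labeled as such.

## The synthetic gait generator

Because no recorded data ship with the package, every claim is exercised
on simulated gait (`make_shoe_cloud`, `simulate_foot_poses`,
`synthesize_imu`, `oracle_clearance`). The generator produces exact poses:
constant flat-footed stance (the IMU height equals the analytic support
height of the sole footprint, so the support plane sits exactly at zero),
and a swing composed of C² profiles — a smoothed forward ramp, an apex
bump, plantarflexion at toe-off decaying into dorsiflexion before landing,
optional inversion roll, and an optional mid-late-swing "scuff" dip. All
profiles and their first two derivatives vanish at the stance boundaries,
so the synthesized inertial signals contain no impulses. IMU signals are
derived by central second differences of position and forward rotation
differences, sharing the reconstruction's discretization; Gaussian noise
and a constant accelerometer bias are added under a mandatory seed (an
analytic-derivative mode is not provided; convergence is instead checked
by raising the sample rate).

Default conditions: 1.1 s stride, 60% stance, 1.2 m stride length, 5 cm
apex, 25° plantarflexion, 22° dorsiflexion, 128 Hz — a typical self-paced
adult walk. The scenario pack mirrors the clinically interesting walking
styles: `typical` (M-shaped toe path), `foot_drop` (no late dorsiflexion;
the lost dorsiflexion partly becomes a 5° plantar droop so the forefoot
hangs low, giving a single-peaked toe path), `inversion` (8° sustained
roll; the lateral sole edge, negative y for this right-foot geometry,
becomes the late-swing lowest region), and `toe_drag` (2 cm apex plus a
2 cm scuff dip, driving true mFC to about −6 mm). The scuff dip is an
explicit parameter because the support-height construction otherwise
guarantees non-negative clearance by design.

`oracle_clearance` evaluates the lowest point, window and mFC directly
from the exact poses and the actual point cloud — no integration, no
estimation — and is the reference all closed-loop tests compare against.

What the generator does *not* emulate, and what passing tests therefore do
not show: soft-tissue and shoe deformation (the rigid-body assumption is
shared with the method itself, and is why stance-phase clearance is never
reported), gyroscope bias and scale error, magnetometer-free heading drift
interacting with turning paths (the simulated walk is straight; heading is
uncorrected by design), uneven floors, and marker occlusion patterns
beyond simple gaps.

## Numerical choices and edge cases

* Gravity is fixed at 9.80665 m/s²; all internal lengths are meters,
  outputs are millimeters; indices are 1-based with `start`/`end` window
  bounds where `end` is one past the last sample.
* Argmax/argmin ties take the earliest index everywhere.
* The support-plane fit errors on collinear contact sets; the fixture
  rotation errors when axes are nearly parallel (smallest singular value
  below 0.5) or norms leave [0.9, 1.1].
* Problem sizes in the test-suite: bouts of 5–20 strides at 128 Hz with a
  1 cm sole grid (~260 points), which exercises every code path at
  sub-second cost per bout; the brute-force plane-search oracle uses a
  2 cm grid to keep triple enumeration tractable.
* Zero-variance agreement input and constant-mFC trends are handled
  explicitly (collapsed limits; zero slope with p = 1).

## Known limitations

* Heading drift is uncorrected; only heights and scan-frame locations are
  trustworthy, not world x–y paths over long bouts.
* The floor estimate carries a stance-compression bias: the floor is
  defined while the sole is loaded by body weight, so it may sit slightly
  below the true surface, making swing clearances read slightly high.
* The forward-swing window definition fails (and is flagged) for gait
  patterns whose toe-height maximum precedes the heel-height maximum.
* One trial-level floor offset assumes level ground.

## A worked run

```{r, eval = FALSE}
cloud <- make_shoe_cloud()
params <- scenario_params("typical", seed = 1, n_strides = 20)
truth <- simulate_foot_poses(params, cloud)
rec <- synthesize_imu(truth)

ba <- analyze_bout(rec, cloud)
ba
mean(abs(sapply(ba$strides, `[[`, "mfc") -
         sapply(oracle_clearance(truth)$strides, `[[`, "mfc"))) * 1000
```

The same pipeline is exposed as files via `run_simulate()`,
`run_reconstruct()`, `run_clearance()` and `run_validate()`, and as the
`exec/footclear` command-line script.
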