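---
title: "Joint kinematics from inertial sensors: models, calibration and drift correction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint kinematics from inertial sensors: models, calibration and drift correction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Marker-based optical motion capture does not scale to the capture volumes
of outdoor sports, so 3D joint angles in alpine skiing have to come from
body-worn inertial sensors: one accelerometer + gyroscope unit per body
segment, no magnetometer (indoor steel structures and lift infrastructure
make magnetic heading unusable). Getting clinically meaningful knee, hip
and trunk angles out of raw inertial data requires three stages, each with
its own error budget:

1. **sensor-to-segment calibration** — the fixed rotation between each
   sensor's axes and the segment's anatomical axes, estimated functionally
   (from prescribed movements) because ski boots make the usual neutral
   reference posture impossible (they impose roughly 17 degrees of ankle
   flexion);
2. **initial orientation** — strap-down integration needs a starting
   orientation per segment;
3. **orientation tracking** — integration of angular velocity drifts,
   dominated by gyroscope bias; the drift has to be estimated and removed
   without a magnetometer.

`skimu` implements the full pipeline plus a rigid-body simulator that
generates IMU data with known ground truth, so every stage can be tested
end to end.

# Conventions

Quaternions are Hamilton, scalar-first; `q` maps body (anatomical)
coordinates to world coordinates and `quat_multiply(q1, q2)` applies `q2`
first. Segment anatomical frames are X anterior, Y superior, Z right
(medio-lateral); the global frame is Y up, X pointing down the fall line,
Z right. With these axes, forward hip flexion is a negative rotation about
Z and knee flexion is positive, which matches the sign convention in which
skiing reference data are usually reported (hip flexion between roughly
-67 and -25 degrees, knee flexion between 36 and 75 degrees during
carpet-skiing turns).

Joint angles follow the Grood--Suntay joint coordinate system: flexion
about the proximal segment's medio-lateral axis, internal/external
rotation about the distal segment's longitudinal axis, ab/adduction about
the floating axis orthogonal to both. In these frames this is exactly the
intrinsic Z-X'-Y'' Euler factorisation, which is what `jcs_decompose()`
computes; `jcs_compose()` is its exact inverse, and the simulator builds
relative rotations with it so scripted angles are recoverable to machine
precision. For the trunk the same decomposition is used by default; a
`"yxz"` variant (axial rotation resolved first) is exposed because
published trunk conventions differ and the adaptation used alongside this
calibration scheme is not uniquely defined — the choice is a configuration
switch, not a hidden default.

# Functional calibration

The four movements are executable in ski boots on the slope: three slow
squats, three axial trunk rotations holding a ski pole behind the neck,
three slow hip ab/adductions per leg, and 10 s of upright standing. Each
calibration hypothesis is implemented directly:

* **trunk/head sensors** (`calibrate_trunk`): squats rotate the segment
  about its medio-lateral axis; trunk rotations about the vertical; the
  trunk is vertical when standing. The gravity direction measured upright
  is kept as the exact superior axis, the squat axis is projected
  orthogonal to it, and the trunk-rotation axis is only used as a
  consistency check (its residual to the superior axis is reported).
* **shanks** (`calibrate_shank`): the ab/adduction axis is kept exact as
  anterior-posterior; the medio-lateral axis is its cross product with the
  gravity direction at movement start (when the leg is vertical).
* **thighs** (`calibrate_thigh`): the squat pins the medio-lateral axis
  but leaves the rotation about it free. That residual angle is resolved
  by the joint-acceleration constraint at the hip: lower-back and thigh
  accelerations, translated to the hip centre with the fixed offsets
  (0.05, -0.10, 0) m and (-0.05, 0.30, 0) m, must agree in direction once
  expressed in the global frame. A 1-D golden-section search over +/-30
  degrees minimises the mean orientation difference; the objective is
  returned in the diagnostics so a grid search can audit the optimum. A
  coarse 2-degree grid backstop restarts the search if golden-section
  bracketing lands in a worse local minimum.
* **refinement** (`refine_lower_limb`): three biomechanical constraints
  are enforced as minimal corrective rotations, swept twice in a fixed
  order — medio-lateral axes perpendicular to gravity when upright, zero
  mean knee flexion during the ab/adduction (applied to the thigh, whose
  sagittal alignment comes from the comparatively weak acceleration
  matching, never to the shank, whose alignment is pinned by gravity),
  and equal left/right inclination at squat start (split half/half).
  Total corrections above 25 degrees abort with a movement-mis-execution
  error.

Rotation axes are estimated as the principal direction of the
angular-velocity samples weighted by rate magnitude. The sign of a
symmetric back-and-forth movement's mean angular velocity is near zero,
so the calibration routines fix signs against a reference direction
(assumed mounting error below ~45 degrees), while `estimate_rotation_axis`
itself defaults to the mean-projection rule.

Repeated calibrations are summarised by the dispersion
$\chi = \sqrt{\sum_F \Delta_F^2 /(N-1)}$ with
$\Delta_F = 2\arccos\,\lvert\mathrm{Re}(\bar q \otimes q_F^{-1})\rvert$
(the geodesic angle between each calibration and the rotation mean; the
mean is the principal eigenvector of the sign-aligned outer-product sum).
A literal transcription of the defining equation would read
"$2\cos(\cdot)$", which cannot produce an angle; the `acos` form is the
standard geodesic distance and is what `dispersion_chi()` computes.

# Strap-down tracking and the two-pass drift correction

Initial orientations take inclination from the mean acceleration over a
quasi-static trial start and assign every segment the same azimuth (zero:
facing the fall line), which is exact when the athlete stands facing
downhill. `strapdown_integrate()` advances the quaternion with exact
axis-angle increments, using the trapezoidal average of consecutive
gyroscope samples per step; the half-sample phase this removes is worth
~0.09 degrees over 120 s at 500 Hz, which matters against the 0.1 degree
round-trip bound the simulator is held to.

Drift is observed through the joint acceleration constraint. For a joint
with distal and proximal sensors at lever arms $r_d$, $r_p$:

$$\tilde a = a + \dot\omega \times r + \omega \times (\omega \times r),$$

rotated into the global frame with the current (drift-affected)
orientation estimates. The instantaneous drift $\delta(t)$ is the minimal
rotation taking the distal vector onto the proximal one (angle from the
normalised dot product, axis from the cross product). Samples count only
when both magnitudes exceed 6 m/s^2 and differ by less than 20% of their
mean. Because $\delta(t)$ also contains movement-correlated error, it is
averaged (rotation average) over windows of two movement cycles, where a
cycle (one left + one right turn) starts at a local maximum of the
segment's global-X angular velocity (2 Hz smoothing, 1 s minimum period).
The per-sample correction is the spherical-linear interpolation between
consecutive window means anchored at window midpoints, left-applied to
the distal trace; correction is applied to the distal segment only,
processing joints from the trunk outwards so the lower back anchors the
chain's heading.

Gravity dominates the translated accelerations, so the first pass mostly
constrains rotations about horizontal axes — heading (azimuth) drift
survives it nearly untouched. The second pass therefore zeroes the
acceleration component along the vertical axis and re-estimates drift
from the horizontal components alone, with a 0.6 m/s^2 threshold and the
same 20% rule, reducing each window estimate to its twist about the
vertical. One numerical choice matters here: the "vertical" is measured
per window as the mean direction of the proximal translated acceleration
(the gravity reaction) rather than taken as the fixed global Y axis. The
two coincide exactly when the orientation estimates are drift-free; when
the estimates carry tens of degrees of accumulated drift, the fixed-Y
variant leaks several m/s^2 of rotated gravity into the "horizontal"
plane and buries the heading signal, while the measured vertical keeps
the pass effective (in the simulated bias regime below, ~2 degrees of
residual instead of ~20).

Two robustness rules guard the window machinery: a window with fewer than
25 (or 2% of) valid samples inherits the previous window's estimate
instead of contributing a noise-dominated rotation, and a trailing window
stub shorter than half the median window is merged into its neighbour.

# The simulator and what passing tests mean

`ski_chain()` defines a six-segment chain (lower back, sternum, both
thighs and shanks) with sensor-to-joint vectors; the hip offsets are the
fixed values above, the remaining lever arms realistic mid-segment
placements. `ski_motion_script()` drives it with sinusoidal turn cycles
(4 s per left+right turn, 120 s trials at 500 Hz) whose joint-angle
ranges match reference values for carpet skiing: knee flexion 36.3-74.7
degrees, hip flexion -67.2 to -24.8, trunk flexion 3.7-16.6, trunk
lateral/axial within about +/-7 degrees; the pelvis translates +/-0.6 m
laterally and bobs vertically with the turns, providing the horizontal
joint accelerations that make azimuth drift observable. All envelopes use
a C-infinity ramp so every scripted derivative is smooth; motion ramps up
from 2 s of standstill so gravity-based initialisation applies.

Gyroscope signals are derived from the ground-truth orientations by
central-difference quaternion logarithms and accelerometers from central
second differences of sensor position plus gravity — deliberately not the
integrator's discretisation, so round trips test the tracker rather than
a shared approximation. The default noise model is a consumer-grade MEMS
unit after coarse factory calibration: constant gyro bias of 0.25 deg/s
per axis with sign pattern (+, +, -) on every sensor, 0.2 deg/s gyro and
0.05 m/s^2 accelerometer white noise, seeded mandatorily. The bias sign
pattern was chosen so that, with the default postures, uncorrected knee
azimuth drift over 120 s lands near 30 degrees — the regime the azimuth
pass exists to fix; a pattern aligned with both segments' frames would
largely cancel in the relative orientation and test nothing.

What the simulator does **not** model: soft-tissue artefact (segments are
perfectly rigid), ski-snow vibration, accelerometer scale/offset error,
magnetic anything, and inter-sensor clock drift. Consequently the
end-to-end precision achieved on synthetic data (well under 1 degree for
knee flexion once the gyro offset is estimated from the upright stance)
is far better than the few-degree precision achievable on humans, where
soft tissue dominates. Passing the synthetic suite demonstrates
correctness of the algorithms, not field accuracy; the acceptance bound
on knee-flexion precision (<= 5 degrees) is an order-of-magnitude guard
chosen to match precision levels reported for real skiing data, not an
equality claim.

Simulation sizes in the test suite: unit tests run 20 s trials at 250 Hz
and calibration movements at 250 Hz; the acceptance checks run the study
conditions (120 s at 500 Hz, 100 random mountings at 500 Hz). These sizes
were chosen to exercise every code path at full fidelity where the claim
depends on it.

# Degenerate inputs and tie-breaks

* Antiparallel vectors in `quat_between_vectors()`: the rotation axis is
  undefined; a deterministic orthogonal axis (smallest-component rule) is
  used so results are reproducible.
* Quaternion sign: `q` and `-q` are the same rotation; canonicalisation
  (non-negative scalar part) happens only at API boundaries, never inside
  integration or interpolation, where sign flips would break continuity.
* Floating-axis singularity: samples with ab/adduction within 1 degree of
  +/-90 degrees carry a `gimbal` flag.
* Zero-variance inputs to the validation statistics (constant curves)
  return explicit `defined = FALSE` flags rather than silent NaN; a CMC
  whose variance ratio exceeds 1 (curves more dissimilar than the
  grand-mean model) is likewise flagged undefined rather than imaginary.
* `signal::filtfilt` starts from zero initial conditions; every zero-phase
  filter call goes through an odd-reflection padding wrapper (20/cutoff
  seconds of padding) so edges are transient-free.

# Parameters at a glance

| Parameter | Default | Units | Role |
|---|---|---|---|
| `th_max` | 6 | m/s^2 | minimum joint-acceleration magnitude, pass 1 |
| `rel_tol` | 0.2 | — | max relative magnitude difference, both passes |
| `th_azimuth` | 0.6 | m/s^2 | minimum horizontal magnitude, pass 2 |
| `window_cycles` | 2 | cycles | drift-averaging window length |
| cycle smoothing | 2 | Hz | low-pass before peak picking |
| minimum cycle period | 1 | s | peak merging |
| `gyro_derivative` cutoff | 10 | Hz | low-pass before differentiating gyro |
| anti-alias cutoff | 0.4 x target | Hz | resampling low-pass |
| upright window | 10 | s | gyro offset estimation |
| hip centre offsets | (0.05, -0.10, 0) / (-0.05, 0.30, 0) | m | lower back / thigh to hip |

# Known limitations

The azimuth of the whole chain is unobservable without a magnetometer:
all segments share an arbitrary common heading (initialised to zero), so
only relative (joint) orientations are meaningful. Between-subject
absolute angle offsets observed on real data (athlete-specific calibration
bias) are outside what the rigid simulator can reproduce. The trunk
"adapted" convention is an interpretation with a documented switch. The
correction assigns all joint drift to the distal segment; a split
assignment would need information the joint constraint does not provide.
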