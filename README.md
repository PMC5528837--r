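# skimu

3D knee, hip and trunk joint angles in alpine skiing from body-worn
inertial sensors (accelerometer + gyroscope only — no magnetometer, no
cameras).

Optical motion capture cannot cover the volumes of a ski slope, and
magnetometers fail indoors. `skimu` implements a complete inertial
pipeline for people who study skiing (or other cyclic whole-body sports)
biomechanics:

* **functional sensor-to-segment calibration** from four movements an
  athlete can perform wearing ski boots — squats, trunk rotations, hip
  ab/adductions, upright standing — combined with biomechanical
  constraints (zero mean knee flexion during ab/adduction, medio-lateral
  axes perpendicular to gravity when upright, left/right symmetry);
* **strap-down orientation tracking** (quaternion integration of angular
  velocity) with a **two-pass joint-drift correction**: accelerations
  measured on two segments sharing a joint are translated to that joint
  by rigid-body kinematics,

  `ã = a + ω̇ × r + ω × (ω × r)`,

  and any orientation mismatch between the globally expressed
  `ã_distal` and `ã_proximal` is attributed to drift
  (`δ(t)` = the rotation taking one onto the other, averaged over
  two-turn-cycle windows, valid only where both magnitudes exceed
  6 m/s² and agree within 20%). Because gravity dominates, a first pass
  corrects mainly inclination; a second pass zeroes the vertical
  acceleration component and re-estimates the remaining drift about the
  vertical axis (threshold 0.6 m/s²) — this is what removes heading
  (azimuth) drift, which gravity alone cannot observe;
* **Grood–Suntay joint angles** (flexion / ab-adduction /
  internal-external rotation via the floating-axis decomposition), with
  a configurable trunk variant;
* **validation statistics**: calibration dispersion
  `χ = √(ΣΔ²/(N−1))` with `Δ = 2 acos|Re(q̄ ⊗ q_F⁻¹)|`, repeatability
  offset/precision across repeated calibrations, the coefficient of
  multiple correlation, and accuracy / precision / Pearson correlation
  against a reference trace;
* a **rigid-body kinematic-chain simulator** producing ground-truth
  orientations and synthetic IMU streams (cyclic skiing turns, the four
  calibration movements, gyro bias + white noise, mounting misalignment)
  so the whole pipeline is testable with known truth.

## Worked example

Simulate a 60 s skiing trial at 500 Hz with a realistic constant gyro
bias (0.25 deg/s per axis), track the thigh and shank, and correct the
knee's drift:

```r
library(skimu)

chain  <- ski_chain()
script <- ski_motion_script(duration = 60, rate = 500)
sim    <- simulate_trial(chain, script)
noise  <- noise_model(seed = 1)
streams <- synthesize_trial_imu(sim, chain, noise,
                                segments = c("thigh_l", "shank_l"))

thigh <- strapdown_integrate(streams$thigh_l, sim$q$thigh_l[1, ])
shank <- strapdown_integrate(streams$shank_l, sim$q$shank_l[1, ])
j   <- chain$joints$knee_l
res <- drift_correct_pair(thigh, shank, streams$thigh_l, streams$shank_l,
                          j$r_p, j$r_d)

max(abs(relative_azimuth_error(thigh$q, shank$q,
                               sim$q$thigh_l, sim$q$shank_l)))
max(abs(relative_azimuth_error(thigh$q, res$dist_trace$q,
                               sim$q$thigh_l, sim$q$shank_l)))

knee <- grood_suntay(thigh, res$dist_trace, joint = "knee_l")
error_metrics(knee$flexion, sim$script$joints$knee_l[, 1])[1:3]
```

Output:

```
uncorrected max |azimuth error|: 17.7 deg
corrected   max |azimuth error|: 2.4 deg
knee flexion accuracy 0.00 deg, precision 0.14 deg, r = 1.000
```

Over 60 s the gyro bias rotates the knee's internal/external-rotation
axis by ~18 degrees (over 120 s it exceeds 30); the two-pass correction
brings the error down to ~2 degrees, and the recovered flexion matches
the scripted ground truth to a fraction of a degree. On real athletes
soft-tissue artefact (not modelled by the rigid simulator) raises these
errors to the few-degree range.

A command-line interface covering the same pipeline
(`simulate | calibrate | track | angles | validate`) is installed at
`system.file("cli", "skimu", package = "skimu")`; see `?skimu_cli`.

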