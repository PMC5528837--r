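# Shared helpers for the skimu test suite. Fixtures are built in code; the
# heavier simulations reused by several tests are cached per session.

rad <- function(deg) deg * pi / 180
deg <- function(rad) rad * 180 / pi

random_unit_quat <- function() {
  q <- stats::rnorm(4L)
  q / sqrt(sum(q^2))
}

random_unit_vec <- function() {
  v <- stats::rnorm(3L)
  v / sqrt(sum(v^2))
}

# Angle (deg) between two rotations, sign-ambiguity safe.
quat_angle_between <- function(q1, q2) {
  deg(quat_angle(quat_multiply(quat_normalize(q1), quat_conjugate(quat_normalize(q2)))))
}

# Rodrigues rotation formula, the independent oracle for axis-angle rotation.
rodrigues <- function(axis, angle, v) {
  k <- axis / sqrt(sum(axis^2))
  v * cos(angle) + pracma_cross(k, v) * sin(angle) + k * sum(k * v) * (1 - cos(angle))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

# Small noise-free skiing simulation shared across tests (20 s @ 250 Hz).
local_sim_cache <- new.env(parent = emptyenv())

small_trial <- function() {
  if (is.null(local_sim_cache$trial)) {
    chain <- ski_chain()
    script <- ski_motion_script(duration = 20, rate = 250)
    sim <- simulate_trial(chain, script)
    streams <- synthesize_trial_imu(sim, chain, noise = NULL)
    local_sim_cache$trial <- list(chain = chain, sim = sim, streams = streams)
  }
  local_sim_cache$trial
}

calibration_sim <- function() {
  if (is.null(local_sim_cache$calib)) {
    chain <- ski_chain()
    local_sim_cache$calib <- list(
      chain = chain,
      cm = simulate_calibration_movements(chain, noise = NULL, rate = 250)
    )
  }
  local_sim_cache$calib
}

truth_traces <- function(sim, chain) {
  out <- lapply(names(chain$segments), function(nm) {
    orientation_trace(sim$t, sim$q[[nm]], nm)
  })
  stats::setNames(out, names(chain$segments))
}
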