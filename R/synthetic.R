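# Synthetic multi-sensor IMU gait simulator.
#
# The generator produces kinematically self-consistent recordings: a
# per-sensor orientation trajectory drives the gyroscope, Euler-angle,
# accelerometer (gravity projection + gait harmonics), magnetometer
# (Earth-field projection), velocity-increment and orientation-increment
# channels, so the cross-channel identities a real strap-down unit obeys
# hold exactly and downstream stages can be validated against them.

GRAVITY_MS2 <- 9.81
B_EARTH <- c(0.4, 0.0, -0.6)  # Earth magnetic field, arbitrary units

#' Default surface effect table
#'
#' Per-surface orientation baselines and gait modifiers: slopes tilt the
#' pitch baseline up/down by equal magnitude, banked surfaces tilt the
#' roll baseline left/right symmetrically, stairs slow the cadence and
#' amplify vertical motion, and grass/cobblestone inject orientation
#' jitter several times the flat-pavement level (cobblestone the most).
#' Flat even pavement is the low-noise reference.
#'
#' @return data.frame keyed by surface code with columns `pitch_deg`,
#'   `roll_deg`, `cadence_factor`, `vertical_amp_factor`, `jitter_sd`
#'   (degrees).
#' @export
default_surface_effects <- function() {
  df <- data.frame(
    surface = surface_levels(),
    pitch_deg           = c(0,    5,   -5,   10,  -10,  0,    0,    0,   0),
    roll_deg            = c(0,    0,    0,    0,    0,  0,   -8,    8,   0),
    cadence_factor      = c(1,    0.7,  0.7,  1,    1,  0.95, 1,    1,   0.9),
    vertical_amp_factor = c(1,    1.8,  1.8,  1,    1,  1.1,  1,    1,   1.2),
    jitter_sd           = c(0.5,  1.0,  1.0,  0.8,  0.8, 1.5, 0.8,  0.8, 2.5),
    stringsAsFactors = FALSE)
  rownames(df) <- df$surface
  df
}

#' Default sensor-site gains for the surface signal
#'
#' How strongly each placement expresses surface-dependent orientation
#' structure: shanks respond most, thighs less, the trunk less still,
#' and the wrist barely at all (the freely swinging arm decouples from
#' the ground), mirroring the empirical ordering of placement
#' informativeness.
#'
#' @return Named numeric vector over [sensor_levels()].
#' @export
default_site_gain <- function() {
  c(wrist = 0.05, thighR = 0.6, thighL = 0.6,
    shankR = 1.0, shankL = 1.0, trunk = 0.4)
}

#' Simulation configuration
#'
#' Defaults encode the emulated study design: 30 participants, 9
#' surfaces, 6 trials per condition, trial durations 16.4 +/- 4.2 s at
#' 100 Hz, and 14 trials whose left-thigh recording is entirely missing.
#' Effect sizes are strong enough that surface classes are separable by
#' a small network while flat/grass/cobblestone remain the hardest to
#' tell apart.
#'
#' @param n_participants Number of simulated participants.
#' @param trials_per_condition Trials per (participant, surface) pair.
#' @param duration_mean_s,duration_sd_s,duration_min_s Trial-duration
#'   distribution (normal, truncated below at `duration_min_s`), seconds.
#' @param sample_rate Sampling rate, Hz.
#' @param cadence_mean_hz,cadence_sd Stride-frequency distribution
#'   across participants, strides/s.
#' @param surface_effects Surface effect table, see
#'   [default_surface_effects()].
#' @param site_gain Named site gains, see [default_site_gain()].
#' @param noise_sd Named list of white-noise standard deviations per
#'   channel family: `Acc` (m/s^2), `Gyr` (rad/s), `Mag` (a.u.).
#' @param mag_surface_shift Magnitude (a.u.) of a per-surface static
#'   offset added to the world magnetic field, emulating environment-
#'   specific magnetic anomalies (rebar in stairwells, street furniture
#'   on cobblestone, and so on). Each surface receives a fixed, distinct
#'   offset direction scaled by this value; the default 0 disables the
#'   effect.
#' @param missing_sensor Sensor whose recording is dropped in
#'   `missing_sensor_trials` randomly chosen trials.
#' @param missing_sensor_trials Number of trials with that sensor fully
#'   missing.
#' @param seed Integer seed; a fixed seed reproduces the cohort exactly.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_participants = 30,
                       trials_per_condition = 6,
                       duration_mean_s = 16.4,
                       duration_sd_s = 4.2,
                       duration_min_s = 6.0,
                       sample_rate = 100,
                       cadence_mean_hz = 1.8,
                       cadence_sd = 0.15,
                       surface_effects = default_surface_effects(),
                       site_gain = default_site_gain(),
                       noise_sd = list(Acc = 0.05, Gyr = 0.02, Mag = 0.02),
                       mag_surface_shift = 0,
                       missing_sensor = "thighL",
                       missing_sensor_trials = 14,
                       seed = 20231008) {
  stopifnot(n_participants >= 1, trials_per_condition >= 1,
            duration_mean_s > 0, duration_min_s > 0,
            sample_rate > 0, all(site_gain > 0),
            mag_surface_shift >= 0,
            missing_sensor %in% sensor_levels(),
            missing_sensor_trials >= 0)
  structure(as.list(environment()), class = "sim_config")
}

#' Draw a participant profile
#'
#' Per-participant idiosyncrasies: cadence, a global baseline yaw
#' (heading, uniform on the circle), mild per-site amplitude multipliers
#' and an arm-swing amplitude/phase that only affects the wrist.
#'
#' @param participant_id Integer id.
#' @return Object of class `participant_profile`. Uses the current RNG
#'   stream.
#' @export
participant_profile <- function(participant_id) {
  structure(list(
    participant_id = as.integer(participant_id),
    cadence_hz = max(0.5, stats::rnorm(1, 1.8, 0.15)),
    yaw0 = stats::runif(1, 0, 2 * pi),
    site_amp = stats::setNames(
      pmax(0.5, stats::rnorm(6, 1, 0.1)), sensor_levels()),
    armswing_amp = stats::runif(1, 0.5, 1.5),
    armswing_phase = stats::runif(1, 0, 2 * pi)
  ), class = "participant_profile")
}

# Body-frame reading of a world vector under intrinsic Z-Y-X
# (yaw-pitch-roll) orientation; vectorized over time. Angles in radians.
.world_to_body <- function(yaw, pitch, roll, v) {
  cy <- cos(yaw); sy <- sin(yaw)
  cp <- cos(pitch); sp <- sin(pitch)
  cr <- cos(roll); sr <- sin(roll)
  # rows of R^T where R = Rz(yaw) %*% Ry(pitch) %*% Rx(roll)
  bx <- cy * cp * v[1] + sy * cp * v[2] - sp * v[3]
  by <- (cy * sp * sr - sy * cr) * v[1] + (sy * sp * sr + cy * cr) * v[2] +
    cp * sr * v[3]
  bz <- (cy * sp * cr + sy * sr) * v[1] + (sy * sp * cr - cy * sr) * v[2] +
    cp * cr * v[3]
  cbind(bx, by, bz)
}

# Fixed, distinct world-frame magnetic anomaly direction per surface
# (evenly spread headings plus a varying vertical part), scaled by the
# configured shift magnitude. Deterministic: no RNG involved.
.surface_mag_offset <- function(surface, shift) {
  if (shift == 0) return(c(0, 0, 0))
  i <- match(surface, surface_levels())
  a <- 2 * pi * (i - 1) / 9
  shift * c(cos(a), sin(a), 0.5 * sin(3 * a + 1))
}

# Unit quaternion of per-sample small rotation omega * dt (rotation
# vector, radians); returns n x 4 matrix (q0, q1, q2, q3), q0 ~ 1.
.rotvec_quaternion <- function(wx, wy, wz, dt) {
  theta <- sqrt(wx^2 + wy^2 + wz^2) * dt
  half <- theta / 2
  s <- rep(0.5, length(theta))           # lim sin(theta/2)/theta = 1/2
  nz <- theta > 0
  s[nz] <- sin(half[nz]) / theta[nz]
  cbind(cos(half), s * wx * dt, s * wy * dt, s * wz * dt)
}

#' Simulate one walking trial
#'
#' Generates all six sensors of a labeled trial from the kinematic
#' model: a per-site orientation trajectory (surface baseline scaled by
#' site gain + cadence-locked oscillation + surface jitter) from which
#' every channel family is derived. The identities
#' `VelInc = Acc / sample_rate`, `FreeAcc = Acc - gravity projection`
#' and unit-norm `OriInc` hold exactly by construction.
#'
#' @param profile A [participant_profile()].
#' @param surface Surface code.
#' @param duration_s Trial duration in seconds (>= 1).
#' @param config A [sim_config()] (effect tables, gains, noise levels).
#' @param trial_index Trial repetition index.
#' @return A [gait_trial()] with all 6 sensors. Uses the current RNG
#'   stream.
#' @export
simulate_trial <- function(profile, surface, duration_s, config = sim_config(),
                           trial_index = 1L) {
  if (!is.finite(duration_s) || duration_s < 1)
    stop("simulate_trial: duration must be at least 1 s")
  surface <- match.arg(surface, surface_levels())
  fs <- config$sample_rate
  n <- floor(duration_s * fs)
  t <- seq_len(n) / fs
  eff <- config$surface_effects[surface, ]
  f <- profile$cadence_hz * eff$cadence_factor  # stride frequency, Hz
  deg <- pi / 180
  b_world <- B_EARTH +
    .surface_mag_offset(surface, config$mag_surface_shift %||% 0)

  data <- list()
  for (s in sensor_levels()) {
    gain <- config$site_gain[[s]] * profile$site_amp[[s]]
    # site-specific phase offsets so left/right limbs are out of phase
    ph <- switch(s, shankL = pi, thighL = pi, 0)

    # oscillation amplitudes (radians) at unit gain
    amp_pitch <- 8 * deg * eff$vertical_amp_factor
    amp_roll <- 3 * deg
    amp_yaw <- 2 * deg

    jit_sd <- eff$jitter_sd * deg * gain
    yaw <- profile$yaw0 +
      gain * amp_yaw * sin(2 * pi * f * t + ph + 1.0) +
      stats::rnorm(n, 0, jit_sd)
    pitch <- gain * eff$pitch_deg * deg +
      gain * amp_pitch * sin(2 * pi * f * t + ph) +
      stats::rnorm(n, 0, jit_sd)
    roll <- gain * eff$roll_deg * deg +
      gain * amp_roll * sin(2 * pi * f * t + ph + 0.5) +
      stats::rnorm(n, 0, jit_sd)
    if (s == "wrist") {
      # idiosyncratic arm swing: strong, but carries no surface signal
      swing <- profile$armswing_amp * 20 * deg *
        sin(2 * pi * profile$cadence_hz * t + profile$armswing_phase)
      pitch <- pitch + swing
    }

    # gyroscope: analytic derivative of the oscillatory orientation
    # component (rad/s), mapped to body axes (X=roll, Y=pitch, Z=yaw
    # rate under the small-angle approximation), plus white noise
    w <- 2 * pi * f
    gyr_x <- gain * amp_roll * w * cos(2 * pi * f * t + ph + 0.5)
    gyr_y <- gain * amp_pitch * w * cos(2 * pi * f * t + ph)
    if (s == "wrist") {
      ws <- 2 * pi * profile$cadence_hz
      gyr_y <- gyr_y + profile$armswing_amp * 20 * deg * ws *
        cos(2 * pi * profile$cadence_hz * t + profile$armswing_phase)
    }
    gyr_z <- gain * amp_yaw * w * cos(2 * pi * f * t + ph + 1.0)
    gyr <- cbind(gyr_x, gyr_y, gyr_z) +
      matrix(stats::rnorm(3 * n, 0, config$noise_sd$Gyr), n, 3)

    # gravity and Earth-field projections into the body frame
    grav <- .world_to_body(yaw, pitch, roll, c(0, 0, -GRAVITY_MS2))
    mag <- .world_to_body(yaw, pitch, roll, b_world) +
      matrix(stats::rnorm(3 * n, 0, config$noise_sd$Mag), n, 3)

    # gait motion component: vertical bounce at double the stride
    # frequency plus a fore-aft component at the stride frequency
    amp_motion <- 2.0 * gain * eff$vertical_amp_factor
    motion <- cbind(
      0.4 * amp_motion * sin(2 * pi * f * t + ph + 0.7),
      0.15 * amp_motion * sin(2 * pi * f * t + ph + 2.1),
      amp_motion * sin(2 * pi * 2 * f * t + 2 * ph))
    acc <- grav + motion +
      matrix(stats::rnorm(3 * n, 0, config$noise_sd$Acc), n, 3)

    free_acc <- acc - grav                  # exact by construction
    vel_inc <- acc / fs                     # exact by construction
    ori_inc <- .rotvec_quaternion(gyr[, 1], gyr[, 2], gyr[, 3], 1 / fs)
    ypr <- cbind(yaw, pitch, roll) / deg    # degrees

    m <- cbind(acc, free_acc, gyr, mag, vel_inc, ori_inc, ypr)
    colnames(m) <- channel_names()
    data[[s]] <- m
  }
  gait_trial(profile$participant_id, surface, trial_index, data,
             sample_rate = fs)
}

#' Simulate a full cohort
#'
#' Generates `n_participants x 9 surfaces x trials_per_condition`
#' labeled trials with durations drawn from the configured truncated
#' normal, then marks the configured number of trials as having a fully
#' missing sensor recording. Fully deterministic for a fixed
#' `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A [gait_dataset()] with `provenance = "synthetic"`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  profiles <- lapply(seq_len(config$n_participants), participant_profile)
  trials <- vector("list",
                   config$n_participants * 9 * config$trials_per_condition)
  i <- 0L
  for (p in profiles) {
    for (surf in surface_levels()) {
      for (k in seq_len(config$trials_per_condition)) {
        dur <- max(config$duration_min_s,
                   stats::rnorm(1, config$duration_mean_s, config$duration_sd_s))
        i <- i + 1L
        trials[[i]] <- simulate_trial(p, surf, dur, config, trial_index = k)
      }
    }
  }
  ds <- gait_dataset(trials, provenance = "synthetic")
  if (config$missing_sensor_trials > 0)
    ds <- inject_missing(ds, config$missing_sensor,
                         min(config$missing_sensor_trials, length(trials)))
  ds
}

#' Mark a sensor's recording as fully missing in random trials
#'
#' Emulates recording failures in which one sensor produced no usable
#' data for an entire trial: the chosen trials keep the sensor entry but
#' every value becomes `NA`.
#'
#' @param dataset A [gait_dataset()].
#' @param sensor Sensor site code.
#' @param n_trials Number of trials to affect (chosen uniformly at
#'   random from the current RNG stream).
#' @return The modified dataset.
#' @export
inject_missing <- function(dataset, sensor, n_trials) {
  if (!sensor %in% sensor_levels())
    stop("inject_missing: unknown sensor: ", sensor)
  n_trials <- as.integer(n_trials)
  if (n_trials > length(dataset$trials))
    stop("inject_missing: n_trials exceeds dataset size")
  if (n_trials == 0L) return(dataset)
  hit <- sample(length(dataset$trials), n_trials)
  for (i in hit) {
    tr <- dataset$trials[[i]]
    if (sensor %in% names(tr$data))
      dataset$trials[[i]]$data[[sensor]][] <- NA_real_
  }
  dataset
}
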