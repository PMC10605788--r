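# Independent body-frame reading of a world vector under intrinsic
# Z-Y-X angles, used to cross-check simulator outputs.
rotate_to_body <- function(yaw_deg, pitch_deg, roll_deg, v) {
  d <- pi / 180
  t(vapply(seq_along(yaw_deg), function(i) {
    cy <- cos(yaw_deg[i] * d); sy <- sin(yaw_deg[i] * d)
    cp <- cos(pitch_deg[i] * d); sp <- sin(pitch_deg[i] * d)
    cr <- cos(roll_deg[i] * d); sr <- sin(roll_deg[i] * d)
    Rz <- matrix(c(cy, sy, 0, -sy, cy, 0, 0, 0, 1), 3, 3)
    Ry <- matrix(c(cp, 0, -sp, 0, 1, 0, sp, 0, cp), 3, 3)
    Rx <- matrix(c(1, 0, 0, 0, cr, sr, 0, -sr, cr), 3, 3)
    as.numeric(t(Rz %*% Ry %*% Rx) %*% v)
  }, numeric(3)))
}

quiet_effects <- function() {
  eff <- default_surface_effects()
  eff$jitter_sd <- 0
  eff
}

test_that("strap-down identities hold exactly in noise-free trials", {
  cfg <- quiet_config()
  cfg$surface_effects <- quiet_effects()
  set.seed(11)
  p <- participant_profile(1)
  tr <- simulate_trial(p, "GR", 6, cfg)
  for (s in c("shankR", "wrist")) {
    m <- tr$data[[s]]
    acc <- m[, c("Acc_X", "Acc_Y", "Acc_Z")]
    # velocity increment is the acceleration over the sample rate
    expect_equal(m[, c("VelInc_X", "VelInc_Y", "VelInc_Z")], acc / 100,
                 ignore_attr = TRUE)
    # Acc - FreeAcc is gravity read in the body frame: unit direction
    # given by the Euler channels, magnitude 9.81 everywhere
    grav <- acc - m[, c("FreeAcc_X", "FreeAcc_Y", "FreeAcc_Z")]
    expect_equal(sqrt(rowSums(grav^2)), rep(9.81, nrow(m)),
                 tolerance = 1e-10, ignore_attr = TRUE)
    gref <- rotate_to_body(m[, "Yaw"], m[, "Pitch"], m[, "Roll"],
                           c(0, 0, -9.81))
    expect_equal(grav, gref, tolerance = 1e-8, ignore_attr = TRUE)
    # magnetometer is the Earth field read through the same rotation
    mref <- rotate_to_body(m[, "Yaw"], m[, "Pitch"], m[, "Roll"],
                           c(0.4, 0, -0.6))
    expect_equal(m[, c("Mag_X", "Mag_Y", "Mag_Z")], mref,
                 tolerance = 1e-8, ignore_attr = TRUE)
    # orientation-increment quaternions are unit norm
    q <- m[, c("OriInc_q0", "OriInc_q1", "OriInc_q2", "OriInc_q3")]
    expect_equal(rowSums(q^2), rep(1, nrow(m)), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("slope surfaces shift the pitch baseline by the configured tilt", {
  cfg <- quiet_config()
  cfg$surface_effects <- quiet_effects()
  set.seed(13)
  p <- participant_profile(1)
  up <- simulate_trial(p, "SlpU", 6, cfg)
  dn <- simulate_trial(p, "SlpD", 6, cfg)
  # oscillation terms are identical for the two slopes and cancel in the
  # difference of means; what remains is the +10 / -10 degree baseline
  # scaled by the site gain
  for (s in sensor_levels()) {
    gain <- cfg$site_gain[[s]] * p$site_amp[[s]]
    expect_equal(mean(up$data[[s]][, "Pitch"]) - mean(dn$data[[s]][, "Pitch"]),
                 20 * gain, tolerance = 1e-10)
  }
  # the wrist barely expresses the surface; the shank expresses it fully
  gw <- cfg$site_gain[["wrist"]]; gs <- cfg$site_gain[["shankR"]]
  expect_lt(gw / gs, 0.1)
})

test_that("banked surfaces tilt roll symmetrically", {
  cfg <- quiet_config()
  cfg$surface_effects <- quiet_effects()
  set.seed(17)
  p <- participant_profile(1)
  l <- simulate_trial(p, "BnkL", 6, cfg)
  r <- simulate_trial(p, "BnkR", 6, cfg)
  gain <- cfg$site_gain[["trunk"]] * p$site_amp[["trunk"]]
  expect_equal(mean(r$data$trunk[, "Roll"]) - mean(l$data$trunk[, "Roll"]),
               16 * gain, tolerance = 1e-10)
})

test_that("stride frequency is recoverable from the shank pitch spectrum", {
  cfg <- quiet_config()
  cfg$surface_effects <- quiet_effects()
  set.seed(19)
  p <- participant_profile(1)
  tr <- simulate_trial(p, "FE", 8, cfg)
  x <- tr$data$shankR[, "Pitch"]
  x <- x - mean(x)
  n <- length(x)
  spec <- Mod(stats::fft(x))[2:(n %/% 2)]
  f_hat <- which.max(spec) / (n / 100)  # Hz
  expect_lt(abs(f_hat - p$cadence_hz), 100 / n + 1e-9)  # within one bin
  # stairs slow the cadence by the configured factor
  st <- simulate_trial(p, "StrU", 8, cfg)
  y <- st$data$shankR[, "Pitch"]; y <- y - mean(y)
  spec2 <- Mod(stats::fft(y))[2:(n %/% 2)]
  f_st <- which.max(spec2) / (n / 100)
  expect_lt(abs(f_st - 0.7 * p$cadence_hz), 100 / n + 1e-9)
})

test_that("cohorts have the designed size and are seed-deterministic", {
  ds <- tiny_cohort()
  expect_length(ds, 2 * 9 * 2)
  keys <- trial_keys(ds)
  expect_identical(sort(unique(keys$surface)), sort(surface_levels()))
  expect_true(all(table(keys$participant_id, keys$surface) == 2))
  # three trials carry the injected fully-missing left-thigh recording
  expect_equal(sum(!keys$thighL), 3)
  expect_true(all(keys$shankR))
  # same seed, same cohort, bit for bit
  cfg <- sim_config(n_participants = 1, trials_per_condition = 1,
                    missing_sensor_trials = 0, seed = 77)
  a <- simulate_cohort(cfg); b <- simulate_cohort(cfg)
  expect_identical(a$trials[[5]]$data, b$trials[[5]]$data)
  expect_identical(trial_keys(a), trial_keys(b))
})

test_that("inject_missing blanks whole recordings and validates inputs", {
  cfg <- sim_config(n_participants = 1, trials_per_condition = 1,
                    missing_sensor_trials = 0, seed = 5)
  ds <- simulate_cohort(cfg)
  set.seed(1)
  ds2 <- inject_missing(ds, "trunk", 4)
  keys <- trial_keys(ds2)
  expect_equal(sum(!keys$trunk), 4)
  expect_error(inject_missing(ds, "head", 1), "unknown sensor")
  expect_error(inject_missing(ds, "trunk", 99), "exceeds dataset size")
  expect_identical(inject_missing(ds, "trunk", 0), ds)
})

test_that("a magnetic surface shift moves only the magnetometer", {
  eff <- quiet_effects()
  for (col in c("pitch_deg", "roll_deg", "cadence_factor",
                "vertical_amp_factor", "jitter_sd"))
    eff[[col]] <- eff[[col]][1]  # every surface kinematically identical
  cfg <- quiet_config()
  cfg$surface_effects <- eff
  cfg$mag_surface_shift <- 0.5
  set.seed(23)
  p <- participant_profile(1)
  set.seed(31); fe <- simulate_trial(p, "FE", 6, cfg)
  set.seed(31); cs <- simulate_trial(p, "CS", 6, cfg)
  mag_cols <- c("Mag_X", "Mag_Y", "Mag_Z")
  other <- setdiff(channel_names(), mag_cols)
  expect_identical(fe$data$trunk[, other], cs$data$trunk[, other])
  expect_gt(mean(abs(fe$data$trunk[, mag_cols] - cs$data$trunk[, mag_cols])),
            0.05)
  # the default configuration applies no shift
  expect_equal(sim_config()$mag_surface_shift, 0)
})
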