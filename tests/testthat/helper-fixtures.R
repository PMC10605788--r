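# Shared fixtures, cached per test run so expensive simulation and
# preprocessing happen once.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- make()
  .fixture_cache[[name]]
}

# small cohort: 2 participants x 9 surfaces x 2 trials, 6 s each,
# 3 trials with a fully missing left-thigh recording
tiny_cohort <- function() fixture("tiny_cohort", function() {
  simulate_cohort(sim_config(
    n_participants = 2, trials_per_condition = 2,
    duration_mean_s = 6, duration_sd_s = 0,
    missing_sensor_trials = 3, seed = 42))
})

# the same cohort, conditioned (smoothed + repaired)
tiny_cohort_pre <- function() fixture("tiny_cohort_pre", function() {
  preprocess_dataset(tiny_cohort())
})

# one noise-free participant profile + config for identity checks
quiet_config <- function() {
  sim_config(n_participants = 1, trials_per_condition = 1,
             noise_sd = list(Acc = 0, Gyr = 0, Mag = 0),
             missing_sensor_trials = 0, seed = 9)
}

# mock selection evaluator scoring candidates from a fixed schedule
# keyed on "sorted groups|sorted sensors"; records every call
mock_evaluator <- function(schedule) {
  calls <- new.env(parent = emptyenv())
  calls$n <- 0L
  calls$keys <- character()
  f <- function(groups, sensors, window_length) {
    k <- paste(paste(sort(groups), collapse = "+"),
               paste(sort(sensors), collapse = "+"), sep = "|")
    calls$n <- calls$n + 1L
    calls$keys <- c(calls$keys, k)
    if (!k %in% names(schedule))
      stop("mock_evaluator: unscheduled candidate ", k)
    v <- schedule[[k]]
    if (is.numeric(v) && length(v) == 1L) list(accuracy = v) else v
  }
  attr(f, "calls") <- calls
  f
}

# accuracy schedule reproducing a reference signal-group search:
# singles, then each growth round; unreported rivals score below the
# round winner. Full precision distinguishes the two 0.955-rounded rows.
signal_schedule <- function(sensors = "shankR") {
  sk <- paste(sort(sensors), collapse = "+")
  key <- function(groups) paste(paste(sort(groups), collapse = "+"), sk,
                                sep = "|")
  sched <- list()
  put <- function(groups, acc) sched[[key(groups)]] <<- acc
  # round 1: singles
  put("Acc", 0.803); put("FreeAcc", 0.869); put("Gyr", 0.694)
  put("Mag", 0.923); put("VelInc", 0.784); put("Ori", 0.629)
  put("YPR", 0.810)
  # round 2: Mag + g
  put(c("Mag", "FreeAcc"), 0.9551)
  put(c("Mag", "Acc"), 0.941); put(c("Mag", "Gyr"), 0.930)
  put(c("Mag", "VelInc"), 0.938); put(c("Mag", "Ori"), 0.925)
  put(c("Mag", "YPR"), 0.944)
  # round 3: {Mag, FreeAcc} + g
  put(c("Mag", "FreeAcc", "YPR"), 0.9554)
  put(c("Mag", "FreeAcc", "Acc"), 0.951)
  put(c("Mag", "FreeAcc", "Gyr"), 0.948)
  put(c("Mag", "FreeAcc", "VelInc"), 0.950)
  put(c("Mag", "FreeAcc", "Ori"), 0.946)
  # round 4
  put(c("Mag", "FreeAcc", "YPR", "Acc"), 0.956)
  put(c("Mag", "FreeAcc", "YPR", "Gyr"), 0.952)
  put(c("Mag", "FreeAcc", "YPR", "VelInc"), 0.953)
  put(c("Mag", "FreeAcc", "YPR", "Ori"), 0.950)
  # round 5
  put(c("Mag", "FreeAcc", "YPR", "Acc", "VelInc"), 0.961)
  put(c("Mag", "FreeAcc", "YPR", "Acc", "Gyr"), 0.957)
  put(c("Mag", "FreeAcc", "YPR", "Acc", "Ori"), 0.955)
  # round 6: no strict improvement over 0.961 -> stop
  put(c("Mag", "FreeAcc", "YPR", "Acc", "VelInc", "Gyr"), 0.960)
  put(c("Mag", "FreeAcc", "YPR", "Acc", "VelInc", "Ori"), 0.960)
  sched
}

# accuracy schedule reproducing a reference sensor-placement search
sensor_schedule <- function(groups = names(signal_groups())) {
  gk <- paste(sort(groups), collapse = "+")
  key <- function(sensors) paste(gk, paste(sort(sensors), collapse = "+"),
                                 sep = "|")
  sched <- list()
  put <- function(sensors, acc) sched[[key(sensors)]] <<- acc
  # singles (the two shanks tie; canonical rank orders shankR first)
  put("wrist", 0.760); put("thighR", 0.881); put("thighL", 0.865)
  put("shankR", 0.935); put("shankL", 0.935); put("trunk", 0.883)
  # walk down the ranking shankR, shankL, trunk, thighR, thighL, wrist
  put(c("shankR", "shankL"), 0.961)
  put(c("shankR", "shankL", "trunk"), 0.968)
  put(c("shankR", "shankL", "trunk", "thighR"), 0.969)
  put(c("shankR", "shankL", "trunk", "thighR", "thighL"), 0.965)  # reject
  put(c("shankR", "shankL", "trunk", "thighR", "wrist"), 0.969)   # tie: reject
  # full-complement check over the two rejected sensors
  put(sensor_levels(), 0.966)                                     # reject
  sched
}
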