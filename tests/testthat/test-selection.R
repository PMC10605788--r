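test_that("signal-group search replays the reference schedule in 27 evaluations", {
  ev <- mock_evaluator(signal_schedule())
  res <- greedy_signal_selection(sensors = "shankR", window_length = 400,
                                 evaluator = ev)
  expect_identical(res$selected, c("Mag", "FreeAcc", "YPR", "Acc", "VelInc"))
  expect_equal(res$best_accuracy, 0.961)
  # 7 + 6 + 5 + 4 + 3 + 2 scored configurations
  expect_equal(attr(ev, "calls")$n, 27)
  expect_equal(nrow(res$records), 27)
  # the trace records one accepted candidate per growth round and a
  # final rejected round
  accepted <- vapply(res$trace, function(r) !is.na(r$accepted), logical(1))
  expect_identical(accepted, c(rep(TRUE, 5), FALSE))
})

test_that("signal-group search stops after round one when nothing helps", {
  # singles as in the reference schedule, but every growth candidate scores poorly
  sched2 <- list()
  gk <- function(groups) paste(paste(sort(groups), collapse = "+"),
                               "shankR", sep = "|")
  for (g in names(signal_groups())) sched2[[gk(g)]] <- signal_schedule()[[gk(g)]]
  for (g in setdiff(names(signal_groups()), "Mag"))
    sched2[[gk(c("Mag", g))]] <- 0.5
  ev <- mock_evaluator(sched2)
  res <- greedy_signal_selection(sensors = "shankR", window_length = 400,
                                 evaluator = ev)
  expect_identical(res$selected, "Mag")
  # 7 singles + 6 failed growth candidates
  expect_equal(attr(ev, "calls")$n, 13)
})

test_that("an exact accuracy tie rejects the larger configuration", {
  gk <- function(groups) paste(paste(sort(groups), collapse = "+"),
                               "trunk", sep = "|")
  sched <- list()
  sched[[gk("Acc")]] <- 0.8
  sched[[gk("Gyr")]] <- 0.7
  sched[[gk(c("Acc", "Gyr"))]] <- 0.8  # tie with current best
  ev <- mock_evaluator(sched)
  res <- greedy_signal_selection(sensors = "trunk", window_length = 100,
                                 evaluator = ev, groups = c("Acc", "Gyr"))
  expect_identical(res$selected, "Acc")
  expect_equal(res$best_accuracy, 0.8)
})

test_that("max_rounds = 1 scores only the singles round", {
  ev <- mock_evaluator(signal_schedule())
  res <- greedy_signal_selection(sensors = "shankR", window_length = 400,
                                 evaluator = ev, max_rounds = 1)
  expect_identical(res$selected, "Mag")
  expect_equal(attr(ev, "calls")$n, 7)
})

test_that("sensor search replays the reference schedule in 12 evaluations", {
  ev <- mock_evaluator(sensor_schedule())
  res <- greedy_sensor_selection(groups = names(signal_groups()),
                                 window_length = 400, evaluator = ev)
  # final set in canonical site order
  expect_identical(res$selected, c("thighR", "shankR", "shankL", "trunk"))
  expect_equal(res$best_accuracy, 0.969)
  # 6 singles + 5 ranked additions + 1 full-complement check
  expect_equal(attr(ev, "calls")$n, 12)
  expect_equal(nrow(res$records), 12)
  # the tied shanks rank by canonical site order
  expect_identical(res$ranking[1:2], c("shankR", "shankL"))
  expect_identical(res$ranking[3], "trunk")
})

test_that("sensor search skips the full-complement check for one rejection", {
  gk <- function(sensors) paste(paste(sort(names(signal_groups())),
                                      collapse = "+"),
                                paste(sort(sensors), collapse = "+"),
                                sep = "|")
  sched <- list()
  pool <- c("shankR", "shankL", "trunk")
  sched[[gk("shankR")]] <- 0.9
  sched[[gk("shankL")]] <- 0.85
  sched[[gk("trunk")]] <- 0.8
  sched[[gk(c("shankR", "shankL"))]] <- 0.93
  sched[[gk(c("shankR", "shankL", "trunk"))]] <- 0.92  # the one rejection
  ev <- mock_evaluator(sched)
  res <- greedy_sensor_selection(groups = names(signal_groups()),
                                 window_length = 100, evaluator = ev,
                                 sensors = pool)
  expect_identical(res$selected, c("shankR", "shankL"))
  # re-scoring {current + trunk} would duplicate the rejected candidate
  expect_equal(attr(ev, "calls")$n, 5)
})

test_that("window_sweep scores each length and keeps class counts", {
  key <- function(L) paste(paste(sort(c("Mag", "Acc")), collapse = "+"),
                           "shankR", sep = "|")
  counts <- stats::setNames(rep(10L, 9), surface_levels())
  ev <- function(groups, sensors, window_length) {
    list(accuracy = 0.9 - window_length / 1e4, precision = 0.9,
         recall = 0.9, f1 = 0.9, n_segments = 90,
         class_counts = counts)
  }
  res <- window_sweep(groups = c("Mag", "Acc"), sensors = "shankR",
                      lengths = c(100, 300), evaluator = ev)
  expect_equal(nrow(res$records), 2)
  expect_identical(res$records$L, c(100, 300))
  expect_equal(dim(res$class_counts), c(2L, 9L))
})

test_that("selection evaluators score real data end to end", {
  ds <- tiny_cohort()
  cfg <- train_config(epochs = 2, patience_stop = 2, patience_lr = 1, seed = 8)
  ev <- make_holdout_evaluator(ds, config = cfg, n_folds = 3)
  res <- ev("Acc", "shankR", 300)
  expect_true(is.finite(res$accuracy))
  expect_gte(res$accuracy, 0)
  expect_lte(res$accuracy, 1)
  expect_equal(sum(res$class_counts), res$n_segments)
  expect_equal(res$recall, res$accuracy)  # weighted recall identity
})

test_that("experiment records are written with the report headers", {
  rec <- data.frame(signal_groups = "Mag", sensors = "shankR", L = 400,
                    PR = 0.92, RE = 0.92, F1 = 0.92, ACC = 0.92)
  path <- tempfile(fileext = ".csv")
  write_experiment_records(rec, path)
  out <- utils::read.csv(path, check.names = FALSE)
  expect_identical(names(out),
                   c("Signal Group(s)", "Sensor Location(s)", "L",
                     "PR", "RE", "F1", "ACC"))
  expect_equal(out$ACC, 0.92)
  unlink(path)
})
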