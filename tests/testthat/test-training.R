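# tiny, linearly separable segment set: class ordinal encoded in the
# channel means, plus small noise
separable_set <- function(n_per_class = 8, L = 9, C = 2, classes = 0:2,
                          seed = 1) {
  set.seed(seed)
  n <- n_per_class * length(classes)
  x <- array(rnorm(L * C * n, sd = 0.1), c(L, C, n))
  label <- rep(classes, each = n_per_class)
  for (i in seq_len(n)) x[, 1, i] <- x[, 1, i] + 2 * label[i]
  prov <- data.frame(participant_id = rep(seq_len(n), 1),
                     surface = surface_levels()[label + 1],
                     trial_index = seq_len(n),  # all distinct trials
                     window_ordinal = 0)
  segment_set(x, label, prov, channel_layout("Acc", "trunk")[seq_len(C), ])
}

test_that("train_config validates the schedule relation", {
  tc <- train_config()
  expect_equal(tc$epochs, 100)
  expect_equal(tc$batch_size, 32)
  expect_equal(tc$learning_rate, 0.001)
  expect_equal(tc$patience_stop, 25)
  expect_equal(tc$patience_lr, 10)
  expect_error(train_config(patience_stop = 5, patience_lr = 5),
               "smaller than")
})

test_that("fold plan partitions trials one-per-pair per fold", {
  ds <- tiny_cohort()  # 2 trials per (participant, surface) pair
  plan <- make_fold_plan(ds, seed = 3, n_folds = 2)
  expect_s3_class(plan, "fold_plan")
  expect_equal(nrow(plan), length(ds))
  agg <- table(paste(plan$participant_id, plan$surface), plan$fold)
  expect_true(all(agg == 1))
  # deterministic under seed, different under another seed
  expect_identical(plan, make_fold_plan(ds, seed = 3, n_folds = 2))
  plan2 <- make_fold_plan(ds, seed = 4, n_folds = 2)
  expect_false(identical(plan$fold, plan2$fold))
  # works from a bare key table too
  keys <- trial_keys(ds)[c("participant_id", "surface", "trial_index")]
  expect_identical(make_fold_plan(keys, seed = 3, n_folds = 2)$fold,
                   plan$fold)
})

test_that("fold plan spreads fewer-than-n_folds trials without collision", {
  keys <- expand.grid(participant_id = 1:4, surface = surface_levels(),
                      trial_index = 1:3, stringsAsFactors = FALSE)
  plan <- make_fold_plan(keys, seed = 1, n_folds = 6)
  agg <- table(paste(plan$participant_id, plan$surface), plan$fold)
  # 3 trials per pair over 6 folds: never two in one fold
  expect_true(all(agg <= 1))
  expect_true(all(rowSums(agg) == 3))
})

test_that("training refuses trial leakage between train and validation", {
  s <- separable_set()
  model <- build_surface_cnn(9, 2, n_classes = 3, seed = 1)
  expect_error(train_one_fold(model, s, s, train_config(epochs = 1)),
               "leakage")
})

test_that("early stopping, LR schedule and best-weight restore behave", {
  # enough optimizer steps for the batch-norm running statistics to
  # converge before early stopping can trigger
  s <- separable_set(n_per_class = 40)
  tr <- subset_segments(s, which(seq_len(n_segments(s)) %% 3 != 0))
  va <- subset_segments(s, which(seq_len(n_segments(s)) %% 3 == 0))
  model <- build_surface_cnn(9, 2, n_classes = 3, seed = 2)
  cfg <- train_config(epochs = 100, batch_size = 8, patience_stop = 40,
                      patience_lr = 20, seed = 2)
  set.seed(cfg$seed)
  fit <- train_one_fold(model, tr, va, cfg)
  h <- fit$history
  # separable data: the network learns it
  expect_gte(max(h$val_accuracy), 0.9)
  expect_true(fit$model$trained)
  # stop no later than best_epoch + patience, never past the cap
  expect_lte(nrow(h), 100)
  expect_lte(nrow(h), fit$best_epoch + cfg$patience_stop)
  expect_equal(h$val_accuracy[fit$best_epoch], fit$best_val)
  expect_equal(max(h$val_accuracy), fit$best_val)
  # learning rate never increases and respects the floor
  expect_true(all(diff(h$lr) <= 0))
  expect_true(all(h$lr >= train_config()$lr_floor))
  # restored weights reproduce the best epoch's validation accuracy
  acc_now <- mean(predict_class(fit$model, va) == va$label)
  expect_equal(acc_now, fit$best_val)
})

test_that("cross-validation predicts every segment once, without leakage", {
  ds <- tiny_cohort()
  cfg <- train_config(epochs = 2, patience_stop = 2, patience_lr = 1, seed = 6)
  cv <- cross_validate(ds, "Acc", "shankR", 300, config = cfg, n_folds = 3)
  s <- assemble_segments(preprocess_dataset(ds), "Acc", "shankR", 300)
  expect_equal(length(cv$truth), n_segments(s))
  # each segment appears exactly once in the aggregated predictions
  key <- function(p) paste(p$participant_id, p$surface, p$trial_index,
                           p$window_ordinal)
  expect_setequal(key(cv$provenance), key(s$provenance))
  expect_false(anyDuplicated(key(cv$provenance)) > 0)
  # a trial's segments never land in the fold trained on that trial
  for (f in cv$folds) {
    te_trials <- unique(with(cv$provenance[cv$provenance$fold == f$fold, ],
                             paste(participant_id, surface, trial_index)))
    plan_te <- with(cv$plan[cv$plan$fold == f$fold, ],
                    paste(participant_id, surface, trial_index))
    expect_true(all(te_trials %in% plan_te))
  }
  # per-rotation scalers are fitted on different training folds
  expect_false(identical(cv$folds[[1]]$scaler$min, cv$folds[[2]]$scaler$min))
  # aggregate weighted recall is the aggregate accuracy
  m <- cv_metrics(cv)
  expect_equal(m$recall, m$accuracy)
  expect_equal(m$recall, mean(cv$truth == cv$predicted))
  expect_equal(sum(m$confusion), length(cv$truth))
})
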