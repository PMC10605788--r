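# Wrapper selection harnesses: greedy signal-group selection, greedy
# sensor-placement selection, and the window-length sweep. Each
# candidate configuration is scored by an injectable evaluator (by
# default, full cross-validation plus weighted metrics), so the search
# logic can be verified against mock accuracy schedules.

#' Build the default cross-validation evaluator
#'
#' Preprocesses the dataset once and fixes a single fold plan and seed,
#' so every candidate configuration is scored under identical
#' conditions and differences reflect the configuration only.
#'
#' @param dataset A [gait_dataset()].
#' @param config A [train_config()].
#' @param plan Optional [make_fold_plan()]; defaults to one derived
#'   from `config$seed`.
#' @param n_folds Number of folds.
#' @param preprocess Condition the dataset first (set `FALSE` when it
#'   is already conditioned).
#' @param verbose Print per-fold progress.
#' @return Function `(groups, sensors, window_length)` returning a list
#'   with `accuracy`, `precision`, `recall`, `f1`, `n_segments` and
#'   `class_counts`.
#' @export
make_cv_evaluator <- function(dataset, config = train_config(), plan = NULL,
                              n_folds = 6, preprocess = TRUE,
                              verbose = FALSE) {
  if (preprocess) dataset <- preprocess_dataset(dataset)
  if (is.null(plan)) plan <- make_fold_plan(dataset, seed = config$seed,
                                            n_folds = n_folds)
  function(groups, sensors, window_length) {
    cv <- cross_validate(dataset, groups, sensors, window_length,
                         config = config, plan = plan, preprocess = FALSE,
                         n_folds = n_folds, verbose = verbose)
    m <- cv_metrics(cv)
    counts <- table(factor(cv$provenance$surface, levels = surface_levels()))
    list(accuracy = m$accuracy, precision = m$precision,
         recall = m$recall, f1 = m$f1,
         n_segments = length(cv$truth),
         class_counts = stats::setNames(as.integer(counts), surface_levels()),
         cv = cv)
  }
}

#' Build a single-rotation holdout evaluator
#'
#' A cheaper alternative to [make_cv_evaluator()] for screening runs:
#' instead of all fold rotations, each candidate is scored once on a
#' fixed train/validation/test split (test fold `test_fold`, validation
#' fold `(test_fold %% n_folds) + 1`, remaining folds train). The split,
#' the preprocessed dataset and the seed are shared across candidates so
#' comparisons stay paired.
#'
#' @inheritParams make_cv_evaluator
#' @param test_fold Which fold serves as the held-out test set.
#' @return Function `(groups, sensors, window_length)` with the same
#'   return shape as [make_cv_evaluator()]'s evaluator.
#' @export
make_holdout_evaluator <- function(dataset, config = train_config(),
                                   plan = NULL, test_fold = 1, n_folds = 6,
                                   preprocess = TRUE, verbose = FALSE) {
  if (preprocess) dataset <- preprocess_dataset(dataset)
  if (is.null(plan)) plan <- make_fold_plan(dataset, seed = config$seed,
                                            n_folds = n_folds)
  val_fold <- (test_fold %% n_folds) + 1L
  function(groups, sensors, window_length) {
    set <- assemble_segments(dataset, groups, sensors, window_length)
    fold <- .segment_folds(set, plan)
    te <- which(fold == test_fold)
    va <- which(fold == val_fold)
    tr <- which(!fold %in% c(test_fold, val_fold))
    if (!length(te) || !length(va) || !length(tr))
      stop("make_holdout_evaluator: empty subset in holdout split")
    scaler <- fit_scaler(subset_segments(set, tr))
    s_tr <- apply_scaler(scaler, subset_segments(set, tr))
    s_va <- apply_scaler(scaler, subset_segments(set, va))
    s_te <- apply_scaler(scaler, subset_segments(set, te))
    set.seed(config$seed * 1000L + test_fold)
    model <- build_surface_cnn(window_length, nrow(set$layout),
                               bn_momentum = config$bn_momentum %||% 0.99)
    fit <- train_one_fold(model, s_tr, s_va, config, verbose = verbose)
    p <- predict_class(fit$model, s_te)
    cm <- confusion(set$label[te], p, n_classes = 9)
    m <- weighted_metrics(cm)
    counts <- table(factor(set$provenance$surface[te],
                           levels = surface_levels()))
    list(accuracy = m$accuracy, precision = m$precision,
         recall = m$recall, f1 = m$f1,
         n_segments = length(te),
         class_counts = stats::setNames(as.integer(counts),
                                        surface_levels()))
  }
}

.eval_candidate <- function(evaluator, groups, sensors, window_length) {
  res <- tryCatch(evaluator(groups, sensors, window_length),
                  error = function(e) {
                    warning("candidate {", paste(groups, collapse = ","),
                            "} x {", paste(sensors, collapse = ","),
                            "} skipped: ", conditionMessage(e))
                    NULL
                  })
  if (is.null(res)) return(NULL)
  if (is.numeric(res)) res <- list(accuracy = res)
  res
}

.record_row <- function(groups, sensors, window_length, res) {
  data.frame(signal_groups = paste(groups, collapse = ", "),
             sensors = paste(sensors, collapse = ", "),
             L = window_length,
             PR = res$precision %||% NA_real_,
             RE = res$recall %||% NA_real_,
             F1 = res$f1 %||% NA_real_,
             ACC = res$accuracy,
             stringsAsFactors = FALSE)
}

.check_trace_monotone <- function(path_acc) {
  if (length(path_acc) > 1 && any(diff(path_acc) <= 0))
    stop("selection trace violated strict improvement along accepted path")
}

#' Greedy forward selection of signal groups
#'
#' Sequential forward wrapper search at fixed sensors and window
#' length: the first round scores every group alone and keeps the best;
#' each later round scores the current set augmented by each remaining
#' group and accepts the best candidate only if it strictly improves
#' the cross-validated accuracy, stopping otherwise. Accuracy
#' comparisons use full floating precision; an exact tie rejects the
#' addition (smaller configurations win).
#'
#' @param dataset A [gait_dataset()] (ignored when `evaluator` is
#'   supplied).
#' @param sensors Fixed sensor configuration.
#' @param window_length Fixed window length.
#' @param evaluator Scoring function, see [make_cv_evaluator()]; built
#'   from `dataset` and `config` when `NULL`.
#' @param groups Candidate pool (default: all 7 groups).
#' @param config Used only to build the default evaluator.
#' @param max_rounds Optional cap on the number of accepted rounds
#'   (e.g. 1 to score the single-group round only).
#' @return List with `selected` (the chosen groups, in acceptance
#'   order), `trace` (per-round candidates, accuracies and decision)
#'   and `records` (one row per evaluated configuration).
#' @export
greedy_signal_selection <- function(dataset = NULL, sensors, window_length,
                                    evaluator = NULL,
                                    groups = names(signal_groups()),
                                    config = train_config(),
                                    max_rounds = Inf) {
  if (is.null(evaluator)) evaluator <- make_cv_evaluator(dataset, config)
  records <- list(); trace <- list()
  selected <- character(0); best_acc <- -Inf
  remaining <- groups
  round <- 0L
  repeat {
    round <- round + 1L
    if (round > max_rounds || length(remaining) == 0L) break
    cand <- lapply(remaining, function(g) c(selected, g))
    accs <- rep(NA_real_, length(cand))
    for (i in seq_along(cand)) {
      res <- .eval_candidate(evaluator, cand[[i]], sensors, window_length)
      if (is.null(res)) next
      accs[i] <- res$accuracy
      records[[length(records) + 1L]] <-
        .record_row(cand[[i]], sensors, window_length, res)
    }
    if (all(is.na(accs))) break
    best_i <- which.max(accs)  # ties: earliest candidate in pool order
    accepted <- accs[best_i] > best_acc
    trace[[round]] <- list(candidates = cand, accuracy = accs,
                           accepted = if (accepted) best_i else NA_integer_)
    if (!accepted) break
    selected <- cand[[best_i]]
    best_acc <- accs[best_i]
    remaining <- setdiff(remaining, selected)
  }
  .check_trace_monotone(vapply(Filter(function(r) !is.na(r$accepted), trace),
                               function(r) r$accuracy[r$accepted], numeric(1)))
  list(selected = selected, best_accuracy = best_acc, trace = trace,
       records = do.call(rbind, records))
}

#' Greedy ranked selection of sensor placements
#'
#' Scores each sensor alone, ranks them by decreasing accuracy
#' (canonical site order breaks ties), then walks down the ranking,
#' keeping each added sensor only when it strictly improves accuracy.
#' After the full pass, if two or more sensors were rejected, the
#' current set augmented with all of them is scored once as a
#' full-complement check (kept only on strict improvement); with a
#' single rejected sensor that check would duplicate an already scored
#' candidate and is skipped.
#'
#' @inheritParams greedy_signal_selection
#' @param groups Fixed signal-group configuration.
#' @param sensors Candidate pool (default: all 6 sites).
#' @return List with `selected` (canonical site order), `ranking`,
#'   `trace` and `records`.
#' @export
greedy_sensor_selection <- function(dataset = NULL, groups, window_length,
                                    evaluator = NULL,
                                    sensors = sensor_levels(),
                                    config = train_config()) {
  if (is.null(evaluator)) evaluator <- make_cv_evaluator(dataset, config)
  records <- list(); trace <- list()
  singles <- rep(NA_real_, length(sensors))
  for (i in seq_along(sensors)) {
    res <- .eval_candidate(evaluator, groups, sensors[i], window_length)
    if (is.null(res)) next
    singles[i] <- res$accuracy
    records[[length(records) + 1L]] <-
      .record_row(groups, sensors[i], window_length, res)
  }
  # descending accuracy; canonical rank breaks ties deterministically
  ord <- order(-singles, match(sensors, sensor_levels()))
  ranked <- sensors[ord]
  trace[[1]] <- list(candidates = as.list(sensors), accuracy = singles,
                     accepted = ord[1])
  current <- ranked[1]
  best_acc <- singles[ord[1]]
  path_acc <- best_acc
  rejected <- character(0)
  for (s in ranked[-1]) {
    cand <- c(current, s)
    res <- .eval_candidate(evaluator, groups, cand, window_length)
    if (is.null(res)) { rejected <- c(rejected, s); next }
    records[[length(records) + 1L]] <-
      .record_row(groups, cand, window_length, res)
    accepted <- res$accuracy > best_acc
    trace[[length(trace) + 1L]] <- list(candidates = list(cand),
                                        accuracy = res$accuracy,
                                        accepted = if (accepted) 1L else NA_integer_)
    if (accepted) {
      current <- cand; best_acc <- res$accuracy
      path_acc <- c(path_acc, best_acc)
    } else rejected <- c(rejected, s)
  }
  if (length(rejected) >= 2) {
    cand <- c(current, rejected)
    res <- .eval_candidate(evaluator, groups, cand, window_length)
    if (!is.null(res)) {
      records[[length(records) + 1L]] <-
        .record_row(groups, cand, window_length, res)
      accepted <- res$accuracy > best_acc
      trace[[length(trace) + 1L]] <- list(candidates = list(cand),
                                          accuracy = res$accuracy,
                                          accepted = if (accepted) 1L else NA_integer_)
      if (accepted) {
        current <- cand; best_acc <- res$accuracy
        path_acc <- c(path_acc, best_acc)
      }
    }
  }
  .check_trace_monotone(path_acc)
  current <- sensor_levels()[sensor_levels() %in% current]
  list(selected = current, best_accuracy = best_acc,
       ranking = ranked, trace = trace, records = do.call(rbind, records))
}

#' Window-length sweep
#'
#' Scores one fixed signal/sensor configuration at each window length
#' and reports the per-class segment counts alongside.
#'
#' @inheritParams greedy_signal_selection
#' @param groups,sensors Fixed configuration.
#' @param lengths Window lengths to evaluate, in samples.
#' @return List with `records` (one row per length) and `class_counts`
#'   (matrix length x class of segment counts, when the evaluator
#'   reports them).
#' @export
window_sweep <- function(dataset = NULL, groups, sensors,
                         lengths = c(100, 200, 300, 400, 500),
                         evaluator = NULL, config = train_config()) {
  if (is.null(evaluator)) evaluator <- make_cv_evaluator(dataset, config)
  records <- list(); counts <- list()
  for (L in lengths) {
    res <- .eval_candidate(evaluator, groups, sensors, L)
    if (is.null(res)) next
    records[[length(records) + 1L]] <- .record_row(groups, sensors, L, res)
    if (!is.null(res$class_counts))
      counts[[as.character(L)]] <- res$class_counts
  }
  list(records = do.call(rbind, records),
       class_counts = if (length(counts)) do.call(rbind, counts) else NULL)
}

#' Write experiment records as a report table
#'
#' @param records data.frame of experiment records (from the selection
#'   harnesses).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_experiment_records <- function(records, path) {
  out <- records
  names(out) <- c("Signal Group(s)", "Sensor Location(s)", "L",
                  "PR", "RE", "F1", "ACC")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
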