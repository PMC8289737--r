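# Subject-level HC-vs-RBD classification from the metric vectors, with the
# same balanced 10-subject fold construction as staging. RBD is the
# positive class throughout.

#' Detection configuration
#'
#' @param combination `"D1_ecg"` (13 ECG metrics), `"E1_emg"` (7 EMG
#'   metrics) or `"D2_both"` (all 20).
#' @param n_trees number of trees.
#' @param mtry `NULL` for `floor(sqrt(M))`.
#' @param seed integer seed.
#' @param threshold fixed atonia-index threshold for the baseline
#'   classifier; `NULL` tunes it on training folds.
#' @return a `detection_config` list.
#' @export
detection_config <- function(combination = c("E1_emg", "D1_ecg", "D2_both"),
                             n_trees = 500, mtry = NULL, seed = 1,
                             threshold = NULL) {
  structure(list(combination = match.arg(combination), n_trees = n_trees,
                 mtry = mtry, seed = as.integer(seed), threshold = threshold),
            class = "detection_config")
}

detection_feature_names <- function(combination) {
  switch(combination,
         D1_ecg = ECG_METRIC_NAMES,
         E1_emg = EMG_METRIC_NAMES,
         D2_both = c(ECG_METRIC_NAMES, EMG_METRIC_NAMES),
         stop("unknown detection combination '", combination, "'"))
}

#' Train the RBD detection forest
#'
#' Sentinel (missing) metrics are median-imputed with training-set medians;
#' metric columns that are entirely missing are dropped with a warning.
#'
#' @param metrics subject metric tibble with `cohort` and metric columns.
#' @param cfg a [detection_config()].
#' @return an `rbd_detector`.
#' @export
train_detector <- function(metrics, cfg = detection_config()) {
  y <- factor(metrics$cohort, levels = c("HC", "RBD"))
  if (length(unique(y)) < 2) stop("training set contains a single class")
  fc <- intersect(detection_feature_names(cfg$combination), names(metrics))
  x <- metrics[fc]
  all_na <- vapply(x, function(col) all(!is.finite(col)), logical(1))
  if (any(all_na)) {
    warning("dropping all-missing metric column(s): ",
            paste(names(x)[all_na], collapse = ", "))
    x <- x[!all_na]
  }
  imp <- median_impute(x)
  mtry <- if (is.null(cfg$mtry)) max(1L, floor(sqrt(ncol(x)))) else cfg$mtry
  fit <- ranger::ranger(x = imp$data, y = y, num.trees = cfg$n_trees,
                        mtry = mtry, importance = "impurity",
                        seed = cfg$seed, num.threads = 1)
  structure(list(forest = fit, manifest = names(imp$data),
                 medians = imp$medians, config = cfg),
            class = "rbd_detector")
}

#' @export
print.rbd_detector <- function(x, ...) {
  cat(sprintf("<rbd_detector> %s: %d trees, %d metrics, OOB error %.3f\n",
              x$config$combination, x$forest$num.trees, length(x$manifest),
              x$forest$prediction.error))
  invisible(x)
}

#' Metric importance of a detection forest, tidied
#'
#' @param x an `rbd_detector`.
#' @param ... unused.
#' @return tibble with `metric` and `importance`, descending.
#' @export
tidy.rbd_detector <- function(x, ...) {
  imp <- x$forest$variable.importance
  tibble::tibble(metric = names(imp), importance = as.numeric(imp)) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}

#' @export
predict.rbd_detector <- function(object, newdata, ...) {
  x <- newdata[object$manifest]
  x <- median_impute(x, object$medians)$data
  stats::predict(object$forest, data = x, num.threads = 1)$predictions
}

binary_rates <- function(truth, pred) {
  tp <- sum(truth == "RBD" & pred == "RBD")
  tn <- sum(truth == "HC" & pred == "HC")
  fp <- sum(truth == "HC" & pred == "RBD")
  fn <- sum(truth == "RBD" & pred == "HC")
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  c(accuracy = (tp + tn) / length(truth),
    sensitivity = sens,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    f1 = if (!is.na(sens) && !is.na(prec) && sens + prec > 0)
      2 * sens * prec / (sens + prec) else NA_real_)
}

finish_detection_report <- function(fold_rates, per_subject, cfg, extra = list()) {
  fr <- dplyr::bind_rows(fold_rates)
  report <- tibble::tibble(
    metric = names(fr),
    mean = vapply(fr, mean, numeric(1), na.rm = TRUE),
    sd = vapply(fr, stats::sd, numeric(1), na.rm = TRUE))
  structure(c(list(report = report, per_subject = per_subject, config = cfg),
              extra),
            class = "detection_report")
}

#' @export
print.detection_report <- function(x, ...) {
  cat(sprintf("<detection_report> %s (RBD positive):\n",
              if (!is.null(x$config$combination)) x$config$combination else "atonia"))
  print(x$report)
  invisible(x)
}

#' Cross-validated RBD detection
#'
#' Balanced 10-subject folds (construction shared with the staging module);
#' the forest and its imputation medians are fit on training folds only.
#' Rates are aggregated fold-wise (each subject yields one prediction) as
#' mean and SD, with RBD as the positive class.
#'
#' @param metrics subject metric tibble with `subject_id`, `cohort` and
#'   metric columns.
#' @param cfg a [detection_config()].
#' @param fold_size subjects held out per fold.
#' @return a `detection_report`: `report` (accuracy/sensitivity/
#'   specificity/F1 mean and sd), `per_subject` predictions.
#' @export
detect_cv <- function(metrics, cfg = detection_config(), fold_size = 10) {
  if (length(unique(metrics$cohort)) < 2)
    stop("both cohorts must be present for detection")
  folds <- make_subject_folds(metrics[c("subject_id", "cohort")],
                              fold_size, seed = cfg$seed)
  metrics <- dplyr::left_join(metrics, folds, by = c("subject_id", "cohort"))
  fold_rates <- list(); per_subject <- list()
  for (f in sort(unique(metrics$fold))) {
    train <- metrics[metrics$fold != f, ]
    test <- metrics[metrics$fold == f, ]
    model <- train_detector(train, cfg)
    pred <- predict(model, test)
    fold_rates[[f]] <- binary_rates(test$cohort, as.character(pred))
    per_subject[[f]] <- tibble::tibble(subject_id = test$subject_id,
                                       cohort = test$cohort,
                                       predicted = as.character(pred),
                                       fold = f)
  }
  finish_detection_report(lapply(fold_rates, as.list),
                          dplyr::bind_rows(per_subject), cfg)
}

#' Atonia-index threshold baseline
#'
#' Classifies a subject as RBD when `AtoniaIndex_REM` falls below a
#' threshold. With `threshold = NULL` the threshold is chosen on each
#' training fold by maximising balanced accuracy over candidate midpoints;
#' a fixed literature threshold can be supplied instead. Subjects with a
#' sentinel atonia index are excluded with a warning.
#'
#' @param metrics subject metric tibble (needs `AtoniaIndex_REM`).
#' @param threshold fixed threshold, or `NULL` to tune per training fold.
#' @param fold_size subjects held out per fold.
#' @param seed fold-construction seed.
#' @return a `detection_report` with the per-fold thresholds attached.
#' @export
atonia_threshold_classifier <- function(metrics, threshold = NULL,
                                        fold_size = 10, seed = 1) {
  ok <- is.finite(metrics$AtoniaIndex_REM)
  if (!all(ok)) {
    warning("excluding ", sum(!ok), " subject(s) with sentinel atonia index")
    metrics <- metrics[ok, ]
  }
  folds <- make_subject_folds(metrics[c("subject_id", "cohort")],
                              fold_size, seed = seed)
  metrics <- dplyr::left_join(metrics, folds, by = c("subject_id", "cohort"))
  pick_threshold <- function(ai, cohort) {
    cand <- sort(unique(ai))
    cand <- c(cand[1] - 0.01, (cand[-1] + cand[-length(cand)]) / 2,
              cand[length(cand)] + 0.01)
    bal <- vapply(cand, function(th) {
      pred <- ifelse(ai < th, "RBD", "HC")
      r <- binary_rates(cohort, pred)
      mean(c(r["sensitivity"], r["specificity"]), na.rm = TRUE)
    }, numeric(1))
    cand[which.max(bal)]
  }
  fold_rates <- list(); per_subject <- list(); thresholds <- numeric(0)
  for (f in sort(unique(metrics$fold))) {
    train <- metrics[metrics$fold != f, ]
    test <- metrics[metrics$fold == f, ]
    th <- if (is.null(threshold))
      pick_threshold(train$AtoniaIndex_REM, train$cohort) else threshold
    thresholds[as.character(f)] <- th
    pred <- ifelse(test$AtoniaIndex_REM < th, "RBD", "HC")
    fold_rates[[f]] <- binary_rates(test$cohort, pred)
    per_subject[[f]] <- tibble::tibble(subject_id = test$subject_id,
                                       cohort = test$cohort, predicted = pred,
                                       fold = f)
  }
  finish_detection_report(lapply(fold_rates, as.list),
                          dplyr::bind_rows(per_subject),
                          list(combination = "atonia_threshold"),
                          extra = list(thresholds = thresholds))
}
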