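# Random-forest sleep staging over any sensor combination, with
# subject-wise cross-validation so no subject contributes epochs to both
# training and test sets.

ID_COLS <- c("subject_id", "cohort", "epoch", "stage")

#' Staging configuration
#'
#' @param n_trees number of trees (500, the convention for this task).
#' @param mtry candidate features per split; `NULL` means `floor(sqrt(M))`.
#' @param combination sensor combination id: `A1` (ECG), `B1` (EOG), `C1`
#'   (EMG), `A2` (ECG+EOG), `B2` (ECG+EMG), `C2` (EOG+EMG), `A3` (all
#'   three). `Z3` (EEG-bearing) is out of scope and rejected.
#' @param class_weighting `"none"` or `"balanced"` (inverse class frequency
#'   case weights).
#' @param seed integer seed controlling subsampling and forest growth.
#' @param max_train_epochs stratified cap on training epochs per fit; keeps
#'   single-CPU forest growth tractable at overnight scale without touching
#'   the evaluation set.
#' @param min_node_size terminal node size.
#' @return a `staging_config` list.
#' @export
staging_config <- function(n_trees = 500, mtry = NULL, combination = "C2",
                           class_weighting = c("none", "balanced"), seed = 1,
                           max_train_epochs = 8000, min_node_size = 20) {
  stopifnot(n_trees >= 1)
  structure(list(n_trees = n_trees, mtry = mtry, combination = combination,
                 class_weighting = match.arg(class_weighting),
                 seed = as.integer(seed),
                 max_train_epochs = max_train_epochs,
                 min_node_size = min_node_size),
            class = "staging_config")
}

#' Select the feature columns of a sensor combination
#'
#' Feature columns are prefixed by modality (`ecg_`, `eog_`, `emg_`);
#' identifier columns are kept.
#'
#' @param rows epoch-feature tibble.
#' @param combination combination id (see [staging_config()]).
#' @return tibble restricted to the combination's columns.
#' @export
select_combination <- function(rows, combination) {
  mods <- switch(combination,
                 A1 = "ecg", B1 = "eog", C1 = "emg",
                 A2 = c("ecg", "eog"), B2 = c("ecg", "emg"),
                 C2 = c("eog", "emg"), A3 = c("ecg", "eog", "emg"),
                 Z3 = stop("EEG combinations (Z3) are out of scope"),
                 stop("unknown combination '", combination, "'"))
  keep <- names(rows) %in% ID_COLS |
    grepl(paste0("^(", paste(mods, collapse = "|"), ")_"), names(rows))
  if (!any(grepl("_", names(rows)[keep], fixed = TRUE)))
    stop("no feature columns found for combination ", combination)
  rows[keep]
}

feature_cols <- function(rows) setdiff(names(rows), ID_COLS)

median_impute <- function(m, medians = NULL) {
  if (is.null(medians))
    medians <- vapply(m, function(col) stats::median(col, na.rm = TRUE),
                      numeric(1))
  medians[!is.finite(medians)] <- 0
  for (j in seq_along(m)) {
    bad <- !is.finite(m[[j]])
    if (any(bad)) m[[j]][bad] <- medians[[j]]
  }
  list(data = m, medians = medians)
}

#' Train the three-state staging forest
#'
#' @param rows epoch-feature tibble with a `stage` column over W/NREM/REM
#'   (UNSCORED rows are dropped) and numeric feature columns; identifier
#'   columns `subject_id`, `cohort`, `epoch` are ignored.
#' @param cfg a [staging_config()].
#' @return an `rbd_stager` object.
#' @export
train_stager <- function(rows, cfg = staging_config()) {
  rows <- rows[!is.na(rows$stage) & rows$stage != "UNSCORED", ]
  y <- factor(rows$stage, levels = STAGES3)
  if (length(unique(y)) < 2) stop("training set contains a single class")
  fc <- feature_cols(rows)
  x <- rows[fc]
  imp <- median_impute(x)
  x <- imp$data

  set.seed(cfg$seed)
  if (nrow(x) > cfg$max_train_epochs) {
    # stratified subsample preserving stage proportions
    idx <- unlist(lapply(split(seq_len(nrow(x)), y), function(ii) {
      k <- max(1L, round(length(ii) / nrow(x) * cfg$max_train_epochs))
      sample(ii, min(k, length(ii)))
    }))
    x <- x[idx, ]; y <- y[idx]
  }
  cw <- NULL
  if (cfg$class_weighting == "balanced") {
    tb <- table(y)
    cw <- as.numeric(1 / tb[y]) * length(y) / length(tb)
  }
  mtry <- if (is.null(cfg$mtry)) max(1L, floor(sqrt(ncol(x)))) else
    min(cfg$mtry, ncol(x))
  fit <- ranger::ranger(x = x, y = droplevels(y),
                        num.trees = cfg$n_trees, mtry = mtry,
                        min.node.size = cfg$min_node_size,
                        case.weights = cw,
                        importance = "impurity",
                        seed = cfg$seed, num.threads = 1)
  structure(list(forest = fit, manifest = fc, medians = imp$medians,
                 config = cfg, levels = STAGES3),
            class = "rbd_stager")
}

#' @export
print.rbd_stager <- function(x, ...) {
  cat(sprintf("<rbd_stager> %s: %d trees, %d features, OOB error %.3f\n",
              x$config$combination, x$forest$num.trees,
              length(x$manifest), x$forest$prediction.error))
  invisible(x)
}

#' Variable importance of a staging forest, tidied
#'
#' @param x an `rbd_stager`.
#' @param ... unused.
#' @return tibble with `feature` and impurity `importance`, descending.
#' @export
tidy.rbd_stager <- function(x, ...) {
  imp <- x$forest$variable.importance
  tibble::tibble(feature = names(imp), importance = as.numeric(imp)) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}

#' One-row summary of a staging forest
#'
#' @param x an `rbd_stager`.
#' @param ... unused.
#' @return one-row tibble (trees, mtry, features, OOB error).
#' @export
glance.rbd_stager <- function(x, ...) {
  tibble::tibble(n_trees = x$forest$num.trees, mtry = x$forest$mtry,
                 n_features = length(x$manifest),
                 oob_error = x$forest$prediction.error)
}

#' Predict a hypnogram from epoch features
#'
#' @param model an `rbd_stager`.
#' @param rows epoch-feature tibble whose feature columns match the model's
#'   manifest; missing values are imputed with the training medians.
#' @return a [hypnogram()] with one label per input row (never UNSCORED).
#' @export
predict_stages <- function(model, rows) {
  stopifnot(inherits(model, "rbd_stager"))
  if (nrow(rows) == 0) return(hypnogram(character(0)))
  missing <- setdiff(model$manifest, names(rows))
  if (length(missing))
    stop("feature manifest mismatch; missing: ",
         paste(utils::head(missing, 5), collapse = ", "))
  x <- rows[model$manifest]
  had_na <- any(!vapply(x, function(col) all(is.finite(col)), logical(1)))
  x <- median_impute(x, model$medians)$data
  pr <- stats::predict(model$forest, data = x, num.threads = 1)$predictions
  hyp <- hypnogram(as.character(pr))
  attr(hyp, "imputed") <- had_na
  hyp
}

# ---------------------------------------------------------------------------

#' Staging agreement metrics
#'
#' Pairwise comparison of two hypnograms (or stage vectors): epochs where
#' the reference is UNSCORED are excluded, the 3x3 confusion matrix is
#' accumulated, per-stage one-vs-rest accuracy/sensitivity/specificity/
#' precision/F1 are derived, and three-state Cohen's kappa
#' (po - pe)/(1 - pe) summarises chance-corrected agreement.
#'
#' @param truth reference [hypnogram()] or character vector.
#' @param pred predicted [hypnogram()] or character vector of equal length.
#' @return a list of class `staging_metrics`: `confusion`, `per_stage`
#'   tibble, `kappa3`, `n`.
#' @export
staging_metrics <- function(truth, pred) {
  tv <- if (inherits(truth, "hypnogram")) as.character(truth$stages) else
    as.character(truth)
  pv <- if (inherits(pred, "hypnogram")) as.character(pred$stages) else
    as.character(pred)
  if (length(tv) != length(pv)) stop("hypnogram length mismatch")
  keep <- tv != "UNSCORED" & pv != "UNSCORED"
  tv <- factor(tv[keep], levels = STAGES3)
  pv <- factor(pv[keep], levels = STAGES3)
  cm <- table(truth = tv, pred = pv)
  n <- sum(cm)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  kappa3 <- if (abs(1 - pe) < 1e-12) 0 else (po - pe) / (1 - pe)
  per <- lapply(STAGES3, function(s) {
    tp <- cm[s, s]; fn <- sum(cm[s, ]) - tp
    fp <- sum(cm[, s]) - tp; tn <- n - tp - fn - fp
    sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    tibble::tibble(stage = s, accuracy = (tp + tn) / n, sensitivity = sens,
                   specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
                   precision = prec,
                   f1 = if (!is.na(sens) && !is.na(prec) && sens + prec > 0)
                     2 * sens * prec / (sens + prec) else NA_real_)
  })
  structure(list(confusion = unclass(cm), per_stage = dplyr::bind_rows(per),
                 kappa3 = kappa3, n = n),
            class = "staging_metrics")
}

#' @export
print.staging_metrics <- function(x, ...) {
  cat(sprintf("<staging_metrics> n=%d epochs, kappa3=%.3f\n", x$n, x$kappa3))
  print(x$per_stage)
  invisible(x)
}

#' Balanced subject folds
#'
#' Partitions subjects into folds of (nominally) `fold_size` subjects with
#' an even cohort split (5 HC + 5 RBD at the default size where both
#' cohorts allow it). With fewer subjects the fold count adapts and a
#' warning is emitted.
#'
#' @param subjects tibble with `subject_id` and `cohort`.
#' @param fold_size target subjects per fold.
#' @param seed shuffling seed.
#' @return the input tibble with a `fold` column.
#' @export
make_subject_folds <- function(subjects, fold_size = 10, seed = 1) {
  subjects <- dplyr::distinct(subjects, .data$subject_id, .data$cohort)
  n <- nrow(subjects)
  if (n < fold_size)
    warning("fewer subjects (", n, ") than the fold size; folds shrink")
  n_folds <- max(2L, ceiling(n / fold_size))
  if (n < 2) stop("need at least 2 subjects for cross-validation")
  set.seed(seed)
  subjects$fold <- NA_integer_
  strata <- split(seq_len(n), subjects$cohort)
  for (ii in strata) {
    ii <- ii[sample.int(length(ii))]
    subjects$fold[ii] <- rep(seq_len(n_folds), length.out = length(ii))
  }
  subjects
}

#' Subject-fold cross-validated staging
#'
#' Folds partition subjects (never epochs), each nominally holding out 10
#' subjects with an even HC/RBD split. Per-subject agreement metrics are
#' aggregated as mean and SD across subjects; a pooled kappa over all
#' held-out epochs and per-cohort kappas are also reported.
#'
#' @param rows cohort epoch-feature tibble with `subject_id`, `cohort`,
#'   `stage` and prefixed feature columns.
#' @param cfg a [staging_config()]; its `combination` selects the feature
#'   subset.
#' @param fold_size subjects held out per fold.
#' @return a list of class `staging_cv`: `report` (per-stage mean/sd),
#'   `kappa` (mean, sd, pooled, by_cohort), `per_subject`, `predictions`
#'   (named list of hypnograms), `folds`.
#' @export
subject_fold_cv <- function(rows, cfg = staging_config(), fold_size = 10) {
  rows <- select_combination(rows, cfg$combination)
  scored_by <- tapply(rows$stage != "UNSCORED", rows$subject_id, sum)
  empty <- names(scored_by)[scored_by == 0]
  if (length(empty)) {
    warning("excluding subject(s) with no scored epochs: ",
            paste(empty, collapse = ", "))
    rows <- rows[!rows$subject_id %in% empty, ]
  }
  subjects <- dplyr::distinct(rows[c("subject_id", "cohort")])
  folds <- make_subject_folds(subjects, fold_size, seed = cfg$seed)

  preds <- list()
  per_subject <- list()
  for (f in sort(unique(folds$fold))) {
    test_ids <- folds$subject_id[folds$fold == f]
    train <- rows[!rows$subject_id %in% test_ids, ]
    stopifnot(!any(test_ids %in% train$subject_id))  # leakage guard
    model <- train_stager(train, cfg)
    for (sid in test_ids) {
      sub <- rows[rows$subject_id == sid, ]
      hyp <- predict_stages(model, sub)
      preds[[sid]] <- hyp
      mt <- staging_metrics(sub$stage, hyp)
      per_subject[[sid]] <- dplyr::mutate(mt$per_stage, subject_id = sid,
                                          cohort = sub$cohort[1],
                                          kappa3 = mt$kappa3, fold = f)
    }
  }
  ps <- dplyr::bind_rows(per_subject)
  report <- ps |>
    dplyr::group_by(.data$stage) |>
    dplyr::summarise(dplyr::across(c("accuracy", "sensitivity", "specificity",
                                     "precision", "f1"),
                                   list(mean = ~mean(.x, na.rm = TRUE),
                                        sd = ~stats::sd(.x, na.rm = TRUE))),
                     .groups = "drop")
  ks <- ps |> dplyr::distinct(.data$subject_id, .data$cohort, .data$kappa3)
  pooled <- staging_metrics(
    unlist(lapply(names(preds), function(sid)
      rows$stage[rows$subject_id == sid])),
    unlist(lapply(names(preds), function(sid)
      as.character(preds[[sid]]$stages))))
  by_cohort <- tapply(ks$kappa3, ks$cohort, mean)
  structure(list(report = report,
                 kappa = list(mean = mean(ks$kappa3), sd = stats::sd(ks$kappa3),
                              pooled = pooled$kappa3,
                              by_cohort = by_cohort),
                 per_subject = ps, predictions = preds, folds = folds,
                 config = cfg),
            class = "staging_cv")
}

#' @export
print.staging_cv <- function(x, ...) {
  cat(sprintf("<staging_cv> %s: kappa %.3f +/- %.3f (pooled %.3f)\n",
              x$config$combination, x$kappa$mean, x$kappa$sd, x$kappa$pooled))
  print(x$report)
  invisible(x)
}
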