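sep_rows <- function(n = 3000, seed = 1, shift = 6) {
  set.seed(seed)
  stage <- sample(c("W", "NREM", "REM"), n, TRUE, c(0.25, 0.5, 0.25))
  mu <- c(W = 0, NREM = 1, REM = 2) * shift
  tibble::tibble(
    subject_id = sprintf("s%02d", rep(1:10, length.out = n)),
    cohort = rep(c("HC", "RBD"), length.out = n),
    epoch = seq_len(n) - 1L, stage = stage,
    eog_f1 = rnorm(n, mu[stage]), eog_f2 = rnorm(n, -mu[stage]),
    emg_f3 = rnorm(n), emg_f4 = rnorm(n, mu[stage] / 2))
}

test_that("the forest recovers separable classes and stores its manifest", {
  rows <- sep_rows()
  cfg <- staging_config(n_trees = 100, combination = "C2", seed = 1,
                        min_node_size = 5)
  fit <- train_stager(select_combination(rows, "C2"), cfg)
  pred <- predict_stages(fit, rows)
  expect_gte(staging_metrics(rows$stage, pred)$kappa3, 0.99)
  expect_setequal(fit$manifest, c("eog_f1", "eog_f2", "emg_f3", "emg_f4"))
  # same seed, same forest
  fit2 <- train_stager(select_combination(rows, "C2"), cfg)
  expect_identical(as.character(predict_stages(fit2, rows)$stages),
                   as.character(pred$stages))
})

test_that("label-shuffled features carry no out-of-fold skill", {
  kappas <- vapply(1:10, function(s) {
    rows <- sep_rows(n = 1500, seed = s, shift = 6)
    set.seed(1000 + s)
    rows$stage <- sample(rows$stage)        # break the association
    cfg <- staging_config(n_trees = 60, combination = "C2", seed = s,
                          min_node_size = 5)
    cv <- suppressWarnings(subject_fold_cv(rows, cfg, fold_size = 2))
    cv$kappa$pooled
  }, numeric(1))
  expect_lt(abs(median(kappas)), 0.05)
  expect_true(all(abs(kappas) < 0.15))
})

test_that("prediction enforces the manifest and degenerate contracts", {
  rows <- sep_rows(n = 600)
  fit <- train_stager(select_combination(rows, "C2"),
                      staging_config(n_trees = 30, combination = "C2"))
  bad <- dplyr::rename(rows, eog_other = "eog_f1")
  expect_error(predict_stages(fit, bad), "manifest")
  expect_equal(length(predict_stages(fit, rows[0, ])), 0)
  # sentinel features are imputed, then classified
  rows_na <- rows[1:5, ]
  rows_na$eog_f1[2] <- NA
  hyp <- predict_stages(fit, rows_na)
  expect_equal(length(hyp), 5)
  expect_false("UNSCORED" %in% as.character(hyp$stages))
  expect_true(attr(hyp, "imputed"))
  # single-class training is rejected
  one <- rows[rows$stage == "NREM", ]
  expect_error(train_stager(select_combination(one, "C2")), "single class")
})

test_that("combination selection follows the sensor map and rejects EEG", {
  rows <- sep_rows(n = 50)
  expect_setequal(setdiff(names(select_combination(rows, "B1")),
                          c("subject_id", "cohort", "epoch", "stage")),
                  c("eog_f1", "eog_f2"))
  expect_setequal(setdiff(names(select_combination(rows, "C1")),
                          c("subject_id", "cohort", "epoch", "stage")),
                  c("emg_f3", "emg_f4"))
  expect_error(select_combination(rows, "Z3"), "out of scope")
  expect_error(select_combination(rows, "Q9"), "unknown")
})

test_that("staging metrics match analytic anchors and hand computation", {
  truth <- c(rep("W", 5), rep("NREM", 10), rep("REM", 5))
  m_id <- staging_metrics(truth, truth)
  expect_equal(m_id$kappa3, 1)
  expect_true(all(unlist(m_id$per_stage[-1]) == 1))

  # constant predictor: po == pe analytically, kappa 0
  m_cst <- staging_metrics(truth, rep("NREM", 20))
  expect_equal(m_cst$kappa3, 0)

  # frozen confusion matrix, hand-computed kappa
  cm <- rbind(W = c(50, 10, 0), NREM = c(5, 100, 5), REM = c(0, 20, 30))
  truth2 <- rep(rep(c("W", "NREM", "REM"), 3), times = as.vector(t(cm)))
  pred2 <- rep(rep(c("W", "NREM", "REM"), each = 3), times = as.vector(t(cm)))
  m <- staging_metrics(truth2, pred2)
  n <- sum(cm); po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  expect_equal(m$kappa3, (po - pe) / (1 - pe))
  expect_equal(sum(m$confusion), 220)

  # kappa invariant under simultaneous class relabelling
  relab <- c(W = "REM", NREM = "W", REM = "NREM")
  m_rel <- staging_metrics(unname(relab[truth2]), unname(relab[pred2]))
  expect_equal(m_rel$kappa3, m$kappa3)

  # per-stage TP+FN equals the truth-class count
  for (s in c("W", "NREM", "REM"))
    expect_equal(sum(m$confusion[s, ]), sum(truth2 == s))

  expect_error(staging_metrics(truth, truth[-1]), "mismatch")
  # UNSCORED truth epochs are excluded pairwise
  tr3 <- c("W", "UNSCORED", "REM"); pr3 <- c("W", "NREM", "REM")
  expect_equal(staging_metrics(tr3, pr3)$n, 2)
})

test_that("folds are balanced, subject-disjoint and leak-free", {
  subs <- tibble::tibble(subject_id = sprintf("s%03d", 1:100),
                         cohort = rep(c("HC", "RBD"), each = 50))
  f <- make_subject_folds(subs, 10, seed = 4)
  expect_equal(length(unique(f$fold)), 10)
  counts <- table(f$fold, f$cohort)
  expect_true(all(counts == 5))

  expect_warning(make_subject_folds(subs[1:7, ], 10, seed = 1), "fold size")

  co <- tiny_cohort()
  cv <- suppressWarnings(subject_fold_cv(
    co$features, staging_config(n_trees = 50, combination = "C2", seed = 2),
    fold_size = 4))
  # every subject predicted exactly once, by a model that never saw it
  expect_setequal(names(cv$predictions), unique(co$features$subject_id))
  expect_equal(nrow(cv$folds), 8)
})

test_that("EOG+EMG staging beats EMG-only staging on the synthetic cohort", {
  co <- tiny_cohort()
  k <- vapply(c("C2", "C1"), function(cmb) {
    cv <- suppressWarnings(subject_fold_cv(
      co$features, staging_config(n_trees = 80, combination = cmb, seed = 3),
      fold_size = 4))
    cv$kappa$pooled
  }, numeric(1))
  expect_gte(k[["C2"]], k[["C1"]] - 0.02)
  expect_gte(k[["C2"]], 0.7)
})
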