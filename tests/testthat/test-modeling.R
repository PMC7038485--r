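test_that("classifier specs pin the documented defaults and reject typos", {
  d <- classifier_defaults()
  expect_equal(d$knn$n_neighbors, 6L)
  expect_equal(d$knn$p, 1L)
  expect_equal(d$random_forest$n_estimators, 90L)
  expect_equal(d$random_forest$random_state, 10L)
  expect_equal(d$decision_tree$max_depth, 6L)
  expect_equal(d$gradient_boosting$n_estimators, 120L)
  expect_equal(d$gradient_boosting$learning_rate, 0.01)
  expect_equal(d$gradient_boosting$subsample, 0.5)
  expect_equal(d$adaboost$n_estimators, 6L)
  expect_equal(d$adaboost$learning_rate, 0.1)

  sp <- classifier_spec("knn", list(n_neighbors = 3))
  expect_equal(sp$params$n_neighbors, 3)
  expect_error(classifier_spec("knn", list(neighbours = 3)),
               class = "hr_parameter_error")
})

test_that("a 10-sigma separated task is classified perfectly by every family", {
  # the separable feature tops the MI ranking in every fold, so evaluating on
  # the selected feature makes separability guarantee a perfect leave-one-out
  # score for every family
  fm <- planted_matrix(10, delta = 10, sd = 1, seed = 5)
  for (family in setdiff(names(classifier_defaults()), "gradient_boosting")) {
    res <- loocv_evaluate(fm, "neutral_vs_happy", family, k = 1, rng_seed = 1)
    expect_equal(res$accuracy, 1.0)
  }
  # the boosting backend thresholds at the neighbouring data value rather than
  # the midpoint, so the held-out minimum of the upper class always lands on
  # the wrong side: exactly one leave-one-out error on separable 1-D data
  res <- loocv_evaluate(fm, "neutral_vs_happy", "gradient_boosting", 1,
                        rng_seed = 1)
  expect_equal(res$accuracy, 19 / 20)
})

test_that("accuracy equals the confusion-matrix identity on every cell", {
  fm <- planted_matrix(12, delta = 1.5, seed = 9)
  res <- loocv_evaluate(fm, "neutral_vs_happy", "decision_tree", 8,
                        rng_seed = 3)
  expect_equal(sum(res$confusion), res$n_total)
  expect_equal(sum(diag(res$confusion)), res$n_correct)
  expect_equal(res$accuracy, res$n_correct / res$n_total)
  expect_gte(res$accuracy, 0)
  expect_lte(res$accuracy, 1)
})

test_that("a single run is exactly reproducible under a fixed seed", {
  fm <- planted_matrix(10, delta = 1, seed = 2)
  a <- loocv_evaluate(fm, "neutral_vs_happy", "random_forest", 10, rng_seed = 5)
  b <- loocv_evaluate(fm, "neutral_vs_happy", "random_forest", 10, rng_seed = 5)
  expect_identical(a, b)
  g <- loocv_evaluate(fm, "neutral_vs_happy", "gradient_boosting", 10,
                      rng_seed = 5)
  g2 <- loocv_evaluate(fm, "neutral_vs_happy", "gradient_boosting", 10,
                       rng_seed = 5)
  expect_identical(g$accuracy, g2$accuracy)
})

test_that("fold-wise feature rankings never see the held-out sample", {
  fm <- planted_matrix(10, delta = 2, seed = 3)
  X <- as.matrix(fm[hr_feature_names()])
  y <- factor(fm$emotion, levels = c("neutral", "happy"))
  rk <- hrmood:::loocv_rankings(X, y, rng_seed = 4)
  # corrupting row i cannot change row i's ranking (only other rows')
  for (i in c(1, 7, 20)) {
    Xc <- X
    Xc[i, ] <- 1e6
    rkc <- hrmood:::loocv_rankings(Xc, y, rng_seed = 4)
    expect_identical(rkc[i, ], rk[i, ])
  }
})

test_that("label-permuted data stays at chance level", {
  # null feature matrix: no class signal at all; distance-weighted kNN under
  # leave-one-out should sit inside a generous chance band
  accs <- vapply(1:3, function(s) {
    fm <- planted_matrix(25, delta = 0, seed = 100 + s)
    loocv_evaluate(fm, "neutral_vs_happy", "knn", 10, rng_seed = s)$accuracy
  }, numeric(1))
  expect_gt(mean(accs), 0.25)
  expect_lt(mean(accs), 0.75)
})

test_that("the mode-of-runs rule picks smallest ties and falls back to median", {
  m <- hrmood:::mode_accuracy(c(0.8, 0.8, 0.9, 0.9, 0.7))
  expect_equal(m$value, 0.8)
  expect_equal(m$note, "mode")
  m2 <- hrmood:::mode_accuracy(c(0.1, 0.2, 0.3, 0.4))
  expect_equal(m2$value, 0.25)
  expect_equal(m2$note, "median_fallback")
  m3 <- hrmood:::mode_accuracy(rep(0.96, 10))
  expect_equal(m3$value, 0.96)
})

test_that("a small experiment grid has the full cross-product structure", {
  fm <- planted_matrix(8, classes = c("neutral", "happy", "sad"),
                       delta = 3, seed = 7)
  cfg <- pipeline_config(k_grid = c(8, 5), n_eval_runs = 3, rng_seed = 2)
  res <- run_experiment(fm, cfg,
                        tasks = c("neutral_vs_happy", "three_class"),
                        classifiers = c("knn", "adaboost"))
  expect_s3_class(res, "hr_experiment")
  expect_equal(nrow(res), 2 * 2 * 2)
  expect_setequal(unique(res$task), c("neutral_vs_happy", "three_class"))
  for (i in seq_len(nrow(res))) {
    acc <- res$accuracies[[i]]
    expect_length(acc, 3)
    expect_true(all(acc >= 0 & acc <= 1))
    if (res$mode_note[i] == "mode") {
      expect_true(res$mode_accuracy[i] %in% acc)
    }
    expect_equal(sum(res$confusion[[i]]), res$n_total[i])
  }
  # pairwise task evaluated on 16 samples, three-class on 24
  expect_equal(unique(res$n_total[res$task == "neutral_vs_happy"]), 16)
  expect_equal(unique(res$n_total[res$task == "three_class"]), 24)

  # reproducible end to end under the master seed
  res2 <- run_experiment(fm, cfg,
                         tasks = c("neutral_vs_happy", "three_class"),
                         classifiers = c("knn", "adaboost"))
  expect_equal(res$mode_accuracy, res2$mode_accuracy)
  expect_equal(res$accuracies, res2$accuracies)
})

test_that("grid cells record errors instead of aborting, and tasks skip", {
  fm <- planted_matrix(8, classes = c("neutral", "happy"), delta = 2, seed = 1)
  cfg <- pipeline_config(k_grid = 5, n_eval_runs = 2)
  expect_warning(
    res <- run_experiment(fm, cfg,
                          tasks = c("neutral_vs_happy", "happy_vs_sad"),
                          classifiers = "knn"),
    "skipped"
  )
  expect_equal(nrow(res), 2)
  sad_cell <- res[res$task == "happy_vs_sad", ]
  expect_true(is.na(sad_cell$mode_accuracy))
  expect_match(sad_cell$mode_note, "error")
  ok_cell <- res[res$task == "neutral_vs_happy", ]
  expect_false(is.na(ok_cell$mode_accuracy))
})

test_that("summaries reshape per task, find the best cell, and print", {
  fm <- planted_matrix(8, delta = 3, seed = 4)
  cfg <- pipeline_config(k_grid = c(8, 5), n_eval_runs = 2)
  res <- run_experiment(fm, cfg, tasks = "neutral_vs_happy",
                        classifiers = c("knn", "decision_tree"))
  sm <- summarize_results(res)
  expect_named(sm$tables, "neutral_vs_happy")
  expect_equal(dim(sm$tables$neutral_vs_happy), c(2, 3))  # classifier, k8, k5
  expect_equal(nrow(sm$best), 1)
  expect_equal(sm$best$mode_accuracy, max(res$mode_accuracy))
  expect_output(print(sm), "Best cell per task")

  empty <- run_experiment(fm, cfg, tasks = character(0))
  expect_equal(nrow(summarize_results(empty)$best), 0)
  expect_output(print(summarize_results(empty)), "empty grid")

  # results CSV layout
  path <- withr::local_tempfile(fileext = ".csv")
  write_results(res, path)
  out <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(names(out),
               c("task", "classifier", "k", "run_1", "run_2", "mode_accuracy"))
})

test_that("tidy and glance views expose the grid in long and one-row form", {
  fm <- planted_matrix(8, delta = 3, seed = 4)
  cfg <- pipeline_config(k_grid = c(8, 5), n_eval_runs = 2)
  res <- run_experiment(fm, cfg, tasks = "neutral_vs_happy",
                        classifiers = "knn")
  td <- tidy(res)
  expect_equal(nrow(td), 2 * 2)
  expect_named(td, c("task", "classifier", "k", "run", "accuracy",
                     "mode_accuracy"))
  gl <- glance(res)
  expect_equal(gl$n_cells, 2)
  expect_equal(gl$n_failed, 0)
  expect_equal(gl$best_accuracy, max(res$mode_accuracy))

  sel <- select_top_k(score_mutual_information(fm, 1), 5)
  expect_equal(sum(tidy(sel)$selected), 5)
  expect_equal(glance(sel)$k, 5)
  p1 <- autoplot(res)
  p2 <- autoplot(sel)
  expect_s3_class(p1, "ggplot")
  expect_s3_class(p2, "ggplot")
})
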