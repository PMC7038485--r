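#' Classification task definitions
#'
#' The four evaluation tasks: three pairwise emotion discriminations and the
#' full three-class problem.
#'
#' @param names Optional subset of task names to return.
#' @return A tibble with columns `task` and `classes` (list-column).
#' @export
emotion_tasks <- function(names = NULL) {
  tasks <- tibble::tibble(
    task = c("neutral_vs_happy", "neutral_vs_sad", "happy_vs_sad",
             "three_class"),
    classes = list(c("neutral", "happy"), c("neutral", "sad"),
                   c("happy", "sad"), c("neutral", "happy", "sad"))
  )
  if (is.null(names)) return(tasks)
  bad <- setdiff(names, tasks$task)
  if (length(bad) > 0) {
    abort(paste0("unknown task(s): ", paste(bad, collapse = ", ")),
          class = "hr_parameter_error")
  }
  tasks[match(names, tasks$task), ]
}

# Fold-wise feature rankings for one evaluation run. The jitter matrix for the
# mutual-information estimator is drawn up-front from `rng_seed`, so rankings
# are a pure function of (matrix, seed) and can be shared across classifier
# families and k values without touching the classifiers' RNG streams.
# Returns an n x p integer matrix; row i ranks features with sample i held out
# (or the same full-data ranking in every row when `outside_folds`).
loocv_rankings <- function(X, y, rng_seed, outside_folds = FALSE) {
  n <- nrow(X)
  p <- ncol(X)
  if (outside_folds) {
    sc <- mi_score_matrix(mi_jitter(X, rng_seed), y)
    rk <- order(-sc, seq_len(p))
    return(matrix(rk, nrow = n, ncol = p, byrow = TRUE))
  }
  # one standard-normal draw per (sample, feature); each fold rescales it by
  # column scales computed on its own training rows, so nothing about the
  # held-out row (value or scale contribution) enters that fold's ranking
  Z <- withr::with_seed(rng_seed, matrix(rnorm(n * p), n, p))
  t(vapply(seq_len(n), function(i) {
    Xt <- X[-i, , drop = FALSE]
    scales <- pmax(1, colMeans(abs(Xt)))
    Xj <- Xt + Z[-i, , drop = FALSE] * rep(1e-10 * scales, each = n - 1)
    sc <- mi_score_matrix(Xj, y[-i])
    order(-sc, seq_len(p))
  }, integer(p)))
}

restrict_task <- function(matrix, classes) {
  sub <- matrix[matrix$emotion %in% classes, , drop = FALSE]
  counts <- table(factor(sub$emotion, levels = classes))
  if (any(counts < 2)) {
    abort(paste0("each task class needs at least 2 samples; got ",
                 paste(names(counts), counts, sep = "=", collapse = ", ")),
          class = "hr_degenerate_fold_error")
  }
  sub
}

loocv_cell <- function(X, y, rankings, spec, k, rng_seed) {
  n <- nrow(X)
  lv <- levels(y)
  pred <- character(n)
  for (i in seq_len(n)) {
    sel <- rankings[i, seq_len(k)]
    ytr <- y[-i]
    if (nlevels(droplevels(ytr)) < length(lv)) {
      abort("a class is absent from a training fold",
            class = "hr_degenerate_fold_error")
    }
    pred[i] <- as.character(fit_predict(
      spec,
      X[-i, sel, drop = FALSE], ytr,
      X[i, sel, drop = FALSE],
      seed = rng_seed + i * 131L
    ))
  }
  pred <- factor(pred, levels = lv)
  confusion <- table(truth = y, predicted = pred)
  list(
    accuracy = sum(diag(confusion)) / n,
    confusion = confusion,
    n_total = n,
    n_correct = sum(diag(confusion))
  )
}

#' Leave-one-out evaluation of one classifier on one task
#'
#' For every sample: rank the features by mutual information on the remaining
#' n - 1 rows, keep the top `k`, fit the classifier on those columns of the
#' n - 1 rows and predict the held-out sample. Accuracy is
#' `n_correct / n_total`. Keeping selection inside each fold means the
#' held-out sample never influences its own feature set; set
#' `select_outside_folds = TRUE` in the config to rank once on the full matrix
#' instead.
#'
#' @param matrix Feature-matrix tibble.
#' @param task Task name (see [emotion_tasks()]) or a one-row task tibble.
#' @param spec An `hr_classifier_spec` (or family name).
#' @param k Number of features to keep in each fold.
#' @param rng_seed Seed for the estimator jitter and stochastic fitters; a
#'   fixed seed reproduces the run exactly.
#' @param config A [pipeline_config()]; supplies `select_outside_folds`.
#' @return List with `accuracy`, `confusion` (truth x predicted table),
#'   `n_total`, `n_correct`.
#' @export
loocv_evaluate <- function(matrix, task, spec, k, rng_seed = 1L,
                           config = pipeline_config()) {
  if (is.character(task)) task <- emotion_tasks(task)
  if (is.character(spec)) spec <- classifier_spec(spec)
  classes <- task$classes[[1]]
  sub <- restrict_task(matrix, classes)
  feats <- feature_columns(sub)
  if (k < 1 || k > length(feats)) {
    abort(paste0("k must lie in [1, ", length(feats), "]"),
          class = "hr_parameter_error")
  }
  X <- as.matrix(sub[feats])
  y <- factor(sub$emotion, levels = classes)
  rankings <- loocv_rankings(X, y, rng_seed, config$select_outside_folds)
  loocv_cell(X, y, rankings, spec, k, rng_seed)
}

# Mode of the run accuracies: the most frequent value, smallest on ties. When
# every value is distinct the mode is undefined and the median is reported
# instead (flagged in `mode_note`).
mode_accuracy <- function(acc) {
  ux <- unique(acc)
  counts <- tabulate(match(acc, ux))
  if (max(counts) == 1 && length(acc) > 1) {
    return(list(value = median(acc), note = "median_fallback"))
  }
  list(value = min(ux[counts == max(counts)]), note = "mode")
}

#' Run the full evaluation grid
#'
#' Evaluates every (task, classifier family, k) cell of the experiment grid:
#' each cell repeats [loocv_evaluate()] `n_eval_runs` times with seeds
#' `rng_seed, rng_seed + 1, ...` and reports the mode of the run accuracies
#' (smallest value on ties; median when all runs differ). The confusion matrix
#' of the final run is kept per cell. A failing cell is recorded with an error
#' note rather than aborting the grid.
#'
#' @param matrix Feature-matrix tibble.
#' @param config A [pipeline_config()]; supplies `k_grid`, `n_eval_runs`,
#'   `rng_seed`, `select_outside_folds` and classifier overrides.
#' @param tasks Optional character subset of task names.
#' @param classifiers Optional character subset of classifier families.
#' @return A tibble of class `hr_experiment`: columns `task`, `classifier`,
#'   `k`, `accuracies` (list of per-run accuracy vectors), `mode_accuracy`,
#'   `mode_note`, `n_total` and `confusion` (list of tables).
#' @export
run_experiment <- function(matrix, config = pipeline_config(),
                           tasks = NULL, classifiers = NULL) {
  task_tbl <- emotion_tasks(tasks)
  families <- classifiers %||% names(classifier_defaults())
  specs <- lapply(families, function(f) {
    classifier_spec(f, config$classifier_params[[f]] %||% list())
  })
  names(specs) <- families
  feats <- feature_columns(matrix)
  seeds <- config$rng_seed + seq_len(config$n_eval_runs) - 1L
  cells <- list()
  for (ti in seq_len(nrow(task_tbl))) {
    task_name <- task_tbl$task[ti]
    classes <- task_tbl$classes[[ti]]
    prep <- tryCatch(restrict_task(matrix, classes), error = function(e) e)
    if (inherits(prep, "error")) {
      warning(sprintf("task %s skipped: %s", task_name,
                      conditionMessage(prep)), call. = FALSE)
      for (fam in families) for (k in config$k_grid) {
        cells[[length(cells) + 1L]] <- tibble::tibble(
          task = task_name, classifier = fam, k = k,
          accuracies = list(numeric(0)), mode_accuracy = NA_real_,
          mode_note = paste0("error: ", conditionMessage(prep)),
          n_total = NA_integer_, confusion = list(NULL)
        )
      }
      next
    }
    X <- as.matrix(prep[feats])
    y <- factor(prep$emotion, levels = classes)
    # per-run fold rankings, shared across families and k
    rankings <- lapply(seeds, function(s) {
      loocv_rankings(X, y, s, config$select_outside_folds)
    })
    for (fam in families) {
      for (k in config$k_grid) {
        runs <- vector("list", length(seeds))
        failed <- NULL
        for (r in seq_along(seeds)) {
          runs[[r]] <- tryCatch(
            loocv_cell(X, y, rankings[[r]], specs[[fam]], k, seeds[r]),
            error = function(e) e
          )
          if (inherits(runs[[r]], "error")) {
            failed <- conditionMessage(runs[[r]])
            break
          }
        }
        if (!is.null(failed)) {
          cells[[length(cells) + 1L]] <- tibble::tibble(
            task = task_name, classifier = fam, k = k,
            accuracies = list(numeric(0)), mode_accuracy = NA_real_,
            mode_note = paste0("error: ", failed),
            n_total = NA_integer_, confusion = list(NULL)
          )
          next
        }
        acc <- vapply(runs, `[[`, numeric(1), "accuracy")
        m <- mode_accuracy(acc)
        cells[[length(cells) + 1L]] <- tibble::tibble(
          task = task_name, classifier = fam, k = k,
          accuracies = list(acc), mode_accuracy = m$value,
          mode_note = m$note, n_total = runs[[1]]$n_total,
          confusion = list(runs[[length(runs)]]$confusion)
        )
      }
    }
  }
  out <- dplyr::bind_rows(cells)
  attr(out, "config") <- config
  class(out) <- c("hr_experiment", class(out))
  out
}

#' Summarize an experiment grid
#'
#' Reshapes the grid into one mode-accuracy table per task (classifier rows,
#' k columns) and reports the best (classifier, k) cell per task.
#'
#' @param results An `hr_experiment` tibble from [run_experiment()].
#' @return A list of class `hr_summary`: `tables` (named list of wide
#'   tibbles) and `best` (one row per task).
#' @export
summarize_results <- function(results) {
  stopifnot(is.data.frame(results))
  if (nrow(results) == 0) {
    return(structure(list(tables = list(),
                          best = tibble::tibble(task = character(),
                                                classifier = character(),
                                                k = integer(),
                                                mode_accuracy = double())),
                     class = "hr_summary"))
  }
  tables <- results |>
    dplyr::select("task", "classifier", "k", "mode_accuracy") |>
    tidyr::pivot_wider(names_from = "k", values_from = "mode_accuracy",
                       names_prefix = "k") |>
    dplyr::group_split(.data$task, .keep = TRUE)
  names(tables) <- vapply(tables, function(t) t$task[1], character(1))
  tables <- lapply(tables, function(t) dplyr::select(t, -"task"))
  best <- results |>
    dplyr::filter(!is.na(.data$mode_accuracy)) |>
    dplyr::group_by(.data$task) |>
    dplyr::slice_max(.data$mode_accuracy, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("task", "classifier", "k", "mode_accuracy")
  structure(list(tables = tables, best = best), class = "hr_summary")
}

#' @export
print.hr_summary <- function(x, ...) {
  if (length(x$tables) == 0) {
    cat("<hr_summary> empty grid\n")
    return(invisible(x))
  }
  for (nm in names(x$tables)) {
    cat("== ", nm, " (mode accuracy) ==\n", sep = "")
    print(as.data.frame(x$tables[[nm]]), row.names = FALSE, digits = 3)
    cat("\n")
  }
  cat("Best cell per task:\n")
  print(as.data.frame(x$best), row.names = FALSE, digits = 3)
  invisible(x)
}

#' Write experiment results as CSV
#'
#' Columns `task,classifier,k,run_1..run_R,mode_accuracy`, one row per grid
#' cell.
#'
#' @param results An `hr_experiment` tibble.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  n_runs <- max(lengths(results$accuracies), 1L)
  runs <- t(vapply(results$accuracies, function(a) {
    c(a, rep(NA_real_, n_runs - length(a)))
  }, numeric(n_runs)))
  colnames(runs) <- paste0("run_", seq_len(n_runs))
  out <- dplyr::bind_cols(
    results[c("task", "classifier", "k")],
    tibble::as_tibble(runs),
    results["mode_accuracy"]
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
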