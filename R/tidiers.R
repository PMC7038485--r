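#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an experiment grid
#'
#' One row per (task, classifier, k, run) with the run's accuracy, plus the
#' cell's mode accuracy.
#'
#' @param x An `hr_experiment` tibble from [run_experiment()].
#' @param ... Unused.
#' @return A long tibble: `task`, `classifier`, `k`, `run`, `accuracy`,
#'   `mode_accuracy`.
#' @method tidy hr_experiment
#' @export
tidy.hr_experiment <- function(x, ...) {
  x |>
    dplyr::select("task", "classifier", "k", "accuracies", "mode_accuracy") |>
    dplyr::mutate(run = purrr::map(.data$accuracies, seq_along)) |>
    tidyr::unnest(c("accuracies", "run")) |>
    dplyr::rename(accuracy = "accuracies") |>
    dplyr::select("task", "classifier", "k", "run", "accuracy",
                  "mode_accuracy")
}

#' Summarise an experiment grid in one row
#'
#' @param x An `hr_experiment` tibble.
#' @param ... Unused.
#' @return A one-row tibble: cell counts, failed-cell count and the best mode
#'   accuracy with its task/classifier/k.
#' @method glance hr_experiment
#' @export
glance.hr_experiment <- function(x, ...) {
  ok <- x[!is.na(x$mode_accuracy), ]
  best <- if (nrow(ok)) ok[which.max(ok$mode_accuracy), ] else NULL
  tibble::tibble(
    n_cells = nrow(x),
    n_tasks = dplyr::n_distinct(x$task),
    n_classifiers = dplyr::n_distinct(x$classifier),
    n_k = dplyr::n_distinct(x$k),
    n_failed = sum(is.na(x$mode_accuracy)),
    best_accuracy = if (is.null(best)) NA_real_ else best$mode_accuracy,
    best_task = if (is.null(best)) NA_character_ else best$task,
    best_classifier = if (is.null(best)) NA_character_ else best$classifier,
    best_k = if (is.null(best)) NA_integer_ else best$k
  )
}

#' Tidy a feature selection
#'
#' @param x An `hr_selection` from [select_top_k()].
#' @param ... Unused.
#' @return Tibble `feature`, `score`, `rank`, `selected` (logical).
#' @method tidy hr_selection
#' @export
tidy.hr_selection <- function(x, ...) {
  dplyr::mutate(x$scores, selected = .data$rank <= x$k)
}

#' @method glance hr_selection
#' @export
glance.hr_selection <- function(x, ...) {
  tibble::tibble(
    n_features = length(x$ranking),
    k = x$k,
    top_feature = x$ranking[1],
    top_score = x$scores$score[1]
  )
}
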