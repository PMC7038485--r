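#' Run the whole pipeline end to end
#'
#' Simulates a study (or takes a session tibble), extracts the 53-feature
#' matrix, scores features by mutual information per task, evaluates the
#' classifier grid under leave-one-out cross-validation and summarizes it.
#' One call reproduces the complete experiment structure on synthetic data.
#'
#' @param sim_config A [simulation_config()], or an existing session tibble
#'   with a `trace` list-column (e.g. from [load_study()]).
#' @param config A [pipeline_config()].
#' @param tasks,classifiers Optional subsets passed to [run_experiment()].
#' @return A list of class `hr_pipeline`: `study`, `features` (matrix tibble),
#'   `selections` (named list of `hr_selection`, one per task, at the largest
#'   k of the grid), `experiment` and `summary`.
#' @export
#' @examples
#' \donttest{
#' res <- run_pipeline(simulation_config(n_subjects = 6, seed = 3),
#'                     pipeline_config(k_grid = c(8, 5), n_eval_runs = 2),
#'                     tasks = "neutral_vs_happy", classifiers = "knn")
#' res$summary
#' }
run_pipeline <- function(sim_config = simulation_config(),
                         config = pipeline_config(),
                         tasks = NULL, classifiers = NULL) {
  study <- if (inherits(sim_config, "hr_sim_config")) {
    simulate_study(sim_config)
  } else {
    sim_config
  }
  features <- extract_feature_matrix(study, config)
  task_tbl <- emotion_tasks(tasks)
  k_top <- max(config$k_grid)
  selections <- list()
  for (i in seq_len(nrow(task_tbl))) {
    sub <- features[features$emotion %in% task_tbl$classes[[i]], ]
    selections[[task_tbl$task[i]]] <- tryCatch(
      select_top_k(score_mutual_information(sub, config$rng_seed), k_top),
      error = function(e) NULL
    )
  }
  experiment <- run_experiment(features, config, tasks = tasks,
                               classifiers = classifiers)
  structure(
    list(study = study, features = features, selections = selections,
         experiment = experiment, summary = summarize_results(experiment)),
    class = "hr_pipeline"
  )
}

#' @export
print.hr_pipeline <- function(x, ...) {
  cat("<hr_pipeline>\n")
  cat("  sessions:", nrow(x$study), " feature rows:", nrow(x$features), "\n")
  cat("  grid cells:", nrow(x$experiment), "\n\n")
  print(x$summary)
  invisible(x)
}
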