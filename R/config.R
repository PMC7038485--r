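#' Pipeline configuration
#'
#' Bundles the tunable parameters shared across feature extraction, feature
#' selection and classifier evaluation. Defaults follow the reference
#' protocol: absolute first/second differences, base-2 entropy, a 25-sample
#' moving-average window, the k grid \{20, 16, 12, 10, 8, 5\}, and accuracy
#' reported as the mode of ten leave-one-out runs.
#'
#' @param diff_absolute Use the mean *absolute* difference for the four
#'   mean-of-difference features (first/second differences of the original and
#'   normalized signals). Signed means telescope to near-trivial endpoint
#'   differences, so the absolute form is the default.
#' @param entropy_log_base Base of the logarithm in the heart-rate entropy
#'   feature; one of `2` (bits) or `exp(1)` (nats).
#' @param moving_avg_window Window length, in samples, of the moving average
#'   applied to the normalized signal (>= 2).
#' @param k_grid Ordered integer vector of top-k feature-set sizes to evaluate;
#'   every entry must lie in `[1, 53]`.
#' @param n_eval_runs Number of repeated leave-one-out evaluations per grid
#'   cell; the reported accuracy is the mode across runs.
#' @param rng_seed Master seed for every stochastic stage.
#' @param select_outside_folds If `TRUE`, rank features once on the full task
#'   matrix instead of inside each leave-one-out fold. The default (`FALSE`)
#'   keeps selection inside the folds so the held-out sample never influences
#'   its own feature set.
#' @param classifier_params Named list of per-family hyperparameter overrides,
#'   merged over [classifier_defaults()].
#'
#' @return A list of class `hr_config`.
#' @seealso [read_pipeline_config()] to load the same settings from a flat
#'   YAML file.
#' @export
#' @examples
#' cfg <- pipeline_config(k_grid = c(10, 5), n_eval_runs = 3)
#' cfg$k_grid
pipeline_config <- function(diff_absolute = TRUE,
                            entropy_log_base = 2,
                            moving_avg_window = 25,
                            k_grid = c(20L, 16L, 12L, 10L, 8L, 5L),
                            n_eval_runs = 10L,
                            rng_seed = 1L,
                            select_outside_folds = FALSE,
                            classifier_params = list()) {
  if (!isTRUE(diff_absolute) && !isFALSE(diff_absolute)) {
    abort("`diff_absolute` must be TRUE or FALSE.", class = "hr_parameter_error")
  }
  if (!entropy_log_base %in% c(2, exp(1))) {
    abort("`entropy_log_base` must be 2 or exp(1).", class = "hr_parameter_error")
  }
  if (!is.numeric(moving_avg_window) || length(moving_avg_window) != 1 ||
      moving_avg_window < 2 || moving_avg_window != round(moving_avg_window)) {
    abort("`moving_avg_window` must be a single integer >= 2.",
          class = "hr_parameter_error")
  }
  k_grid <- as.integer(k_grid)
  if (length(k_grid) == 0 || anyNA(k_grid) || any(k_grid < 1L | k_grid > 53L)) {
    abort("every k in `k_grid` must satisfy 1 <= k <= 53.",
          class = "hr_parameter_error")
  }
  n_eval_runs <- as.integer(n_eval_runs)
  if (is.na(n_eval_runs) || n_eval_runs < 1L) {
    abort("`n_eval_runs` must be a positive integer.", class = "hr_parameter_error")
  }
  structure(
    list(
      diff_absolute = diff_absolute,
      entropy_log_base = entropy_log_base,
      moving_avg_window = as.integer(moving_avg_window),
      k_grid = k_grid,
      n_eval_runs = n_eval_runs,
      rng_seed = as.integer(rng_seed),
      select_outside_folds = isTRUE(select_outside_folds),
      classifier_params = classifier_params
    ),
    class = "hr_config"
  )
}

#' Read a pipeline configuration from a flat YAML file
#'
#' The file is a flat key/value mapping whose keys are the arguments of
#' [pipeline_config()] (with `classifier_params` as a nested family -> list
#' mapping). Unknown keys are an error so typos fail fast.
#'
#' @param path Path to the YAML file.
#' @return A list of class `hr_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    abort(paste0("unknown configuration key(s): ", paste(unknown, collapse = ", ")),
          class = "hr_config_error")
  }
  if (identical(raw$entropy_log_base, "e")) raw$entropy_log_base <- exp(1)
  do.call(pipeline_config, raw)
}

#' Write a pipeline configuration to a flat YAML file
#'
#' @param config A list of class `hr_config`.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "hr_config"))
  out <- unclass(config)
  if (identical(out$entropy_log_base, exp(1))) out$entropy_log_base <- "e"
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.hr_config <- function(x, ...) {
  cat("<hr_config>\n")
  cat("  diff_absolute:        ", x$diff_absolute, "\n")
  cat("  entropy_log_base:     ", if (x$entropy_log_base == 2) "2 (bits)" else "e (nats)", "\n")
  cat("  moving_avg_window:    ", x$moving_avg_window, "samples\n")
  cat("  k_grid:               ", paste(x$k_grid, collapse = ", "), "\n")
  cat("  n_eval_runs:          ", x$n_eval_runs, "\n")
  cat("  rng_seed:             ", x$rng_seed, "\n")
  cat("  select_outside_folds: ", x$select_outside_folds, "\n")
  invisible(x)
}
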