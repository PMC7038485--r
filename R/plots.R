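#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a segmented session
#'
#' Heart-rate trace with the neutral segment, the target segment and the
#' baseline level marked.
#'
#' @param object An `hr_segmented` object from [segment_session()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hr_segmented
#' @export
autoplot.hr_segmented <- function(object, ...) {
  df <- dplyr::bind_rows(
    dplyr::mutate(object$neutral, segment = "neutral"),
    dplyr::mutate(object$target,
                  segment = paste0("target (", object$emotion %||% "?", ")"))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$hr_bpm,
                                   colour = .data$segment)) +
    ggplot2::geom_step() +
    ggplot2::geom_hline(yintercept = object$baseline_bpm, linetype = "dashed") +
    ggplot2::labs(x = "time (s)", y = "heart rate (BPM)", colour = NULL,
                  title = "Session trace",
                  subtitle = sprintf("baseline %.1f BPM", object$baseline_bpm)) +
    ggplot2::theme_minimal()
}

#' Plot mode accuracy across the experiment grid
#'
#' Mode accuracy against the number of selected features, one line per
#' classifier family, one panel per task.
#'
#' @param object An `hr_experiment` tibble from [run_experiment()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hr_experiment
#' @export
autoplot.hr_experiment <- function(object, ...) {
  df <- object[!is.na(object$mode_accuracy),
               c("task", "classifier", "k", "mode_accuracy")]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$mode_accuracy,
                                   colour = .data$classifier)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~task) +
    ggplot2::labs(x = "top-k features", y = "mode accuracy",
                  colour = "classifier") +
    ggplot2::theme_minimal()
}

#' Plot mutual-information scores
#'
#' Bar chart of the top-ranked features; selected features are highlighted.
#'
#' @param object An `hr_selection` from [select_top_k()].
#' @param n Number of features to show (default 20).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hr_selection
#' @export
autoplot.hr_selection <- function(object, n = 20, ...) {
  df <- tidy(object)[seq_len(min(n, length(object$ranking))), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score,
                                   y = stats::reorder(.data$feature, .data$score),
                                   fill = .data$selected)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "mutual information (nats)", y = NULL,
                  fill = paste0("in top ", object$k)) +
    ggplot2::theme_minimal()
}
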