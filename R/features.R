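# Five-number summary used throughout the feature set. Standard deviation is
# population-flavoured (divisor n); an empty collection yields all zeros (the
# documented sentinel, e.g. no down-runs in a monotone-increasing segment) and
# a single element yields std 0.
summary_stats5 <- function(x) {
  if (length(x) == 0) {
    return(c(max = 0, min = 0, median = 0, mean = 0, std = 0))
  }
  c(
    max = max(x),
    min = min(x),
    median = median(x),
    mean = mean(x),
    std = sqrt(mean((x - mean(x))^2))
  )
}

# Shannon entropy of the empirical distribution of distinct integer-quantized
# values; 0 * log 0 == 0 by construction of table().
signal_entropy <- function(values, log_base = 2) {
  p <- as.numeric(table(round(values))) / length(values)
  -sum(p * log(p, base = log_base))
}

# {max,min,std,median,mean} of a finite-difference series, in the canonical
# order of the diff feature groups. The mean member follows the printed
# mean-of-difference formula and so honours `diff_absolute`; the other four
# summarize the signed series.
diff_series_stats <- function(d, diff_absolute) {
  c(
    max = max(d),
    min = min(d),
    std = sqrt(mean((d - mean(d))^2)),
    median = median(d),
    mean = if (diff_absolute) mean(abs(d)) else mean(d)
  )
}

#' Features of the original target-segment signal
#'
#' Computes the 22 features of the first feature subset on the raw (not
#' baseline-normalized) target-segment heart rate: mean first- and
#' second-order differences, range, entropy of the value distribution,
#' max/min-to-length ratios, RMS of adjacent differences, and five-number
#' summaries of the down-run, up-run and plateau (flat-run) durations.
#'
#' @param target Target-segment trace tibble (`time_s`, `hr_bpm`) or numeric
#'   BPM vector.
#' @param config A [pipeline_config()]; controls `diff_absolute` and
#'   `entropy_log_base`.
#' @param dt_s Sampling interval in seconds, used when `target` is a bare
#'   vector without a `dt_s` attribute.
#' @return A named numeric vector of length 22 in canonical order.
#' @export
extract_original_features <- function(target, config = pipeline_config(),
                                      dt_s = 1) {
  if (is.data.frame(target)) {
    if (!is.null(attr(target, "dt_s"))) dt_s <- attr(target, "dt_s")
    values <- target$hr_bpm
  } else {
    values <- target
  }
  n <- length(values)
  if (n < 10) {
    abort("original-signal features need at least 10 samples",
          class = "hr_insufficient_data_error")
  }
  d1 <- diff(values)
  d2 <- values[3:n] - values[1:(n - 2)]
  runs <- detect_runs(values, dt_s)
  out <- c(
    rate_diff1_mean = if (config$diff_absolute) mean(abs(d1)) else mean(d1),
    rate_diff2_mean = if (config$diff_absolute) mean(abs(d2)) else mean(d2),
    rate_range = max(values) - min(values),
    rate_data_entropy = signal_entropy(values, config$entropy_log_base),
    max_ratio = max(values) / n,
    min_ratio = min(values) / n,
    rate_adjacent_rms = sqrt(mean(d1^2)),
    stats::setNames(summary_stats5(runs$duration_s[runs$direction == "down"]),
                    stat5("rate_down_time_")),
    stats::setNames(summary_stats5(runs$duration_s[runs$direction == "up"]),
                    stat5("rate_up_time_")),
    stats::setNames(summary_stats5(runs$duration_s[runs$direction == "flat"]),
                    stat5("rate_time_continue_"))
  )
  out[hr_feature_names("original")]
}

#' Features of the baseline-normalized signal
#'
#' Computes the 31 features of the second feature subset on the normalized
#' signal (target minus neutral-baseline mean): down-run slope summaries
#' (slope = |amplitude| / duration, so all slopes are positive magnitudes),
#' up-run amplitude summaries (max/median/mean/std — no min, by construction
#' of the canonical set), down-run |amplitude| summaries, five statistics of
#' the 25-sample moving average ("valid" mode: output length `N - window + 1`),
#' the normalized-signal mean and unbiased sample variance, and five
#' statistics each of the first- and second-difference series.
#'
#' @param normalized Normalized-signal tibble (`time_s`, `delta_bpm`) from
#'   [normalize_target()], or a numeric vector of BPM deltas.
#' @param config A [pipeline_config()]; controls `diff_absolute` and
#'   `moving_avg_window`.
#' @param dt_s Sampling interval in seconds for bare-vector input.
#' @return A named numeric vector of length 31 in canonical order.
#' @export
extract_normalized_features <- function(normalized, config = pipeline_config(),
                                        dt_s = 1) {
  if (is.data.frame(normalized)) {
    if (!is.null(attr(normalized, "dt_s"))) dt_s <- attr(normalized, "dt_s")
    x <- normalized$delta_bpm
  } else {
    x <- normalized
  }
  n <- length(x)
  w <- config$moving_avg_window
  if (n < w) {
    abort(paste0("normalized signal (", n, " samples) is shorter than the ",
                 "moving-average window (", w, ")"),
          class = "hr_insufficient_data_error")
  }
  runs <- detect_runs(x, dt_s)
  down <- runs[runs$direction == "down", ]
  up <- runs[runs$direction == "up", ]
  ma <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 1))[w:n]
  d1 <- diff(x)
  d2 <- x[3:n] - x[1:(n - 2)]
  up_amp <- summary_stats5(up$amplitude)
  out <- c(
    stats::setNames(summary_stats5(abs(down$amplitude) / down$duration_s),
                    stat5("rate_down_slope_")),
    stats::setNames(up_amp[c("max", "median", "mean", "std")],
                    paste0("rate_up_amplitude_", c("max", "median", "mean", "std"))),
    stats::setNames(summary_stats5(abs(down$amplitude)),
                    stat5("rate_down_amplitude_")),
    stats::setNames(summary_stats5(ma), stat5("rate_25_mean_")),
    rate_data_mean = mean(x),
    rate_data_var = var(x),
    stats::setNames(diff_series_stats(d1, config$diff_absolute),
                    paste0("rate_norm_diff1_", c("max", "min", "std", "median", "mean"))),
    stats::setNames(diff_series_stats(d2, config$diff_absolute),
                    paste0("rate_norm_diff2_", c("max", "min", "std", "median", "mean")))
  )
  out[hr_feature_names("normalized")]
}

#' Full 53-feature vector of one session
#'
#' Concatenates the 22 original-signal features and the 31 normalized-signal
#' features of a segmented session, in the frozen canonical order.
#'
#' @param segmented An `hr_segmented` object from [segment_session()].
#' @param config A [pipeline_config()].
#' @return A one-row tibble: `subject_id`, `emotion`, then the 53 features.
#' @export
extract_features <- function(segmented, config = pipeline_config()) {
  stopifnot(inherits(segmented, "hr_segmented"))
  normalized <- normalize_target(segmented$target, segmented$baseline_bpm)
  feats <- c(
    extract_original_features(segmented$target, config),
    extract_normalized_features(normalized, config)
  )
  if (!all(is.finite(feats))) {
    abort("feature extraction produced non-finite values",
          class = "hr_shape_error")
  }
  dplyr::bind_cols(
    tibble::tibble(
      subject_id = segmented$subject_id %||% NA_character_,
      emotion = segmented$emotion %||% NA_character_
    ),
    tibble::as_tibble(as.list(feats))
  )
}

#' Extract the feature matrix of a whole study
#'
#' Segments, baseline-normalizes and featurizes every session of a manifest,
#' producing one 53-feature row per (subject, emotion) sample. Sessions that
#' fail a precondition (e.g. a target segment shorter than the moving-average
#' window) are skipped with a warning; an error is raised only if no session
#' survives.
#'
#' @param manifest Manifest tibble with a `trace` list-column (from
#'   [load_study()] or [simulate_study()]); rows lacking loaded traces are read
#'   from `trace_path`.
#' @param config A [pipeline_config()].
#' @return A feature-matrix tibble (`subject_id`, `emotion`, 53 features).
#' @export
extract_feature_matrix <- function(manifest, config = pipeline_config()) {
  stopifnot(is.data.frame(manifest), nrow(manifest) >= 1)
  rows <- purrr::map(seq_len(nrow(manifest)), function(i) {
    rec <- manifest[i, ]
    tryCatch({
      trace <- if ("trace" %in% names(manifest)) rec$trace[[1]] else
        read_hr_trace(rec$trace_path)
      seg <- segment_session(trace, rec$neutral_duration_s,
                             rec$target_duration_s,
                             emotion = rec$emotion,
                             subject_id = rec$subject_id)
      extract_features(seg, config)
    }, error = function(e) {
      warning(sprintf("skipping session %s/%s: %s", rec$subject_id,
                      rec$emotion, conditionMessage(e)), call. = FALSE)
      NULL
    })
  })
  rows <- purrr::compact(rows)
  if (length(rows) == 0) {
    abort("every session failed feature extraction",
          class = "hr_empty_output_error")
  }
  dplyr::bind_rows(rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
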