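#' Split a session into its neutral and target segments
#'
#' Each recording covers a 'neutral + target' video pair: the first segment is
#' always neutral viewing and supplies the subject's baseline, the second
#' carries the target emotion. Segments are half-open on the session-relative
#' time axis: neutral covers `[0, neutral_duration_s)` and target covers
#' `[neutral_duration_s, neutral_duration_s + target_duration_s)`, so the
#' sample at the cut belongs to the target segment and segment lengths sum to
#' the session length.
#'
#' @param trace Heart-rate trace tibble (`time_s`, `hr_bpm`), e.g. from
#'   [read_hr_trace()].
#' @param neutral_duration_s,target_duration_s Segment durations in seconds.
#' @param emotion,subject_id Optional metadata carried through to feature
#'   extraction.
#' @return An object of class `hr_segmented`: a list with elements `neutral`
#'   and `target` (trace tibbles), `baseline_bpm` (mean heart rate of the
#'   neutral segment), `dt_s`, `emotion` and `subject_id`.
#' @export
#' @examples
#' tr <- tibble::tibble(time_s = 0:140, hr_bpm = 70 + sin(0:140 / 10))
#' seg <- segment_session(tr, 70, 71)
#' nrow(seg$neutral); nrow(seg$target)
segment_session <- function(trace, neutral_duration_s, target_duration_s,
                            emotion = NULL, subject_id = NULL) {
  stopifnot(all(c("time_s", "hr_bpm") %in% names(trace)))
  if (neutral_duration_s <= 0 || target_duration_s <= 0) {
    abort("segment durations must be positive", class = "hr_parameter_error")
  }
  dt_s <- attr(trace, "dt_s")
  if (is.null(dt_s)) dt_s <- median(diff(trace$time_s))
  t_rel <- trace$time_s - trace$time_s[1]
  span <- t_rel[length(t_rel)] + dt_s
  if (neutral_duration_s + target_duration_s > span + dt_s) {
    abort("neutral + target durations exceed the session time span",
          class = "hr_format_error")
  }
  in_neutral <- t_rel < neutral_duration_s
  in_target <- t_rel >= neutral_duration_s &
    t_rel < neutral_duration_s + target_duration_s
  neutral <- trace[in_neutral, c("time_s", "hr_bpm")]
  target <- trace[in_target, c("time_s", "hr_bpm")]
  if (nrow(neutral) < 10 || nrow(target) < 10) {
    abort(paste0("each segment needs at least 10 samples (got ",
                 nrow(neutral), " neutral, ", nrow(target), " target)"),
          class = "hr_insufficient_data_error")
  }
  attr(neutral, "dt_s") <- dt_s
  attr(target, "dt_s") <- dt_s
  structure(
    list(
      neutral = neutral,
      target = target,
      baseline_bpm = compute_baseline(neutral),
      dt_s = dt_s,
      emotion = emotion,
      subject_id = subject_id
    ),
    class = "hr_segmented"
  )
}

#' Neutral-baseline heart rate
#'
#' The arithmetic mean of the neutral segment, used as the subject's baseline:
#' subtracting it from the target segment removes inter-individual differences
#' in resting heart rate.
#'
#' @param neutral Neutral-segment trace tibble, or a bare numeric vector of
#'   BPM values.
#' @return The mean heart rate in BPM.
#' @export
compute_baseline <- function(neutral) {
  values <- if (is.data.frame(neutral)) neutral$hr_bpm else neutral
  if (length(values) == 0) {
    abort("cannot compute a baseline from an empty segment",
          class = "hr_insufficient_data_error")
  }
  mean(values)
}

#' Baseline-normalize a target segment
#'
#' Subtracts the neutral-baseline mean from every target-segment sample,
#' yielding the normalized signal (BPM deltas, possibly negative) on which the
#' second feature subset is computed.
#'
#' @param target Target-segment trace tibble (or numeric BPM vector).
#' @param baseline Baseline heart rate in BPM, in (20, 250).
#' @return A tibble with columns `time_s` and `delta_bpm` (attribute `dt_s`
#'   preserved when present). For numeric input, a numeric vector.
#' @export
#' @examples
#' normalize_target(c(72, 74, 70), 70)
normalize_target <- function(target, baseline) {
  if (!is.numeric(baseline) || length(baseline) != 1 ||
      baseline <= 20 || baseline >= 250) {
    abort("`baseline` must be a single BPM value in (20, 250)",
          class = "hr_parameter_error")
  }
  if (!is.data.frame(target)) return(target - baseline)
  out <- tibble::tibble(
    time_s = target$time_s,
    delta_bpm = target$hr_bpm - baseline
  )
  attr(out, "dt_s") <- attr(target, "dt_s")
  out
}
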