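#' Read a heart-rate trace
#'
#' Reads a delimited-text heart-rate trace with header `time_s,hr_bpm` into a
#' tibble. The time grid must be (close to) uniform: the sampling interval is
#' inferred as the median of consecutive time deltas and any delta deviating
#' from it by more than 10% is rejected. Heart-rate values must be plausible
#' (strictly between 20 and 250 beats per minute).
#'
#' @param path Path to the trace CSV.
#' @return A tibble with columns `time_s`, `hr_bpm` and attribute `dt_s`
#'   (inferred sampling interval, seconds).
#' @export
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("time_s,hr_bpm", "0,70", "1,71", "2,72"), tf)
#' tr <- read_hr_trace(tf)
#' attr(tr, "dt_s")
read_hr_trace <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("time_s", "hr_bpm") %in% names(df))) {
    abort(paste0("trace file ", path, " must have columns time_s,hr_bpm"),
          class = "hr_format_error")
  }
  df <- tibble::as_tibble(df[c("time_s", "hr_bpm")])
  if (nrow(df) < 2) {
    abort(paste0("trace file ", path, " has fewer than 2 samples"),
          class = "hr_insufficient_data_error")
  }
  deltas <- diff(df$time_s)
  if (any(deltas <= 0)) {
    abort(paste0("trace file ", path, " has non-increasing time values"),
          class = "hr_format_error")
  }
  dt_s <- median(deltas)
  if (max(abs(deltas - dt_s)) > 0.1 * dt_s) {
    abort(paste0("trace file ", path, " is not on a uniform time grid ",
                 "(max deviation exceeds 10% of the median interval ",
                 signif(dt_s, 6), " s)"),
          class = "hr_format_error")
  }
  if (any(df$hr_bpm <= 20 | df$hr_bpm >= 250)) {
    abort(paste0("trace file ", path,
                 " contains implausible heart-rate values (outside 20-250 BPM)"),
          class = "hr_format_error")
  }
  attr(df, "dt_s") <- dt_s
  df
}

#' Write a heart-rate trace
#'
#' Inverse of [read_hr_trace()]; values round-trip losslessly.
#'
#' @param trace Tibble with columns `time_s`, `hr_bpm`.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_hr_trace <- function(trace, path) {
  stopifnot(all(c("time_s", "hr_bpm") %in% names(trace)))
  readr::write_csv(trace[c("time_s", "hr_bpm")], path, progress = FALSE)
  invisible(path)
}

.manifest_cols <- c("subject_id", "emotion", "neutral_duration_s",
                    "target_duration_s", "trace_path")

#' Read a session manifest
#'
#' A manifest lists one 'neutral + target' session per row: subject, target
#' emotion, the two segment durations and a trace path resolved relative to
#' the manifest file. Emotion labels are validated against
#' `c("neutral", "happy", "sad")` and (subject, emotion) pairs must be unique.
#'
#' @param path Path to the manifest CSV with header
#'   `subject_id,emotion,neutral_duration_s,target_duration_s,trace_path`.
#' @return A tibble of sessions with `trace_path` resolved.
#' @export
read_manifest <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(
                          subject_id = readr::col_character(),
                          emotion = readr::col_character(),
                          neutral_duration_s = readr::col_double(),
                          target_duration_s = readr::col_double(),
                          trace_path = readr::col_character()
                        ))
  if (!all(.manifest_cols %in% names(df))) {
    abort(paste0("manifest ", path, " must have columns ",
                 paste(.manifest_cols, collapse = ",")),
          class = "hr_format_error")
  }
  df <- tibble::as_tibble(df[.manifest_cols])
  if (nrow(df) == 0) return(df)
  bad <- setdiff(unique(df$emotion), hr_emotions())
  if (length(bad) > 0) {
    abort(paste0("unknown emotion label(s): ", paste(bad, collapse = ", "),
                 " (expected one of ", paste(hr_emotions(), collapse = ", "), ")"),
          class = "hr_vocabulary_error")
  }
  if (any(df$neutral_duration_s <= 0) || any(df$target_duration_s <= 0)) {
    abort("segment durations must be positive", class = "hr_format_error")
  }
  key <- paste(df$subject_id, df$emotion, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- df[duplicated(key), , drop = FALSE]
    abort(paste0("duplicate (subject_id, emotion) pair(s): ",
                 paste(unique(paste0(dup$subject_id, "/", dup$emotion)),
                       collapse = ", ")),
          class = "hr_duplicate_error")
  }
  root <- dirname(normalizePath(path, mustWork = TRUE))
  df$trace_path <- ifelse(
    grepl("^(/|[A-Za-z]:)", df$trace_path),
    df$trace_path,
    file.path(root, df$trace_path)
  )
  df
}

#' Write a session manifest
#'
#' @param manifest Tibble with the manifest columns (a `trace` list-column, if
#'   present, is dropped).
#' @param path Destination path. `trace_path` entries are written as given;
#'   keep them relative to the manifest's directory for portability.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(all(.manifest_cols %in% names(manifest)))
  readr::write_csv(manifest[.manifest_cols], path, progress = FALSE)
  invisible(path)
}

#' Load all traces referenced by a manifest
#'
#' Convenience wrapper: reads the manifest and attaches each trace as a
#' `trace` list-column, giving the in-memory study layout that
#' [extract_feature_matrix()] consumes.
#'
#' @param path Path to a manifest CSV.
#' @return The manifest tibble with an added `trace` list-column.
#' @export
load_study <- function(path) {
  manifest <- read_manifest(path)
  manifest$trace <- purrr::map(manifest$trace_path, read_hr_trace)
  manifest
}

#' Write a feature matrix
#'
#' Writes a feature matrix as CSV with header
#' `subject_id,emotion,<53 canonical feature names>`. Values are written with
#' full double precision so read/write round-trips are lossless at 1e-9
#' relative tolerance.
#'
#' @param matrix Feature-matrix tibble: columns `subject_id`, `emotion` and the
#'   53 canonical features in order (as produced by [extract_feature_matrix()]).
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(matrix, path) {
  expected <- c("subject_id", "emotion", hr_feature_names())
  if (!identical(names(matrix), expected)) {
    missing <- setdiff(expected, names(matrix))
    extra <- setdiff(names(matrix), expected)
    abort(paste0(
      "feature matrix must have exactly the columns subject_id, emotion and ",
      "the 53 canonical features in order",
      if (length(missing)) paste0("; missing: ", paste(missing, collapse = ", ")),
      if (length(extra)) paste0("; unexpected: ", paste(extra, collapse = ", "))
    ), class = "hr_shape_error")
  }
  vals <- as.matrix(matrix[hr_feature_names()])
  if (!all(is.finite(vals))) {
    abort("feature matrix contains non-finite values", class = "hr_shape_error")
  }
  readr::write_csv(matrix, path, progress = FALSE)
  invisible(path)
}

#' Read a feature matrix
#'
#' @param path Path to a feature-matrix CSV written by [write_feature_matrix()].
#' @return A feature-matrix tibble.
#' @export
read_feature_matrix <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  expected <- c("subject_id", "emotion", hr_feature_names())
  if (!identical(names(df), expected)) {
    abort(paste0("feature-matrix header of ", path,
                 " does not match the canonical 53-feature layout"),
          class = "hr_format_error")
  }
  df$subject_id <- as.character(df$subject_id)
  tibble::as_tibble(df)
}
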