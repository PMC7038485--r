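# The canonical 53-feature order is frozen: 22 features computed on the
# original target-segment signal, then 31 computed on the baseline-normalized
# signal. Any reordering breaks stored feature matrices, so tests checksum it.

stat5 <- function(prefix) paste0(prefix, c("max", "min", "median", "mean", "std"))

.hr_original_names <- c(
  "rate_diff1_mean", "rate_diff2_mean", "rate_range", "rate_data_entropy",
  "max_ratio", "min_ratio", "rate_adjacent_rms",
  stat5("rate_down_time_"),
  stat5("rate_up_time_"),
  stat5("rate_time_continue_")
)

.hr_normalized_names <- c(
  stat5("rate_down_slope_"),
  paste0("rate_up_amplitude_", c("max", "median", "mean", "std")),
  stat5("rate_down_amplitude_"),
  stat5("rate_25_mean_"),
  "rate_data_mean", "rate_data_var",
  paste0("rate_norm_diff1_", c("max", "min", "std", "median", "mean")),
  paste0("rate_norm_diff2_", c("max", "min", "std", "median", "mean"))
)

#' Canonical feature names
#'
#' The frozen, ordered list of the 53 feature names: 22 from the original
#' target-segment heart-rate signal followed by 31 from the baseline-normalized
#' signal. This order defines the column layout of every feature matrix the
#' package reads or writes; `FEATURES.md` in the package source maps each name
#' to its formula.
#'
#' @param subset One of `"all"` (default), `"original"` or `"normalized"`.
#' @return A character vector (length 53, 22 or 31).
#' @export
#' @examples
#' length(hr_feature_names())
#' head(hr_feature_names("normalized"))
hr_feature_names <- function(subset = c("all", "original", "normalized")) {
  subset <- match.arg(subset)
  switch(subset,
    all = c(.hr_original_names, .hr_normalized_names),
    original = .hr_original_names,
    normalized = .hr_normalized_names
  )
}

#' Emotion label vocabulary
#'
#' The three emotion classes a session's target segment may carry.
#'
#' @return Character vector `c("neutral", "happy", "sad")`.
#' @export
hr_emotions <- function() c("neutral", "happy", "sad")
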