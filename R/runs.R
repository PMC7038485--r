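#' Detect monotone runs in a signal
#'
#' Partitions the consecutive sample-pair differences of a series by sign:
#' each maximal stretch of same-sign differences is one run — `up` for
#' positive, `down` for negative, `flat` for zero (the plateaus an
#' integer-valued heart-rate trace produces). Runs tile the series with shared
#' endpoints, so every run spans at least two samples and run durations sum to
#' `(N - 1) * dt_s`. Run durations, amplitudes and slopes are the basis of the
#' duration/amplitude/slope feature groups.
#'
#' @param values Numeric series of length >= 2.
#' @param dt_s Sampling interval in seconds (default 1).
#' @return A tibble with one row per run: `direction` (`"up"`, `"down"`,
#'   `"flat"`), `start_idx` and `end_idx` (1-based, inclusive), `duration_s`
#'   (`(end_idx - start_idx) * dt_s`) and `amplitude`
#'   (`values[end_idx] - values[start_idx]`).
#' @export
#' @examples
#' detect_runs(c(70, 71, 72, 72, 72, 71))
detect_runs <- function(values, dt_s = 1) {
  n <- length(values)
  if (n < 2) {
    abort("run detection needs at least 2 samples",
          class = "hr_insufficient_data_error")
  }
  sgn <- sign(diff(values))
  r <- rle(sgn)
  ends <- cumsum(r$lengths)       # index into the difference vector
  starts <- c(1L, head(ends, -1L) + 1L)
  start_idx <- starts             # difference i joins samples i and i+1
  end_idx <- ends + 1L
  tibble::tibble(
    direction = c("down", "flat", "up")[r$values + 2L],
    start_idx = start_idx,
    end_idx = end_idx,
    duration_s = (end_idx - start_idx) * dt_s,
    amplitude = values[end_idx] - values[start_idx]
  )
}
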