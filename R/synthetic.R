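#' Simulation scenario configuration
#'
#' Parameters of the emotion-conditioned heart-rate simulator. Defaults
#' emulate the reference study design: 25 subjects, three 'neutral + target'
#' sessions each (neutral+neutral, neutral+happy, neutral+sad), per-second
#' integer BPM traces, neutral segments of 68-122 s and target segments of
#' 53-233 s (the published video-duration ranges). Each segment is an AR(1)
#' process around the subject baseline; the target level is shifted by the
#' emotion effect and its innovation scaled by the emotion variance
#' multiplier. Effect directions follow the cited physiology (happiness
#' lowers heart rate relative to neutral and sad); the magnitudes are scenario
#' parameters, not estimates, since no effect sizes are published. Sadness
#' additionally inflates variance so the happy-vs-sad contrast is not a pure
#' mean-shift problem. Integer rounding of the stored BPM values produces the
#' plateaus on which the flat-run features depend.
#'
#' @param n_subjects Number of subjects (default 25).
#' @param subject_baseline_mean,subject_baseline_sd Population distribution of
#'   subject resting heart rate, BPM (defaults 72 and 6).
#' @param emotion_mean_shift Named BPM shifts of the target-segment level
#'   (defaults neutral 0, happy -2, sad +1).
#' @param emotion_sd_scale Named innovation-sd multipliers (defaults 1, 1.2,
#'   1.5).
#' @param ar_coefficient AR(1) coefficient, in `[0, 1)` (default 0.9).
#' @param innovation_sd AR(1) innovation standard deviation, BPM (default 0.8).
#' @param neutral_duration_range_s,target_duration_range_s Inclusive integer
#'   second ranges from which segment durations are drawn uniformly.
#' @param quantize_integer Round stored BPM values to integers (default TRUE).
#' @param seed Master seed of the simulation.
#' @return A list of class `hr_sim_config`.
#' @export
simulation_config <- function(n_subjects = 25L,
                              subject_baseline_mean = 72,
                              subject_baseline_sd = 6,
                              emotion_mean_shift = c(neutral = 0, happy = -2,
                                                     sad = 1),
                              emotion_sd_scale = c(neutral = 1, happy = 1.2,
                                                   sad = 1.5),
                              ar_coefficient = 0.9,
                              innovation_sd = 0.8,
                              neutral_duration_range_s = c(68L, 122L),
                              target_duration_range_s = c(53L, 233L),
                              quantize_integer = TRUE,
                              seed = 1L) {
  if (ar_coefficient < 0 || ar_coefficient >= 1) {
    abort("`ar_coefficient` must lie in [0, 1)", class = "hr_parameter_error")
  }
  if (innovation_sd <= 0 || subject_baseline_sd <= 0) {
    abort("standard deviations must be positive", class = "hr_parameter_error")
  }
  if (!all(hr_emotions() %in% names(emotion_mean_shift)) ||
      !all(hr_emotions() %in% names(emotion_sd_scale))) {
    abort("`emotion_mean_shift` and `emotion_sd_scale` need entries for neutral, happy and sad",
          class = "hr_parameter_error")
  }
  for (rng in list(neutral_duration_range_s, target_duration_range_s)) {
    if (length(rng) != 2 || rng[1] > rng[2] || rng[1] < 10) {
      abort("duration ranges must be [lo, hi] with 10 <= lo <= hi",
            class = "hr_parameter_error")
    }
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      subject_baseline_mean = subject_baseline_mean,
      subject_baseline_sd = subject_baseline_sd,
      emotion_mean_shift = emotion_mean_shift[hr_emotions()],
      emotion_sd_scale = emotion_sd_scale[hr_emotions()],
      ar_coefficient = ar_coefficient,
      innovation_sd = innovation_sd,
      neutral_duration_range_s = as.integer(neutral_duration_range_s),
      target_duration_range_s = as.integer(target_duration_range_s),
      quantize_integer = isTRUE(quantize_integer),
      seed = as.integer(seed)
    ),
    class = "hr_sim_config"
  )
}

#' Read a simulation scenario from a flat YAML file
#'
#' Keys are the arguments of [simulation_config()]; unknown keys are an error.
#'
#' @param path Path to the YAML file.
#' @return A list of class `hr_sim_config`.
#' @export
read_simulation_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(simulation_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    abort(paste0("unknown scenario key(s): ", paste(unknown, collapse = ", ")),
          class = "hr_config_error")
  }
  for (nm in c("emotion_mean_shift", "emotion_sd_scale")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  }
  do.call(simulation_config, raw)
}

# Stationary AR(1) sample path around `level`; the first value is drawn from
# the stationary distribution so there is no burn-in transient.
ar1_path <- function(n, level, phi, sd_innov) {
  d <- numeric(n)
  d[1] <- rnorm(1, 0, sd_innov / sqrt(1 - phi^2))
  eps <- rnorm(n - 1, 0, sd_innov)
  for (t in 2:n) d[t] <- phi * d[t - 1] + eps[t - 1]
  level + d
}

#' Simulate one 'neutral + target' session
#'
#' Generates a per-second BPM trace: a neutral AR(1) segment around the
#' subject baseline followed by a target AR(1) segment around
#' `baseline + shift(emotion)` with emotion-scaled innovation sd, concatenated
#' on a common 1 Hz grid. Draws from the current RNG state; seed externally
#' (e.g. [withr::with_seed()]) for reproducibility — [simulate_study()] does
#' this for you.
#'
#' @param subject_baseline Subject resting heart rate, BPM.
#' @param emotion Target-segment emotion label.
#' @param config A [simulation_config()].
#' @param neutral_duration_s,target_duration_s Optional fixed durations in
#'   seconds; drawn uniformly from the configured ranges when `NULL`.
#' @param subject_id Identifier carried into the session row.
#' @return One-row session tibble: `subject_id`, `emotion`,
#'   `neutral_duration_s`, `target_duration_s`, `trace_path` (relative file
#'   name) and `trace` (list-column trace tibble).
#' @export
simulate_session <- function(subject_baseline, emotion,
                             config = simulation_config(),
                             neutral_duration_s = NULL,
                             target_duration_s = NULL,
                             subject_id = "s01") {
  stopifnot(inherits(config, "hr_sim_config"))
  if (!emotion %in% hr_emotions()) {
    abort(paste0("unknown emotion: ", emotion), class = "hr_vocabulary_error")
  }
  nd <- neutral_duration_s %||%
    sample(config$neutral_duration_range_s[1]:config$neutral_duration_range_s[2], 1)
  td <- target_duration_s %||%
    sample(config$target_duration_range_s[1]:config$target_duration_range_s[2], 1)
  phi <- config$ar_coefficient
  neutral <- ar1_path(nd, subject_baseline, phi, config$innovation_sd)
  target <- ar1_path(
    td,
    subject_baseline + config$emotion_mean_shift[[emotion]],
    phi,
    config$innovation_sd * config$emotion_sd_scale[[emotion]]
  )
  values <- c(neutral, target)
  if (config$quantize_integer) values <- round(values)
  values <- pmin(pmax(values, 21), 249)   # keep within the plausible BPM band
  trace <- tibble::tibble(time_s = seq_along(values) - 1, hr_bpm = values)
  attr(trace, "dt_s") <- 1
  tibble::tibble(
    subject_id = subject_id,
    emotion = emotion,
    neutral_duration_s = nd,
    target_duration_s = td,
    trace_path = sprintf("trace_%s_%s.csv", subject_id, emotion),
    trace = list(trace)
  )
}

#' Simulate a full study
#'
#' Generates `n_subjects` subjects, each with three sessions
#' (neutral+neutral, neutral+happy, neutral+sad), deterministically under the
#' scenario seed. With defaults this emulates the reference design: 75
#' target-emotion samples overall, 50 per pairwise task.
#'
#' @param config A [simulation_config()].
#' @return A session tibble of class `hr_study` (one row per session, with
#'   `trace` list-column); the scenario is attached as attribute `sim_config`.
#' @export
#' @examples
#' study <- simulate_study(simulation_config(n_subjects = 3, seed = 7))
#' nrow(study)
simulate_study <- function(config = simulation_config()) {
  stopifnot(inherits(config, "hr_sim_config"))
  study <- withr::with_seed(config$seed, {
    purrr::map(seq_len(config$n_subjects), function(s) {
      sid <- sprintf("s%02d", s)
      baseline <- min(max(rnorm(1, config$subject_baseline_mean,
                                config$subject_baseline_sd), 45), 120)
      purrr::map(hr_emotions(), function(em) {
        simulate_session(baseline, em, config, subject_id = sid)
      }) |> dplyr::bind_rows()
    }) |> dplyr::bind_rows()
  })
  attr(study, "sim_config") <- config
  class(study) <- c("hr_study", class(study))
  study
}

#' Write a simulated study to disk
#'
#' Writes one trace CSV per session, the manifest CSV, and a `scenario.yaml`
#' snapshot of the generating parameters, in the formats [read_manifest()]
#' and [read_hr_trace()] consume.
#'
#' @param study An `hr_study` tibble from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(is.data.frame(study), "trace" %in% names(study))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  purrr::walk2(study$trace, study$trace_path, function(tr, p) {
    write_hr_trace(tr, file.path(dir, p))
  })
  manifest_path <- file.path(dir, "manifest.csv")
  write_manifest(study, manifest_path)
  cfg <- attr(study, "sim_config")
  if (!is.null(cfg)) {
    out <- unclass(cfg)
    out$emotion_mean_shift <- as.list(out$emotion_mean_shift)
    out$emotion_sd_scale <- as.list(out$emotion_sd_scale)
    yaml::write_yaml(out, file.path(dir, "scenario.yaml"))
  }
  invisible(manifest_path)
}

#' Recover the planted emotion effects from a feature matrix
#'
#' The normalized-signal mean (`rate_data_mean`) of a target segment estimates
#' the planted level shift of its emotion, since the subject baseline has been
#' subtracted. This report compares the across-subject mean of that feature
#' per emotion with the scenario's planted shift — a parameter-recovery check
#' for the whole simulate -> segment -> normalize -> featurize chain.
#'
#' @param matrix Feature-matrix tibble from a simulated study.
#' @param config The [simulation_config()] that generated the study.
#' @return A tibble with one row per emotion: `emotion`, `n`, `estimate`
#'   (mean `rate_data_mean`), `planted` (configured shift) and `bias`
#'   (`estimate - planted`).
#' @export
recover_planted_effect <- function(matrix, config) {
  stopifnot(inherits(config, "hr_sim_config"))
  matrix |>
    dplyr::group_by(.data$emotion) |>
    dplyr::summarise(n = dplyr::n(),
                     estimate = mean(.data$rate_data_mean),
                     .groups = "drop") |>
    dplyr::mutate(planted = config$emotion_mean_shift[.data$emotion],
                  bias = .data$estimate - .data$planted) |>
    dplyr::arrange(match(.data$emotion, hr_emotions()))
}
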