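test_that("run detection partitions difference signs into tiling runs", {
  runs <- detect_runs(c(70, 71, 72, 72, 72, 71))
  expect_equal(runs$direction, c("up", "flat", "down"))
  expect_equal(runs$start_idx, c(1, 3, 5))
  expect_equal(runs$end_idx, c(3, 5, 6))
  expect_equal(runs$duration_s, c(2, 2, 1))
  expect_equal(runs$amplitude, c(2, 0, -1))

  mono <- detect_runs(1:50)
  expect_equal(nrow(mono), 1)
  expect_equal(mono$direction, "up")
  expect_equal(mono$amplitude, 49)
})

test_that("run durations always tile the series: sum == (N-1)*dt", {
  withr::with_seed(21, {
    for (rep in 1:30) {
      n <- sample(10:200, 1)
      dt <- sample(c(1, 0.5, 2), 1)
      v <- random_hr_series(n)
      runs <- detect_runs(v, dt)
      expect_equal(sum(runs$duration_s), (n - 1) * dt)
      # direction signs match amplitudes
      expect_true(all(runs$amplitude[runs$direction == "up"] > 0))
      expect_true(all(runs$amplitude[runs$direction == "down"] < 0))
      expect_true(all(runs$amplitude[runs$direction == "flat"] == 0))
      expect_true(all(runs$end_idx > runs$start_idx))
      # shared endpoints: next run starts where the previous ended
      if (nrow(runs) > 1) {
        expect_equal(runs$start_idx[-1], runs$end_idx[-nrow(runs)])
      }
    }
  })
})

test_that("hand-worked original-signal features are reproduced", {
  cfg <- pipeline_config()
  v <- c(60, 65, 70, 80, 75, 70, 72, 74, 76, 78)
  f <- extract_original_features(v, cfg)
  expect_equal(unname(f["rate_range"]), 20)

  # 4 distinct values equally often -> 2 bits
  u <- rep(c(70, 72, 74, 76), 25)
  fu <- extract_original_features(u, cfg)
  expect_equal(unname(fu["rate_data_entropy"]), 2)

  # degenerate constant series, worked by hand
  cc <- extract_original_features(rep(70, 100), cfg)
  expect_equal(unname(cc["rate_diff1_mean"]), 0)
  expect_equal(unname(cc["rate_diff2_mean"]), 0)
  expect_equal(unname(cc["rate_range"]), 0)
  expect_equal(unname(cc["rate_data_entropy"]), 0)
  expect_equal(unname(cc["max_ratio"]), 0.7)
  expect_equal(unname(cc["min_ratio"]), 0.7)
  expect_equal(unname(cc["rate_adjacent_rms"]), 0)
  expect_true(all(cc[stat5("rate_up_time_")] == 0))
  expect_true(all(cc[stat5("rate_down_time_")] == 0))
  expect_equal(unname(cc["rate_time_continue_max"]), 99)

  expect_error(extract_original_features(rep(70, 5), cfg),
               class = "hr_insufficient_data_error")
})

test_that("hand-worked normalized-signal features are reproduced", {
  cfg <- pipeline_config(moving_avg_window = 2)
  f <- extract_normalized_features(c(0, 2, 4, 4, 2), cfg)
  expect_equal(unname(f["rate_down_slope_max"]), 2)
  expect_equal(unname(f["rate_up_amplitude_max"]), 4)
  expect_equal(unname(f["rate_down_amplitude_max"]), 2)
  expect_equal(unname(f["rate_data_mean"]), 2.4)

  z <- extract_normalized_features(rep(0, 100), pipeline_config())
  expect_length(z, 31)
  expect_true(all(z == 0))

  expect_error(extract_normalized_features(rep(0, 20), pipeline_config()),
               class = "hr_insufficient_data_error")
})

test_that("every feature matches the independent naive oracle", {
  cfg <- pipeline_config()
  withr::with_seed(99, {
    for (rep in 1:20) {
      n <- sample(60:500, 1)
      v <- random_hr_series(n)
      baseline <- runif(1, 60, 90)
      got <- c(extract_original_features(v, cfg),
               extract_normalized_features(v - baseline, cfg))
      want <- naive_all_features(v, baseline)
      rel <- abs(got - want) / pmax(abs(want), 1e-12)
      expect_lt(max(rel), 1e-9)
    }
  })
})

test_that("signed-difference mode matches the printed telescoping formulas", {
  cfg <- pipeline_config(diff_absolute = FALSE)
  v <- random_hr_series(80)
  f <- extract_original_features(v, cfg)
  n <- length(v)
  expect_equal(unname(f["rate_diff1_mean"]), (v[n] - v[1]) / (n - 1))
  expect_equal(unname(f["rate_diff2_mean"]),
               (v[n] + v[n - 1] - v[1] - v[2]) / (n - 2))
})

test_that("a full session yields the 53-vector with canonical header", {
  tr <- tibble::tibble(time_s = 0:140,
                       hr_bpm = random_hr_series(141))
  seg <- segment_session(tr, 70, 71, emotion = "happy", subject_id = "s01")
  fv <- extract_features(seg)
  expect_identical(names(fv), c("subject_id", "emotion", hr_feature_names()))
  expect_true(all(is.finite(as.matrix(fv[hr_feature_names()]))))
  expect_equal(fv$emotion, "happy")
})

test_that("a constant session offset moves only the max/min ratios", {
  withr::with_seed(31, {
    v <- random_hr_series(160)
    tr1 <- tibble::tibble(time_s = 0:159, hr_bpm = v)
    tr2 <- tibble::tibble(time_s = 0:159, hr_bpm = v + 7)
    f1 <- extract_features(segment_session(tr1, 75, 85, "happy", "a"))
    f2 <- extract_features(segment_session(tr2, 75, 85, "happy", "a"))
    nm <- hr_feature_names()
    shifted <- c("max_ratio", "min_ratio")
    same <- setdiff(nm, shifted)
    expect_equal(as.numeric(f2[same]), as.numeric(f1[same]))
    n_target <- 85
    expect_equal(f2$max_ratio, f1$max_ratio + 7 / n_target)
    expect_equal(f2$min_ratio, f1$min_ratio + 7 / n_target)
  })
})

test_that("normalized features scale correctly and stay finite", {
  cfg <- pipeline_config()
  withr::with_seed(17, {
    x <- random_hr_series(120) - 75
    for (c_scale in c(0.5, 2, 10)) {
      f1 <- extract_normalized_features(x, cfg)
      f2 <- extract_normalized_features(c_scale * x, cfg)
      expect_false(any(is.nan(f2)))
      linear <- setdiff(hr_feature_names("normalized"), "rate_data_var")
      expect_equal(unname(f2[linear]), unname(c_scale * f1[linear]),
                   tolerance = 1e-12)
      expect_equal(unname(f2["rate_data_var"]),
                   unname(c_scale^2 * f1["rate_data_var"]), tolerance = 1e-12)
    }
  })
})

test_that("order-free features are invariant under time reversal", {
  cfg <- pipeline_config()
  withr::with_seed(13, {
    v <- random_hr_series(150)
    f <- extract_original_features(v, cfg)
    fr <- extract_original_features(rev(v), cfg)
    inv <- c("rate_range", "rate_data_entropy", "max_ratio", "min_ratio")
    expect_equal(unname(f[inv]), unname(fr[inv]))
    x <- v - mean(v[1:70])
    g <- extract_normalized_features(x, cfg)
    gr <- extract_normalized_features(rev(x), cfg)
    expect_equal(unname(g[c("rate_data_mean", "rate_data_var")]),
                 unname(gr[c("rate_data_mean", "rate_data_var")]))
  })
})

test_that("entropy respects its bounds and the log-base option", {
  withr::with_seed(41, {
    for (rep in 1:20) {
      v <- random_hr_series(sample(30:300, 1))
      h <- extract_original_features(v, pipeline_config())["rate_data_entropy"]
      expect_gte(h, 0)
      expect_lte(h, log2(length(unique(round(v)))) + 1e-12)
      hn <- extract_original_features(
        v, pipeline_config(entropy_log_base = exp(1)))["rate_data_entropy"]
      expect_equal(unname(hn), unname(h * log(2)), tolerance = 1e-12)
    }
  })
})

test_that("feature matrix extraction skips bad sessions with a warning", {
  study <- simulate_study(simulation_config(n_subjects = 3, seed = 2))
  study$target_duration_s[2] <- 5   # below the 10-sample minimum
  expect_warning(fm <- extract_feature_matrix(study), "skipping session")
  expect_equal(nrow(fm), 8)
  expect_identical(names(fm), c("subject_id", "emotion", hr_feature_names()))
})
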