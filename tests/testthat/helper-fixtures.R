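# In-code fixtures: synthetic feature matrices with a planted class signal
# for selection/modeling tests.

# Feature matrix with every canonical column ~ N(0,1) noise except a planted
# column separating the classes by `delta`.
planted_matrix <- function(n_per_class, classes = c("neutral", "happy"),
                           planted = "rate_data_mean", delta = 1, sd = 1,
                           seed = 1) {
  withr::with_seed(seed, {
    n <- n_per_class * length(classes)
    emotion <- rep(classes, each = n_per_class)
    X <- matrix(rnorm(n * 53, 0, sd), n, 53,
                dimnames = list(NULL, hr_feature_names()))
    X[, planted] <- X[, planted] + delta * (match(emotion, classes) - 1)
    dplyr::bind_cols(
      tibble::tibble(
        subject_id = sprintf("s%02d", rep(seq_len(n_per_class),
                                          length(classes))),
        emotion = emotion
      ),
      tibble::as_tibble(X)
    )
  })
}
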