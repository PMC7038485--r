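# Independent naive implementations of every feature, written as plain loops
# over the definitions. These deliberately share no code with the package
# internals: run detection walks the series sample by sample, summaries are
# written out longhand, and the moving average is a per-window mean.

naive_stat5 <- function(x) {
  if (length(x) == 0) return(c(0, 0, 0, 0, 0))
  m <- sum(x) / length(x)
  c(max(x), min(x), median(x), m, sqrt(sum((x - m)^2) / length(x)))
}

naive_runs <- function(v, dt = 1) {
  n <- length(v)
  runs <- list()
  i <- 1
  while (i < n) {
    s <- sign(v[i + 1] - v[i])
    j <- i
    while (j < n && sign(v[j + 1] - v[j]) == s) j <- j + 1
    runs[[length(runs) + 1]] <- list(
      dir = s, start = i, end = j,
      dur = (j - i) * dt, amp = v[j] - v[i]
    )
    i <- j
  }
  runs
}

naive_run_durations <- function(v, dir, dt = 1) {
  runs <- naive_runs(v, dt)
  out <- numeric(0)
  for (r in runs) if (r$dir == dir) out <- c(out, r$dur)
  out
}

naive_run_amplitudes <- function(v, dir, dt = 1) {
  runs <- naive_runs(v, dt)
  out <- numeric(0)
  for (r in runs) if (r$dir == dir) out <- c(out, r$amp)
  out
}

naive_entropy <- function(v, base = 2) {
  v <- round(v)
  h <- 0
  for (val in unique(v)) {
    p <- sum(v == val) / length(v)
    h <- h - p * log(p, base = base)
  }
  h
}

naive_original <- function(v, dt = 1, diff_absolute = TRUE, base = 2) {
  n <- length(v)
  d1 <- numeric(n - 1)
  for (i in 1:(n - 1)) d1[i] <- v[i + 1] - v[i]
  d2 <- numeric(n - 2)
  for (i in 1:(n - 2)) d2[i] <- v[i + 2] - v[i]
  af <- function(d) if (diff_absolute) mean(abs(d)) else mean(d)
  c(
    af(d1), af(d2), max(v) - min(v), naive_entropy(v, base),
    max(v) / n, min(v) / n, sqrt(sum(d1^2) / (n - 1)),
    naive_stat5(naive_run_durations(v, -1, dt)),
    naive_stat5(naive_run_durations(v, 1, dt)),
    naive_stat5(naive_run_durations(v, 0, dt))
  )
}

naive_diff_stats <- function(d, diff_absolute = TRUE) {
  m <- sum(d) / length(d)
  c(max(d), min(d), sqrt(sum((d - m)^2) / length(d)), median(d),
    if (diff_absolute) mean(abs(d)) else m)
}

naive_normalized <- function(x, dt = 1, diff_absolute = TRUE, window = 25) {
  n <- length(x)
  runs <- naive_runs(x, dt)
  slopes <- numeric(0)
  up_amp <- numeric(0)
  down_amp <- numeric(0)
  for (r in runs) {
    if (r$dir == -1) {
      slopes <- c(slopes, abs(r$amp) / r$dur)
      down_amp <- c(down_amp, abs(r$amp))
    }
    if (r$dir == 1) up_amp <- c(up_amp, r$amp)
  }
  ma <- numeric(n - window + 1)
  for (i in window:n) ma[i - window + 1] <- mean(x[(i - window + 1):i])
  d1 <- x[2:n] - x[1:(n - 1)]
  d2 <- x[3:n] - x[1:(n - 2)]
  up5 <- naive_stat5(up_amp)
  c(
    naive_stat5(slopes),
    up5[c(1, 3, 4, 5)],
    naive_stat5(down_amp),
    naive_stat5(ma),
    mean(x), sum((x - mean(x))^2) / (n - 1),
    naive_diff_stats(d1, diff_absolute),
    naive_diff_stats(d2, diff_absolute)
  )
}

naive_all_features <- function(target, baseline, dt = 1, diff_absolute = TRUE,
                               base = 2, window = 25) {
  c(naive_original(target, dt, diff_absolute, base),
    naive_normalized(target - baseline, dt, diff_absolute, window))
}

# Random integer heart-rate series with plateaus, the phenomenology the
# feature set assumes (small steps, flat stretches).
random_hr_series <- function(n, start = 75) {
  pmin(pmax(start + cumsum(sample(c(-2, -1, 0, 0, 1, 2), n, replace = TRUE)),
            30), 200)
}

# canonical five-stat name expansion (mirrors the package's internal naming)
stat5 <- function(prefix) paste0(prefix, c("max", "min", "median", "mean", "std"))
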