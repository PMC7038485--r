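# Canonical feature set

Every target-emotion sample is described by 53 features in a frozen order:
22 computed on the original (un-normalized) target-segment heart rate
`X_1..X_N` (BPM, 1 sample/s unless stated otherwise) and 31 on the
baseline-normalized signal `X~_i = X_i - mean(neutral segment)`.

Conventions used throughout:

- A **run** is a maximal stretch of consecutive samples whose pairwise
  differences share one sign: *up* (+), *down* (−), *flat* (0, a plateau).
  Runs tile the series; run duration is `(end - start) * dt`, run amplitude
  is `X[end] - X[start]`.
- Five-number summaries (`max/min/median/mean/std`) use the population
  standard deviation (divisor *n*). An empty run collection yields all five
  statistics 0 (sentinel); a single element yields std 0.
- With the default `diff_absolute = TRUE`, the four *mean-of-difference*
  features use the mean **absolute** difference; the max/min/std/median
  members of the difference-series groups summarize the signed series.

## Features from the original signal (22)

| # | Name | Definition |
|---|------|------------|
| 1 | `rate_diff1_mean` | mean (abs.) first difference: `1/(N-1) Σ |X_{n+1} - X_n|` |
| 2 | `rate_diff2_mean` | mean (abs.) second difference: `1/(N-2) Σ |X_{n+2} - X_n|` |
| 3 | `rate_range` | `max(X) - min(X)` |
| 4 | `rate_data_entropy` | Shannon entropy `−Σ p(x_i) log p(x_i)` of the empirical distribution of distinct (integer-quantized) values; base 2 by default |
| 5 | `max_ratio` | `max(X) / N` |
| 6 | `min_ratio` | `min(X) / N` |
| 7 | `rate_adjacent_rms` | RMS of adjacent differences: `sqrt(Σ (X_{i+1} - X_i)² / (N-1))` |
| 8–12 | `rate_down_time_{max,min,median,mean,std}` | summaries of down-run durations (s) |
| 13–17 | `rate_up_time_{max,min,median,mean,std}` | summaries of up-run durations (s) |
| 18–22 | `rate_time_continue_{max,min,median,mean,std}` | summaries of flat-run (plateau) durations (s) |

## Features from the normalized signal (31)

| # | Name | Definition |
|---|------|------------|
| 23–27 | `rate_down_slope_{max,min,median,mean,std}` | summaries of per-down-run slopes, `|amplitude| / duration` (positive magnitudes) |
| 28–31 | `rate_up_amplitude_{max,median,mean,std}` | summaries of per-up-run amplitudes (no `min` member, by construction of the canonical set) |
| 32–36 | `rate_down_amplitude_{max,min,median,mean,std}` | summaries of per-down-run absolute amplitudes |
| 37–41 | `rate_25_mean_{max,min,median,mean,std}` | summaries of the 25-sample moving average ("valid" mode, output length `N - 24`) |
| 42 | `rate_data_mean` | mean of the normalized signal, `1/N Σ X~_i` |
| 43 | `rate_data_var` | unbiased sample variance of the normalized signal (divisor `N - 1`) |
| 44–48 | `rate_norm_diff1_{max,min,std,median,mean}` | summaries of the first-difference series of the normalized signal |
| 49–53 | `rate_norm_diff2_{max,min,std,median,mean}` | summaries of the second-difference series of the normalized signal |
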