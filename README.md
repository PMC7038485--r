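# hrmood

Emotion recognition from wearable heart-rate traces.

Wrist wearables report heart rate continuously, and heart rate shifts with
emotional state: happiness tends to lower it relative to a neutral mood,
sadness to raise it and make it more variable. `hrmood` implements a
heart-rate-only emotion classification pipeline for **'neutral + target'**
sessions — recordings whose first segment (neutral stimulus) supplies a
subject baseline and whose second segment carries the target emotion
(neutral, happy, or sad):

1. **Segment** each session at the neutral/target cut (half-open grid).
2. **Normalize**: `Rate_normal = Rate_original − Rate_neutral_mean`, removing
   between-subject differences in resting heart rate.
3. **Extract 53 features** per sample — 22 from the original target signal
   (difference statistics, range, value entropy `H(X) = −Σ p(xᵢ) log p(xᵢ)`,
   max/min-to-length ratios, adjacent-difference RMS, and five-number
   summaries of up/down/plateau run durations) and 31 from the normalized
   signal (down-run slope `|ΔA|/Δt` and amplitude summaries, 25-sample
   moving-average summaries, mean and variance, first/second-difference
   summaries). See `FEATURES.md` for the full table.
4. **Select top-k features** by nearest-neighbour mutual information with the
   label (3 neighbours, seeded tie-breaking jitter), k ∈ {20, 16, 12, 10, 8, 5}.
5. **Evaluate five classifiers** (kNN, random forest, decision tree, gradient
   boosting, AdaBoost) under leave-one-out cross-validation
   (`Accuracy = N_correct / N_total`) on four tasks (three pairwise + three-class),
   reporting each cell as the mode of ten repeated runs.

Because no subject-level dataset is distributed for this design, the package
includes an emotion-conditioned session simulator: per-second integer BPM
traces from a stationary AR(1) process around a subject baseline, with
emotion-dependent level shifts and variance scaling, at the published study
scale (25 subjects × 3 sessions, segment durations 53–233 s). Everything is
tidyverse-native: data frames in, tibbles out, `tidy()`/`glance()` methods
and `autoplot()` for every result type.

## Worked example

```r
library(hrmood)

# a study-scale synthetic dataset: 25 subjects x 3 'neutral + target' sessions
study    <- simulate_study(simulation_config(seed = 1))
features <- extract_feature_matrix(study)
dim(features)
#> [1] 75 55     # 75 samples: subject_id, emotion + 53 features

# which features carry information about neutral vs happy?
sub <- dplyr::filter(features, emotion %in% c("neutral", "happy"))
report_top_features(score_mutual_information(sub, rng_seed = 1), 5)
#> # A tibble: 5 × 2
#>   feature              score
#>   <chr>                <dbl>
#> 1 rate_norm_diff2_std  0.487
#> 2 rate_adjacent_rms    0.477
#> 3 rate_norm_diff1_std  0.477
#> 4 rate_diff2_mean      0.428
#> 5 rate_norm_diff2_mean 0.428

# one evaluation cell: AdaBoost, top-8 features, leave-one-out
loocv_evaluate(features, "neutral_vs_happy", "adaboost", k = 8,
               rng_seed = 1)$accuracy
#> [1] 0.78

# the full 4-task x 5-classifier x 6-k grid (~10 min on one core)
grid <- run_experiment(features, pipeline_config(rng_seed = 1))
summarize_results(grid)$best
#> # A tibble: 4 × 4
#>   task             classifier            k mode_accuracy
#>   <chr>            <chr>             <int>         <dbl>
#> 1 happy_vs_sad     gradient_boosting    20         0.98
#> 2 neutral_vs_happy knn                  20         0.94
#> 3 neutral_vs_sad   decision_tree        20         1
#> 4 three_class      knn                  10         0.933
```

The mode accuracies are the most frequent value among ten repeated LOOCV
runs of each cell (smallest on ties; median if all ten differ — see
`mode_note`). `tidy(grid)` exposes all per-run accuracies, `autoplot(grid)`
draws mode accuracy against k per task, and `write_results()` /
`write_feature_matrix()` / `write_study()` persist every artifact as plain
CSV. A thin command-line wrapper with `simulate | extract | evaluate | all`
subcommands is installed at `inst/cli/hrmood.R`.

On synthetic data these accuracies measure the pipeline's ability to recover
*planted* effects (happy −2 BPM, sad +1 BPM with extra variance, by
default); they are not estimates of performance on real wearable recordings.

## Package layout

- `R/` — implementation (io, preprocessing, runs/features, selection,
  classifiers, modeling, synthetic generator, tidiers, plots, pipeline).
- `tests/testthat/` — unit + property tests with independent naive oracles
  for all 53 features, and `test-acceptance.R` with the end-to-end checks.
- `vignettes/hrmood-methods.Rmd` — the methods vignette: model assumptions,
  numerical conventions, protocol decisions, limitations.
- `FEATURES.md` — canonical feature-name-to-formula table.
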