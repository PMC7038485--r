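# Nearest-neighbour mutual information between one continuous feature and a
# discrete label (Ross 2014, "Mutual Information between Discrete and
# Continuous Data Sets"). For sample i with label y_i, r_i is the distance to
# its k-th nearest neighbour among same-label points (k shrunk to
# class_count - 1 for small classes) and m_i counts all points strictly within
# r_i (self included):
#   MI = psi(n) + <psi(k_i)> - <psi(class_count_i)> - <psi(m_i)>, in nats.
# Points whose label is unique in the sample are dropped. The feature is 1-D,
# so same-label k-NN distances come from sliding windows over the sorted class
# values and the within-radius counts from findInterval — O(n log n) overall.
# Negative estimates (finite-sample noise) are clamped to zero.
mi_cont_disc <- function(x, y, n_neighbors = 3L) {
  n <- length(x)
  ord <- order(x)
  xs <- x[ord]
  ys <- y[ord]
  r <- rep(NA_real_, n)
  kk <- rep(NA_real_, n)
  cls_n <- rep(NA_real_, n)
  for (cl in unique(ys)) {
    idx <- which(ys == cl)
    cnt <- length(idx)
    if (cnt <= 1) next
    k <- min(n_neighbors, cnt - 1L)
    xc <- xs[idx]                      # already sorted
    d <- rep(Inf, cnt)
    for (a in 0:k) {                   # window [i - a, i - a + k]
      lo <- seq_len(cnt) - a
      hi <- lo + k
      ok <- which(lo >= 1L & hi <= cnt)
      if (length(ok)) {
        d[ok] <- pmin(d[ok], pmax(xc[ok] - xc[lo[ok]], xc[hi[ok]] - xc[ok]))
      }
    }
    r[idx] <- d
    kk[idx] <- k
    cls_n[idx] <- cnt
  }
  keep <- which(!is.na(r))
  if (length(keep) == 0) return(0)
  xs_k <- xs[keep]
  r_k <- r[keep]
  # strict inequality on both sides: #{j : x_i - r_i < x_j < x_i + r_i}
  m <- findInterval(xs_k + r_k, xs, left.open = TRUE) -
    findInterval(xs_k - r_k, xs)
  m <- pmax(m, 1L)
  mi <- digamma(length(keep)) + mean(digamma(kk[keep])) -
    mean(digamma(cls_n[keep])) - mean(digamma(m))
  max(0, mi)
}

# Seeded jitter matching the scale convention of the reference selector:
# sd = 1e-10 * max(1, mean(|x|)) per column. Breaks the ties that integer
# heart-rate features produce, which the k-NN estimator cannot handle.
mi_jitter <- function(X, rng_seed) {
  scales <- pmax(1, colMeans(abs(X)))
  noise <- withr::with_seed(
    rng_seed,
    matrix(rnorm(length(X)), nrow = nrow(X))
  )
  X + noise * rep(1e-10 * scales, each = nrow(X))
}

# Scores for every column of a (pre-jittered) numeric matrix.
mi_score_matrix <- function(Xj, y, n_neighbors = 3L) {
  vapply(seq_len(ncol(Xj)), function(j) mi_cont_disc(Xj[, j], y, n_neighbors),
         numeric(1))
}

feature_columns <- function(matrix) {
  feats <- intersect(hr_feature_names(), names(matrix))
  if (length(feats) == 0) {
    abort("no canonical feature columns found in the matrix",
          class = "hr_shape_error")
  }
  feats
}

#' Score features by mutual information with the emotion label
#'
#' Estimates, for each feature column, the mutual information between the
#' continuous feature and the discrete emotion label with a 3-nearest-neighbour
#' estimator. A tiny seeded jitter (1e-10 of the feature scale) breaks ties;
#' negative raw estimates are clamped to zero. Scores are in nats.
#'
#' @param matrix Feature-matrix tibble with an `emotion` column and canonical
#'   feature columns (a subset is allowed).
#' @param rng_seed Seed for the jitter; fixed seed gives identical scores.
#' @param n_neighbors Neighbour count of the estimator (default 3).
#' @return A tibble with columns `feature` and `score`, in canonical feature
#'   order.
#' @export
score_mutual_information <- function(matrix, rng_seed = 1L, n_neighbors = 3L) {
  feats <- feature_columns(matrix)
  if (nrow(matrix) < 10) {
    abort("mutual-information scoring needs at least 10 rows",
          class = "hr_insufficient_data_error")
  }
  y <- matrix$emotion
  if (length(unique(y)) < 2) {
    abort("mutual-information scoring needs at least 2 classes",
          class = "hr_degenerate_label_error")
  }
  Xj <- mi_jitter(as.matrix(matrix[feats]), rng_seed)
  tibble::tibble(feature = feats,
                 score = mi_score_matrix(Xj, y, n_neighbors))
}

#' Keep the top-k features
#'
#' Ranks features by descending mutual-information score, breaking ties by
#' canonical feature order (so results are reproducible), and keeps the first
#' `k`. The selected set for `k` is always a prefix of the ranking, hence a
#' subset of the selection for any larger `k`.
#'
#' @param scores Score tibble from [score_mutual_information()].
#' @param k Number of features to keep, `1 <= k <=` number of scored features.
#' @return An object of class `hr_selection`: list with `scores` (tibble with
#'   `feature`, `score`, `rank`), `ranking` (character), `k` and `selected`
#'   (first `k` names of the ranking).
#' @export
#' @examples
#' sc <- tibble::tibble(feature = c("a", "b", "c", "d"),
#'                      score = c(0.5, 0.3, 0.3, 0))
#' select_top_k(sc, 2)$selected
select_top_k <- function(scores, k) {
  stopifnot(is.data.frame(scores), all(c("feature", "score") %in% names(scores)))
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > nrow(scores)) {
    abort(paste0("k must be an integer in [1, ", nrow(scores), "]"),
          class = "hr_parameter_error")
  }
  ord <- order(-scores$score, seq_len(nrow(scores)))
  ranking <- scores$feature[ord]
  out <- tibble::tibble(
    feature = ranking,
    score = scores$score[ord],
    rank = seq_along(ranking)
  )
  structure(
    list(scores = out, ranking = ranking, k = k, selected = ranking[seq_len(k)]),
    class = "hr_selection"
  )
}

#' Report the highest-scoring features
#'
#' Two-column table of the top-`n` features by mutual information, the analog
#' of the reference method's top-five score table for any dataset.
#'
#' @param selection An `hr_selection` (from [select_top_k()]) or a score tibble
#'   (from [score_mutual_information()]).
#' @param n Number of features to report; clamped to the number available.
#' @return A tibble with columns `feature` and `score`, descending.
#' @export
report_top_features <- function(selection, n = 5) {
  scores <- if (inherits(selection, "hr_selection")) selection$scores else
    select_top_k(selection, nrow(selection))$scores
  head(scores[c("feature", "score")], min(n, nrow(scores)))
}

#' Write a feature-selection report
#'
#' @param selection An `hr_selection` object.
#' @param path Destination CSV path (columns `feature,score`, descending).
#' @return `path`, invisibly.
#' @export
write_selection_report <- function(selection, path) {
  stopifnot(inherits(selection, "hr_selection"))
  readr::write_csv(selection$scores[c("feature", "score")], path,
                   progress = FALSE)
  invisible(path)
}

#' @export
print.hr_selection <- function(x, ...) {
  cat("<hr_selection> top", x$k, "of", length(x$ranking), "features\n")
  print(head(x$scores, x$k), n = x$k)
  invisible(x)
}
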