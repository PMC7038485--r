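#' Default classifier hyperparameters
#'
#' The pinned defaults of the five classifier families. kNN uses 6 neighbours,
#' Manhattan distance and inverse-distance weighting (the `algorithm` and
#' `leaf_size` entries describe the reference tree-search configuration; exact
#' search gives identical predictions). The random forest grows 90 trees with
#' out-of-bag scoring and a fixed seed of 10; the decision tree splits on Gini
#' impurity to depth 6; gradient boosting runs 120 stages of depth-10 trees at
#' learning rate 0.01 with 0.5 row subsampling and a minimum split size of 4;
#' AdaBoost runs 6 stages of depth-1 stumps at learning rate 0.1.
#'
#' @return Named list: one hyperparameter list per family.
#' @export
classifier_defaults <- function() {
  list(
    knn = list(n_neighbors = 6L, p = 1L, weights = "distance",
               algorithm = "ball_tree", leaf_size = 2L),
    random_forest = list(n_estimators = 90L, oob_score = TRUE,
                         random_state = 10L),
    decision_tree = list(criterion = "gini", max_depth = 6L,
                         splitter = "best"),
    gradient_boosting = list(n_estimators = 120L, max_depth = 10L,
                             learning_rate = 0.01, min_samples_split = 4L,
                             subsample = 0.5),
    adaboost = list(n_estimators = 6L, learning_rate = 0.1)
  )
}

#' Classifier specification
#'
#' @param family One of `"knn"`, `"random_forest"`, `"decision_tree"`,
#'   `"gradient_boosting"`, `"adaboost"`.
#' @param params Named list of hyperparameter overrides merged over
#'   [classifier_defaults()].
#' @return A list of class `hr_classifier_spec`.
#' @export
#' @examples
#' classifier_spec("knn", list(n_neighbors = 3))
classifier_spec <- function(family = c("knn", "random_forest", "decision_tree",
                                       "gradient_boosting", "adaboost"),
                            params = list()) {
  family <- match.arg(family)
  defaults <- classifier_defaults()[[family]]
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("unknown ", family, " parameter(s): ",
                 paste(unknown, collapse = ", ")),
          class = "hr_parameter_error")
  }
  defaults[names(params)] <- params
  structure(list(family = family, params = defaults),
            class = "hr_classifier_spec")
}

#' @export
print.hr_classifier_spec <- function(x, ...) {
  cat("<hr_classifier_spec>", x$family, "\n")
  utils::str(x$params, give.attr = FALSE)
  invisible(x)
}

# Weighted k-nearest-neighbour prediction, Manhattan metric. Zero-distance
# neighbours dominate (their classes vote alone), mirroring the usual
# inverse-distance-weight convention; ties break by factor-level order.
knn_predict <- function(xtr, ytr, xte, params) {
  k <- min(params$n_neighbors, nrow(xtr))
  lv <- levels(ytr)
  out <- character(nrow(xte))
  for (i in seq_len(nrow(xte))) {
    d <- colSums(abs(t(xtr) - xte[i, ]))
    nn <- order(d)[seq_len(k)]
    dn <- d[nn]
    if (any(dn == 0)) {
      votes <- table(factor(ytr[nn][dn == 0], levels = lv))
    } else {
      w <- if (identical(params$weights, "distance")) 1 / dn else rep(1, k)
      votes <- tapply(w, factor(ytr[nn], levels = lv), sum, default = 0)
    }
    out[i] <- lv[which.max(votes)]
  }
  factor(out, levels = lv)
}

# Weighted Gini decision stump: exhaustive search over every feature and
# every midpoint between distinct consecutive values for the split minimizing
# weighted Gini impurity (the depth-1, best-split tree). Each side predicts
# its weighted majority class. Degenerate input (no usable split) falls back
# to the overall weighted majority on both sides.
stump_fit <- function(X, y, w) {
  K <- nlevels(y)
  n <- nrow(X)
  cw_total <- vapply(seq_len(K), function(c) sum(w[as.integer(y) == c]),
                     numeric(1))
  best <- list(score = -Inf, feature = NA_integer_, threshold = NA_real_)
  for (j in seq_len(ncol(X))) {
    ord <- order(X[, j])
    xo <- X[ord, j]
    yo <- as.integer(y)[ord]
    wo <- w[ord]
    cum <- matrix(0, n, K)
    cum[cbind(seq_len(n), yo)] <- wo
    cum <- apply(cum, 2, cumsum)
    cut_ok <- which(diff(xo) > 0)           # split between distinct values
    if (length(cut_ok) == 0) next
    wl <- rowSums(cum)[cut_ok]
    wr <- sum(w) - wl
    # maximizing sum_c w_{c,side}^2 / w_side over sides == minimizing
    # weighted Gini impurity
    sl <- rowSums(cum[cut_ok, , drop = FALSE]^2) / wl
    sr <- rowSums((rep(cw_total, each = length(cut_ok)) -
                     cum[cut_ok, , drop = FALSE])^2) / wr
    sc <- sl + sr
    b <- which.max(sc)
    if (sc[b] > best$score) {
      i <- cut_ok[b]
      left_cw <- cum[i, ]
      best <- list(
        score = sc[b], feature = j,
        threshold = (xo[i] + xo[i + 1]) / 2,
        left_class = which.max(left_cw),
        right_class = which.max(cw_total - left_cw)
      )
    }
  }
  if (!is.finite(best$score)) {
    maj <- which.max(cw_total)
    best <- list(score = 0, feature = 1L, threshold = Inf,
                 left_class = maj, right_class = maj)
  }
  best
}

stump_predict <- function(stump, X) {
  ifelse(X[, stump$feature] <= stump$threshold,
         stump$left_class, stump$right_class)
}

# Multiclass AdaBoost (SAMME) over weighted Gini stumps. A stage with
# weighted error >= 1 - 1/K contributes nothing and stops the ensemble;
# near-perfect stages get a large finite stage weight via the epsilon floor.
adaboost_fit <- function(xtr, ytr, params) {
  n <- nrow(xtr)
  K <- nlevels(ytr)
  w <- rep(1 / n, n)
  stumps <- list()
  alphas <- numeric(0)
  for (m in seq_len(params$n_estimators)) {
    stump <- stump_fit(xtr, ytr, w)
    pred <- stump_predict(stump, xtr)
    miss <- pred != as.integer(ytr)
    err <- sum(w[miss])
    if (err >= 1 - 1 / K) {
      if (m == 1) {
        stumps <- list(stump)
        alphas <- 1
      }
      break
    }
    err <- max(err, 1e-10)
    alpha <- params$learning_rate * (log((1 - err) / err) + log(K - 1))
    stumps[[m]] <- stump
    alphas[m] <- alpha
    w <- w * exp(alpha * miss)
    w <- w / sum(w)
    if (err < 1e-10) break
  }
  list(stumps = stumps, alphas = alphas, levels = levels(ytr))
}

adaboost_predict <- function(model, xte) {
  lv <- model$levels
  scores <- matrix(0, nrow(xte), length(lv))
  for (m in seq_along(model$stumps)) {
    pred <- stump_predict(model$stumps[[m]], xte)
    idx <- cbind(seq_len(nrow(xte)), pred)
    scores[idx] <- scores[idx] + model$alphas[m]
  }
  factor(lv[max.col(scores, ties.method = "first")], levels = lv)
}

# Fit one classifier on (xtr, ytr) and predict xte. `seed` feeds the
# stochastic fitters (forest bootstrap unless the spec pins random_state, and
# gradient-boosting row subsampling); knn and the decision tree are
# deterministic.
fit_predict <- function(spec, xtr, ytr, xte, seed = 1L) {
  stopifnot(inherits(spec, "hr_classifier_spec"))
  ytr <- droplevels(ytr)
  lv <- levels(ytr)
  p <- spec$params
  if (!is.matrix(xte)) xte <- matrix(xte, nrow = 1)
  colnames(xte) <- colnames(xtr)
  switch(spec$family,
    knn = knn_predict(xtr, ytr, xte, p),
    random_forest = {
      fit_seed <- if (!is.null(p$random_state)) p$random_state else seed
      fit <- withr::with_seed(fit_seed,
        randomForest::randomForest(x = xtr, y = ytr, ntree = p$n_estimators))
      factor(as.character(predict(fit, xte)), levels = lv)
    },
    decision_tree = {
      df <- data.frame(.y = ytr, xtr, check.names = FALSE)
      fit <- rpart::rpart(
        .y ~ ., data = df, method = "class",
        parms = list(split = "gini"),
        control = rpart::rpart.control(maxdepth = p$max_depth, minsplit = 2,
                                       minbucket = 1, cp = 0, xval = 0)
      )
      pred <- predict(fit, data.frame(xte, check.names = FALSE), type = "class")
      factor(as.character(pred), levels = lv)
    },
    gradient_boosting = xgb_predict(xtr, ytr, xte, p, seed),
    adaboost = {
      model <- adaboost_fit(xtr, ytr, p)
      adaboost_predict(model, xte)
    }
  )
}

xgb_predict <- function(xtr, ytr, xte, p, seed) {
  lv <- levels(ytr)
  K <- length(lv)
  ytr_num <- as.integer(ytr) - 1L
  # min_child_weight 0: the reference boosting semantics constrain splits by
  # sample counts (min_samples_split), not hessian mass; a positive hessian
  # floor would silently stop late-stage splits as predictions converge
  params <- list(
    max_depth = p$max_depth,
    eta = p$learning_rate,
    subsample = p$subsample,
    min_child_weight = 0,
    nthread = 1
  )
  if (K == 2) {
    params$objective <- "binary:logistic"
  } else {
    params$objective <- "multi:softprob"
    params$num_class <- K
  }
  dtrain <- xgboost::xgb.DMatrix(xtr, label = ytr_num, nthread = 1)
  fit <- withr::with_seed(seed,
    xgboost::xgb.train(params = params, data = dtrain,
                       nrounds = p$n_estimators, verbose = 0))
  pr <- predict(fit, xgboost::xgb.DMatrix(xte, nthread = 1))
  if (K == 2) {
    factor(lv[as.integer(pr > 0.5) + 1L], levels = lv)
  } else {
    pm <- matrix(pr, ncol = K, byrow = TRUE)
    factor(lv[max.col(pm, ties.method = "first")], levels = lv)
  }
}
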