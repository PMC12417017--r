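# Leakage-safe training harness: participant-grouped cross-validation,
# in-fold standardization and select-k-best, hyperparameter search for the
# classical model families, and prediction.

#' Hyperparameter search specification
#'
#' @param algorithm One of "svm", "mlp", "adaboost", "random_forest",
#'   "gboost", "lstm".
#' @param strategy "grid" (exhaustive over the space, default for svm /
#'   mlp / adaboost) or "random" (trial-budgeted sequential search,
#'   default for the tree ensembles); "tpe" is accepted as an alias for
#'   the budgeted sequential search.
#' @param budget Maximum number of candidate hyperparameter sets.
#' @param k_folds Embedded cross-validation folds (default 5).
#' @param seed RNG seed for fold assignment and stochastic learners.
#' @param space Named list of candidate values per hyperparameter;
#'   defaults are small desk-scale spaces per algorithm.
#' @return A `search_spec` object.
#' @export
search_spec <- function(algorithm, strategy = NULL, budget = NULL,
                        k_folds = 5, seed = 1, space = NULL) {
  algorithm <- match.arg(algorithm, c("svm", "mlp", "adaboost",
                                      "random_forest", "gboost", "lstm"))
  if (is.null(strategy))
    strategy <- if (algorithm %in% c("svm", "mlp", "adaboost")) "grid"
                else "random"
  if (strategy == "tpe") strategy <- "random"
  strategy <- match.arg(strategy, c("grid", "random"))
  if (is.null(space)) space <- default_space(algorithm)
  if (!length(space)) stopf("empty hyperparameter space")
  if (is.null(budget)) budget <- if (strategy == "grid") 24 else 4
  if (budget < 1) stopf("budget must be >= 1")
  structure(list(algorithm = algorithm, strategy = strategy,
                 budget = budget, k_folds = k_folds, seed = seed,
                 space = space),
            class = "search_spec")
}

#' Default hyperparameter space for a model family
#'
#' Small desk-scale spaces; the published large search budgets are
#' configuration values, not defaults.
#'
#' @param algorithm Model family name (see [search_spec()]).
#' @return Named list of candidate values per hyperparameter.
#' @export
default_space <- function(algorithm) {
  switch(algorithm,
    svm = list(cost = c(1, 10), k_best = c(32, Inf)),
    mlp = list(size = 8, decay = c(0.1, 0.01), k_best = c(32, Inf)),
    adaboost = list(n_rounds = 50, depth = c(1, 2)),
    random_forest = list(num_trees = 300, mtry_frac = c(0.1, 0.3)),
    gboost = list(nrounds = 80, eta = c(0.3, 0.1), max_depth = c(4, 6)),
    lstm = list(hidden = c(16, 32), lr = 0.01))
}

#' Participant-grouped cross-validation folds
#'
#' Partition of participant ids into k folds whose sizes differ by at most
#' one; deterministic given the seed.  Grouping by participant keeps all
#' epochs of one subject in one fold, preventing leakage across folds.
#'
#' @param train_ids Participant ids.
#' @param k Number of folds.
#' @param seed RNG seed.
#' @return List of k character vectors.
#' @export
make_grouped_folds <- function(train_ids, k, seed = 1) {
  ids <- unique(train_ids)
  if (k > length(ids))
    stopf("k = %d exceeds the %d available participants", k, length(ids))
  perm <- with_seed(seed, sample(ids))
  split(perm, rep_len(seq_len(k), length(perm)))
}

standardize_fit <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(center = ctr, scale = scl)
}

standardize_apply <- function(X, st) {
  sweep(sweep(X, 2, st$center, "-"), 2, st$scale, "/")
}

# univariate one-way ANOVA F score per column
f_scores <- function(X, y) {
  y <- droplevels(as.factor(y))
  n <- nrow(X); g <- nlevels(y)
  gm <- colMeans(X)
  ssb <- numeric(ncol(X)); ssw <- numeric(ncol(X))
  for (lv in levels(y)) {
    sel <- y == lv
    m <- colMeans(X[sel, , drop = FALSE])
    ssb <- ssb + sum(sel) * (m - gm)^2
    ssw <- ssw + colSums(sweep(X[sel, , drop = FALSE], 2, m)^2)
  }
  f <- (ssb / (g - 1)) / (ssw / (n - g))
  f[!is.finite(f)] <- 0
  f
}

select_k_best <- function(X, y, k) {
  if (!is.finite(k) || k >= ncol(X)) return(seq_len(ncol(X)))
  order(f_scores(X, y), decreasing = TRUE)[seq_len(k)]
}

expand_candidates <- function(spec) {
  grid <- expand.grid(spec$space, stringsAsFactors = FALSE)
  if (spec$strategy == "grid") {
    if (nrow(grid) > spec$budget) grid <- grid[seq_len(spec$budget), , drop = FALSE]
  } else {
    take <- min(spec$budget, nrow(grid))
    grid <- grid[with_seed(spec$seed, sample(nrow(grid), take)), , drop = FALSE]
  }
  lapply(seq_len(nrow(grid)), function(i) as.list(grid[i, , drop = FALSE]))
}

est_fit <- function(algorithm, X, y, params, seed) {
  classes <- levels(y)
  with_seed(seed, switch(algorithm,
    svm = e1071::svm(x = X, y = y, cost = params$cost %||% 1,
                     kernel = "radial", scale = FALSE),
    mlp = nnet::nnet(x = X, y = nnet::class.ind(y),
                     size = params$size %||% 8,
                     decay = params$decay %||% 0.01, softmax = TRUE,
                     maxit = 200, trace = FALSE, MaxNWts = 1e5),
    adaboost = fit_samme(X, y, n_rounds = params$n_rounds %||% 50,
                         depth = params$depth %||% 1),
    random_forest = ranger::ranger(
      x = as.data.frame(X), y = y,
      num.trees = params$num_trees %||% 300,
      mtry = max(1, floor((params$mtry_frac %||% 0.3) * ncol(X))),
      num.threads = 1, seed = seed),
    gboost = xgboost::xgb.train(
      params = list(objective = "multi:softmax",
                    num_class = length(classes),
                    eta = params$eta %||% 0.3,
                    max_depth = params$max_depth %||% 6,
                    nthread = 1, tree_method = "hist"),
      data = xgboost::xgb.DMatrix(X, label = as.integer(y) - 1,
                                  nthread = 1),
      nrounds = params$nrounds %||% 80, verbose = 0),
    stopf("unknown algorithm '%s'", algorithm)))
}

est_predict <- function(algorithm, est, X, classes) {
  out <- switch(algorithm,
    svm = as.character(predict(est, X)),
    mlp = classes[max.col(predict(est, X))],
    adaboost = predict_samme(est, X),
    random_forest = as.character(predict(est, as.data.frame(X),
                                         num.threads = 1)$predictions),
    gboost = classes[predict(est, xgboost::xgb.DMatrix(X, nthread = 1)) + 1])
  factor(out, levels = classes)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# SAMME multiclass AdaBoost over shallow rpart trees
fit_samme <- function(X, y, n_rounds = 50, depth = 1) {
  K <- nlevels(y)
  n <- nrow(X)
  df <- as.data.frame(X); df$.y <- y
  w <- rep(1 / n, n)
  trees <- list(); alphas <- numeric(0)
  for (m in seq_len(n_rounds)) {
    fit <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                        control = rpart::rpart.control(
                          maxdepth = depth, cp = 0, minsplit = 2,
                          xval = 0))
    pred <- predict(fit, df, type = "class")
    err <- sum(w * (pred != y))
    if (err <= 1e-12) { trees <- c(trees, list(fit)); alphas <- c(alphas, 10); break }
    if (err >= 1 - 1 / K) break
    alpha <- log((1 - err) / err) + log(K - 1)
    trees <- c(trees, list(fit)); alphas <- c(alphas, alpha)
    w <- w * exp(alpha * (pred != y))
    w <- w / sum(w)
  }
  if (!length(trees)) stopf("AdaBoost found no usable weak learner")
  list(trees = trees, alphas = alphas, classes = levels(y))
}

predict_samme <- function(model, X) {
  df <- as.data.frame(X)
  votes <- matrix(0, nrow(df), length(model$classes),
                  dimnames = list(NULL, model$classes))
  for (m in seq_along(model$trees)) {
    pred <- as.character(predict(model$trees[[m]], df, type = "class"))
    votes[cbind(seq_len(nrow(df)), match(pred, model$classes))] <-
      votes[cbind(seq_len(nrow(df)), match(pred, model$classes))] +
      model$alphas[m]
  }
  model$classes[max.col(votes)]
}

as_matrix_features <- function(features) {
  if (inherits(features, "feature_matrix")) features$values
  else as.matrix(features)
}

#' Fit a classical model with leakage-safe embedded cross-validation
#'
#' For each candidate hyperparameter set, a per-fold pipeline is run:
#' z-score standardization fitted on the training folds only, select-k-best
#' univariate feature selection (where `k_best` is in the space), then the
#' estimator.  The candidate score is the mean validation MCC across the
#' participant-grouped folds; the best candidate is refit on all training
#' rows.
#'
#' @param features Numeric matrix or `feature_matrix` (rows = epochs).
#' @param labels Factor of stage labels, aligned with rows.
#' @param groups Participant id per row (folds never split a participant).
#' @param spec A `search_spec`.
#' @return A `sleep_model` with fitted preprocessing, estimator, best
#'   hyperparameters, per-fold scores, and the in-fold standardization
#'   parameters retained for audit.
#' @export
fit_ml <- function(features, labels, groups, spec) {
  X <- as_matrix_features(features)
  y <- droplevels(as.factor(labels))
  stopifnot(nrow(X) == length(y), length(groups) == length(y))
  if (nlevels(y) < 2) stopf("training labels contain a single class")
  folds <- make_grouped_folds(groups, spec$k_folds, spec$seed)
  candidates <- expand_candidates(spec)
  best <- NULL
  for (ci in seq_along(candidates)) {
    params <- candidates[[ci]]
    fold_scores <- numeric(length(folds))
    fold_preproc <- vector("list", length(folds))
    failed <- FALSE
    for (fi in seq_along(folds)) {
      val_rows <- groups %in% folds[[fi]]
      Xtr <- X[!val_rows, , drop = FALSE]; ytr <- droplevels(y[!val_rows])
      if (nlevels(ytr) < 2) { failed <- TRUE; break }
      st <- standardize_fit(Xtr)
      sel <- select_k_best(standardize_apply(Xtr, st), ytr,
                           params$k_best %||% Inf)
      fold_preproc[[fi]] <- list(center = st$center, scale = st$scale,
                                 selected = sel)
      Ztr <- standardize_apply(Xtr, st)[, sel, drop = FALSE]
      Zval <- standardize_apply(X[val_rows, , drop = FALSE], st)[, sel,
                                                                 drop = FALSE]
      est <- try(est_fit(spec$algorithm, Ztr, ytr, params,
                         derive_seed(spec$seed, ci * 100 + fi)),
                 silent = TRUE)
      if (inherits(est, "try-error")) { failed <- TRUE; break }
      pred <- est_predict(spec$algorithm, est, Zval, levels(ytr))
      fold_scores[fi] <- mcc(confusion(as.character(y[val_rows]),
                                       as.character(pred), levels(y)))
    }
    if (failed) next
    score <- mean(fold_scores)
    if (is.null(best) || score > best$score)
      best <- list(score = score, params = params,
                   fold_scores = fold_scores, fold_preproc = fold_preproc)
  }
  if (is.null(best)) stopf("all %d search trials failed", length(candidates))
  st <- standardize_fit(X)
  sel <- select_k_best(standardize_apply(X, st), y,
                       best$params$k_best %||% Inf)
  Z <- standardize_apply(X, st)[, sel, drop = FALSE]
  est <- est_fit(spec$algorithm, Z, y, best$params,
                 derive_seed(spec$seed, 999))
  structure(list(algorithm = spec$algorithm, classes = levels(y),
                 feature_names = colnames(X),
                 preproc = list(center = st$center, scale = st$scale,
                                selected = sel),
                 est = est,
                 metadata = list(seed = spec$seed,
                                 best_params = best$params,
                                 cv_score = best$score,
                                 fold_scores = best$fold_scores,
                                 fold_preproc = best$fold_preproc,
                                 folds = folds)),
            class = "sleep_model")
}

#' Predict stage labels from a fitted model
#'
#' Columns are realigned by name to the model's feature schema, then the
#' stored standardization and feature selection are applied.  For sequence
#' models, pass a `sequence_dataset` built with the model's normalization
#' statistics.
#'
#' @param object A `sleep_model`.
#' @param newdata Matrix / `feature_matrix`, or `sequence_dataset` for
#'   sequence models.
#' @param ... Unused.
#' @return Factor of predicted labels, one per row (or window).
#' @export
predict.sleep_model <- function(object, newdata, ...) {
  if (object$algorithm %in% c("lstm", "rnn"))
    return(predict_rnn(object, newdata))
  X <- as_matrix_features(newdata)
  if (nrow(X) == 0) return(factor(character(0), levels = object$classes))
  if (!is.null(colnames(X)) && !is.null(object$feature_names)) {
    if (!all(object$feature_names %in% colnames(X)))
      stopf("newdata is missing %d model feature(s)",
            sum(!object$feature_names %in% colnames(X)))
    X <- X[, object$feature_names, drop = FALSE]
  } else if (ncol(X) != length(object$feature_names)) {
    stopf("newdata has %d columns; model expects %d", ncol(X),
          length(object$feature_names))
  }
  Z <- standardize_apply(X, object$preproc)[, object$preproc$selected,
                                            drop = FALSE]
  est_predict(object$algorithm, object$est, Z, object$classes)
}
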