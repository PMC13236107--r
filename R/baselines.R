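# Classical ensemble baselines: random forest with randomized hyperparameter
# search and XGBoost with exhaustive grid search, both model-selected by
# 4-fold cross-validated accuracy. Baselines see the unreduced feature space
# (no PCA), matching how they are compared against the quantum ensembles.

#' Random-forest hyperparameter search space
#'
#' @return A named list of candidate values: `n_estimators` 100..1000 by
#'   100, `max_depth` 5..20, `min_samples_split` 2..10,
#'   `min_samples_leaf` 1..5, `max_features` sqrt / log2.
#' @export
rf_search_space <- function() {
  list(n_estimators = seq(100L, 1000L, by = 100L),
       max_depth = 5:20,
       min_samples_split = 2:10,
       min_samples_leaf = 1:5,
       max_features = c("sqrt", "log2"))
}

#' XGBoost hyperparameter grid
#'
#' @return Data.frame of all 486 combinations: `n_estimators` {100, 200},
#'   `max_depth` {3, 5, 7}, `learning_rate` {0.01, 0.1, 0.2},
#'   `subsample` {0.7, 0.8, 1.0}, `colsample_bytree` {0.7, 0.8, 1.0},
#'   `min_child_weight` {1, 3, 5}.
#' @export
xgb_search_grid <- function() {
  expand.grid(n_estimators = c(100L, 200L), max_depth = c(3L, 5L, 7L),
              learning_rate = c(0.01, 0.1, 0.2), subsample = c(0.7, 0.8, 1.0),
              colsample_bytree = c(0.7, 0.8, 1.0), min_child_weight = c(1L, 3L, 5L),
              KEEP.OUT.ATTRS = FALSE)
}

rf_mtry <- function(rule, p) {
  max(1L, if (rule == "sqrt") floor(sqrt(p)) else floor(log2(p)))
}

rf_fit_one <- function(cand, X, y, seed) {
  ranger::ranger(x = as.data.frame(X), y = factor(y, levels = c(0L, 1L)),
                 num.trees = cand$n_estimators,
                 max.depth = cand$max_depth,
                 min.node.size = cand$min_samples_split,
                 min.bucket = cand$min_samples_leaf,
                 mtry = rf_mtry(cand$max_features, ncol(X)),
                 probability = TRUE, num.threads = 1L, seed = seed)
}

rf_predict_prob <- function(model, X) {
  stats::predict(model, data = as.data.frame(X), num.threads = 1L)$predictions[, "1"]
}

cv_accuracy_generic <- function(X, y, folds, fit, predict_prob, seed) {
  fold <- stratified_folds(y, folds, seed = seed)
  mean(vapply(seq_len(folds), function(f) {
    tr <- fold != f
    model <- fit(X[tr, , drop = FALSE], y[tr])
    mean(classify(predict_prob(model, X[!tr, , drop = FALSE])) == y[!tr])
  }, numeric(1)))
}

#' Random-forest baseline with randomized hyperparameter search
#'
#' Samples `n_iter` candidate configurations uniformly from
#' [rf_search_space()], scores each by 4-fold cross-validated accuracy on
#' the training split, refits the best on the full training split, and
#' predicts the test split. sklearn-style parameters map onto ranger as
#' num.trees / max.depth / min.node.size / min.bucket / mtry.
#'
#' @param X_train,y_train Training split (full feature space, no PCA).
#' @param y_train Training labels.
#' @param X_test Test split features.
#' @param n_iter Number of randomized candidates (default 50).
#' @param folds Internal model-selection folds (default 4).
#' @param seed Integer seed (candidate sampling, CV folds, tree seeds).
#' @return List with `model`, the winning `config`, its `cv_accuracy`, and
#'   test-split probabilities `p`.
#' @export
rf_baseline <- function(X_train, y_train, X_test, n_iter = 50L, folds = 4L,
                        seed = 1L) {
  X_train <- as.matrix(X_train)
  if (nrow(X_train) == 0L) stop("empty training data")
  space <- rf_search_space()
  cands <- with_seed(derive_seed(seed, 71L), {
    lapply(seq_len(n_iter), function(i) {
      lapply(space, function(v) v[[sample.int(length(v), 1L)]])
    })
  })
  scores <- vapply(seq_along(cands), function(i) {
    cv_accuracy_generic(X_train, y_train, folds,
                        fit = function(X, y) rf_fit_one(cands[[i]], X, y,
                                                        derive_seed(seed, 73L, i)),
                        predict_prob = rf_predict_prob,
                        seed = derive_seed(seed, 79L))
  }, numeric(1))
  best <- cands[[which.max(scores)]]
  model <- rf_fit_one(best, X_train, y_train, derive_seed(seed, 83L))
  list(model = model, config = best, cv_accuracy = max(scores),
       p = rf_predict_prob(model, as.matrix(X_test)))
}

xgb_fit_one <- function(cand, X, y, seed) {
  dtrain <- xgboost::xgb.DMatrix(as.matrix(X), label = y)
  params <- list(objective = "binary:logistic",
                 max_depth = cand$max_depth, eta = cand$learning_rate,
                 subsample = cand$subsample,
                 colsample_bytree = cand$colsample_bytree,
                 min_child_weight = cand$min_child_weight,
                 nthread = 1L, seed = seed)
  xgboost::xgb.train(params = params, data = dtrain,
                     nrounds = cand$n_estimators, verbose = 0)
}

xgb_predict_prob <- function(model, X) {
  stats::predict(model, xgboost::xgb.DMatrix(as.matrix(X)))
}

#' XGBoost baseline with exhaustive grid search
#'
#' Scores every row of `grid` (default: the full 486-combination
#' [xgb_search_grid()]) by 4-fold cross-validated accuracy, refits the best
#' configuration, and predicts the test split.
#'
#' @inheritParams rf_baseline
#' @param grid Data.frame of candidate configurations.
#' @return List with `model`, `config`, `cv_accuracy` and test probabilities
#'   `p`.
#' @export
xgb_baseline <- function(X_train, y_train, X_test, grid = xgb_search_grid(),
                         folds = 4L, seed = 1L) {
  X_train <- as.matrix(X_train)
  if (nrow(X_train) == 0L) stop("empty training data")
  scores <- vapply(seq_len(nrow(grid)), function(i) {
    cand <- as.list(grid[i, ])
    cv_accuracy_generic(X_train, y_train, folds,
                        fit = function(X, y) xgb_fit_one(cand, X, y,
                                                         derive_seed(seed, 89L, i)),
                        predict_prob = xgb_predict_prob,
                        seed = derive_seed(seed, 97L))
  }, numeric(1))
  best <- as.list(grid[which.max(scores), ])
  model <- xgb_fit_one(best, X_train, y_train, derive_seed(seed, 101L))
  list(model = model, config = best, cv_accuracy = max(scores),
       p = xgb_predict_prob(model, as.matrix(X_test)))
}
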