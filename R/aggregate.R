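# Ensemble constructions over variational learners: soft voting (learners
# trained jointly on the full training set against the ensemble loss),
# bagging (disjoint near-equal partition, one learner per subset), and
# AdaBoost-style boosting (weighted subset resampling).

#' An ensemble of variational learners
#'
#' @param learners List of [variational_learner()] objects.
#' @param kind `"soft_vote"`, `"bagging"` or `"boosting"`.
#' @param learner_weights Nonnegative aggregation weights (default uniform);
#'   normalized internally.
#' @param partition Optional list of training-index subsets (bagging /
#'   boosting bookkeeping).
#' @return Object of class `vq_ensemble`.
#' @export
vq_ensemble <- function(learners, kind = c("soft_vote", "bagging", "boosting"),
                        learner_weights = NULL, partition = NULL) {
  kind <- match.arg(kind)
  if (length(learners) == 0L) stop("an ensemble needs at least one learner")
  if (is.null(learner_weights)) learner_weights <- rep(1, length(learners))
  if (length(learner_weights) != length(learners)) stop("one weight per learner")
  if (any(!is.finite(learner_weights)) || any(learner_weights < 0)) {
    stop("weights must be finite and nonnegative")
  }
  if (sum(learner_weights) == 0) learner_weights <- rep(1, length(learners))
  structure(list(learners = learners, kind = kind,
                 learner_weights = learner_weights / sum(learner_weights),
                 partition = partition),
            class = "vq_ensemble")
}

#' Soft-vote prediction: unweighted mean of learner probabilities
#'
#' @param ensemble A `vq_ensemble` of kind `soft_vote`.
#' @param X Feature matrix.
#' @return Mean `Pr(y = 1)` across learners, one value per row of `X`.
#' @export
soft_vote_predict <- function(ensemble, X) {
  stopifnot(inherits(ensemble, "vq_ensemble"))
  X <- as.matrix(X)
  P <- vapply(ensemble$learners, function(l) predict_varqc(l, X),
              numeric(nrow(X)))
  rowMeans(matrix(P, nrow = nrow(X)))
}

#' Ensemble prediction (weighted mean of member probabilities)
#'
#' Soft voting uses the unweighted mean; bagging and boosting use the
#' ensemble's learner weights (uniform for bagging by default, AdaBoost
#' coefficients for boosting).
#'
#' @param object A `vq_ensemble`.
#' @param X Feature matrix.
#' @param type `"prob"` for probabilities, `"class"` for thresholded labels.
#' @param ... Unused.
#' @export
predict.vq_ensemble <- function(object, X, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  X <- as.matrix(X)
  P <- vapply(object$learners, function(l) predict_varqc(l, X),
              numeric(nrow(X)))
  P <- matrix(P, nrow = nrow(X))
  w <- if (object$kind == "soft_vote") rep(1 / ncol(P), ncol(P)) else object$learner_weights
  p <- as.vector(P %*% w)
  if (type == "prob") p else classify(p)
}

#' Width of the joint tensor-product instantiation of an ensemble
#'
#' All learner states prepared simultaneously in one circuit as
#' `U_1 (x) ... (x) U_l`: the width is `n * l` qubits for `l` learners of
#' `n` qubits each.
#'
#' @param ensemble A `vq_ensemble` whose learners share one width.
#' @return Total qubit count of the joint circuit.
#' @export
instantiate_joint <- function(ensemble) {
  stopifnot(inherits(ensemble, "vq_ensemble"))
  widths <- vapply(ensemble$learners, function(l) l$n_qubits, integer(1))
  if (length(unique(widths)) != 1L) {
    stop("joint instantiation requires learners of equal width")
  }
  widths[1L] * length(widths)
}

#' Train a soft-voting ensemble
#'
#' All learners see the full training set; the binary cross entropy of the
#' *ensemble mean* prediction is minimized jointly with Adam, parameter-shift
#' gradients flowing to each learner through the average.
#'
#' @param X Training feature matrix; `y` binary labels.
#' @param y Binary labels.
#' @param n_learners Ensemble size.
#' @param learning_rate,batch_size,epochs,seed Training configuration (see
#'   [train_learner()]).
#' @return A `vq_ensemble` of kind `soft_vote` with `loss_trace` attached.
#' @export
soft_vote_fit <- function(X, y, n_learners, learning_rate = 0.1,
                          batch_size = 4L, epochs = 30L, seed = 1L) {
  X <- as.matrix(X)
  n <- feature_qubits(ncol(X))
  learners <- lapply(seq_len(n_learners), function(k) {
    variational_learner(n, seed = derive_seed(seed, 23L, k))
  })
  thetas <- vapply(learners, function(l) l$theta, numeric(6L * n))
  fit <- train_ensemble_core(matrix(thetas, nrow = 6L * n), n, X, y,
                             learning_rate, batch_size, epochs, seed)
  for (k in seq_len(n_learners)) learners[[k]]$theta <- fit$thetas[, k]
  ens <- vq_ensemble(learners, kind = "soft_vote")
  ens$loss_trace <- fit$loss_trace
  ens
}

#' Disjoint near-equal partition of 1..n into k subsets
#'
#' Subset sizes differ by at most one, with the remainder assigned to the
#' earliest subsets; membership is a seeded shuffle.
#'
#' @param n Number of samples; `k` number of subsets; `seed` shuffle seed.
#' @param k Number of subsets.
#' @param seed Shuffle seed.
#' @return List of `k` disjoint index vectors covering `1:n`.
#' @export
partition_indices <- function(n, k, seed = 1L) {
  if (k > n) stop("cannot partition ", n, " samples into ", k, " subsets")
  ord <- with_seed(seed, sample(n))
  sizes <- rep(floor(n / k), k)
  extra <- n - sum(sizes)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  unname(split(ord, rep(seq_len(k), times = sizes)))
}

#' Train a bagged ensemble
#'
#' The training data is partitioned into `k` disjoint near-equal subsets and
#' the k-th learner is trained only on the k-th subset. Inference is a
#' weighted mean over learner probabilities (uniform weights by default,
#' exposed through `learner_weights`).
#'
#' @inheritParams soft_vote_fit
#' @param k Number of learners / subsets (`<=` sample count).
#' @param learner_weights Optional nonuniform aggregation weights.
#' @return A `vq_ensemble` of kind `bagging`.
#' @export
bagging_fit <- function(X, y, k, learning_rate = 0.1, batch_size = 4L,
                        epochs = 30L, seed = 1L, learner_weights = NULL) {
  X <- as.matrix(X)
  parts <- partition_indices(nrow(X), k, seed = derive_seed(seed, 31L))
  n <- feature_qubits(ncol(X))
  learners <- lapply(seq_len(k), function(j) {
    idx <- parts[[j]]
    train_learner(variational_learner(n, seed = derive_seed(seed, 37L, j)),
                  X[idx, , drop = FALSE], y[idx],
                  learning_rate = learning_rate,
                  batch_size = min(batch_size, length(idx)),
                  epochs = epochs, seed = derive_seed(seed, 41L, j))
  })
  vq_ensemble(learners, kind = "bagging", learner_weights = learner_weights,
              partition = parts)
}

#' Train a boosted ensemble (AdaBoost-style)
#'
#' Sample weights start uniform at `1/N`. Each round trains a weak learner
#' on a subset of `floor(N/k)` samples drawn without replacement with
#' probability proportional to the current weights, computes the weighted
#' error `eps` on the full training set, assigns the learner coefficient
#' `0.5 * log((1 - eps) / eps)` (with `eps` clipped to
#' `[1e-6, 1 - 1e-6]`), multiplies misclassified samples' weights by
#' `exp(coef)`, and renormalizes. A round with `eps >= 0.5` stops the loop
#' with a warning, keeping the rounds completed so far.
#'
#' @inheritParams bagging_fit
#' @return A `vq_ensemble` of kind `boosting` with AdaBoost learner weights.
#' @export
boosting_fit <- function(X, y, k, learning_rate = 0.1, batch_size = 4L,
                         epochs = 30L, seed = 1L) {
  X <- as.matrix(X)
  N <- nrow(X)
  if (k < 1L) stop("k must be >= 1")
  m <- max(1L, floor(N / k))
  n <- feature_qubits(ncol(X))
  w <- rep(1 / N, N)
  learners <- list(); alphas <- numeric(0); subsets <- list()
  weight_history <- list(w)
  for (round in seq_len(k)) {
    idx <- with_seed(derive_seed(seed, 43L, round),
                     sample(N, m, replace = FALSE, prob = w))
    learner <- train_learner(variational_learner(n, seed = derive_seed(seed, 47L, round)),
                             X[idx, , drop = FALSE], y[idx],
                             learning_rate = learning_rate,
                             batch_size = min(batch_size, m),
                             epochs = epochs, seed = derive_seed(seed, 53L, round))
    miss <- classify(predict_varqc(learner, X)) != y
    eps <- sum(w * miss)
    eps_c <- min(max(eps, 1e-6), 1 - 1e-6)
    alpha <- 0.5 * log((1 - eps_c) / eps_c)
    if (eps >= 0.5) {
      warning("boosting round ", round, " had weighted error ", signif(eps, 3),
              " >= 0.5; stopping with ", length(learners), " completed round(s)")
      if (length(learners) == 0L) {  # keep the lone learner so predict() is defined
        learners <- list(learner); alphas <- alpha; subsets <- list(idx)
      }
      break
    }
    learners <- c(learners, list(learner))
    alphas <- c(alphas, alpha)
    subsets <- c(subsets, list(idx))
    w <- w * exp(alpha * miss)
    w <- w / sum(w)
    weight_history <- c(weight_history, list(w))
  }
  ens <- vq_ensemble(learners, kind = "boosting", learner_weights = pmax(alphas, 0),
                     partition = subsets)
  ens$sample_weights <- w
  ens$weight_history <- weight_history
  ens
}
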