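# Variational weak learner: amplitude embedding, two RZ-RY-RZ rotation
# layers separated by a linear CNOT chain, readout of qubit 0. 6n trainable
# parameters on n qubits, trained with mini-batch Adam on binary cross
# entropy using parameter-shift gradients. Training uses exact statevector
# probabilities; shot sampling is optional at inference.

#' Number of qubits needed to amplitude-encode f features
#' @param n_feature Feature count.
#' @return `log2` of the next power of two (at least 1).
#' @export
feature_qubits <- function(n_feature) {
  as.integer(log2(next_pow2(max(2L, n_feature))))
}

#' A variational circuit learner
#'
#' @param n_qubits Number of qubits (`>= 1`).
#' @param theta Parameter vector of length `6 * n_qubits` (two rotation
#'   layers, three angles per qubit). If `NULL`, initialized uniformly on
#'   `(-pi, pi]` under `seed`.
#' @param seed Seed for the random initialization.
#' @return Object of class `variational_learner`.
#' @export
variational_learner <- function(n_qubits, theta = NULL, seed = 1L) {
  n_qubits <- as.integer(n_qubits)
  if (n_qubits < 1L) stop("n_qubits must be >= 1")
  if (is.null(theta)) {
    theta <- with_seed(seed, stats::runif(6L * n_qubits, -pi, pi))
  }
  if (length(theta) != 6L * n_qubits) {
    stop("theta must have length 6 * n_qubits = ", 6L * n_qubits)
  }
  structure(list(n_qubits = n_qubits, theta = as.numeric(theta),
                 seed = as.integer(seed)),
            class = "variational_learner")
}

#' Trainable parameter count of a variational learner
#' @param learner A [variational_learner()].
#' @return `6 * n_qubits`.
#' @export
n_params <- function(learner) 6L * learner$n_qubits

## one rotation layer (3 angles per qubit, RZ then RY then RZ) as a dense matrix
rotation_layer_matrix <- function(angles, n) {
  mats <- lapply(seq_len(n), function(qb) {
    a <- angles[(qb - 1L) * 3L + 1:3]
    gate_rz(a[3L]) %*% gate_ry(a[2L]) %*% gate_rz(a[1L])
  })
  kron_le(mats)
}

## linear CNOT chain (i -> i+1) as a basis permutation; identity for n = 1
cnot_chain_perm <- function(n) {
  cur <- 0:(2^n - 1L)
  if (n > 1L) {
    for (i in 0:(n - 2L)) {
      flip <- bitwAnd(cur, bitwShiftL(1L, i)) > 0L
      cur <- ifelse(flip, bitwXor(cur, bitwShiftL(1L, i + 1L)), cur)
    }
  }
  as.integer(cur)
}

## encode sample rows of X into statevector columns (2^n x N)
encode_columns <- function(X, n) {
  X <- as.matrix(X)
  if (ncol(X) > 2^n) stop("too many features for ", n, " qubits")
  if (any(X < 0)) stop("amplitude encoding requires nonnegative features")
  nrm <- sqrt(rowSums(X^2))
  if (any(nrm == 0)) stop("cannot amplitude-encode an all-zero sample")
  Psi <- matrix(0, nrow = 2^n, ncol = nrow(X))
  Psi[seq_len(ncol(X)), ] <- t(X / nrm)
  Psi
}

## class-1 probabilities (qubit 0 = 1) for encoded columns under theta
varqc_probs <- function(theta, n, Psi, chain = cnot_chain_perm(n)) {
  A <- rotation_layer_matrix(theta[1:(3 * n)], n) %*% Psi
  B <- A
  B[chain + 1L, ] <- A
  Out <- rotation_layer_matrix(theta[(3 * n + 1):(6 * n)], n) %*% B
  one <- bitwAnd(0:(2^n - 1L), 1L) > 0L
  colSums(Mod(Out[one, , drop = FALSE])^2)
}

#' Build the variational ansatz circuit for one sample
#'
#' Amplitude encoding, a first RZ-RY-RZ rotation layer, a linear CNOT chain
#' between qubits `(i, i+1)` (present only when `n > 1`), and a second
#' rotation layer; the prediction is read from qubit 0.
#'
#' @param x Nonnegative feature vector.
#' @param theta Parameter vector of length `6n` where `n` is the qubit count
#'   implied by `length(x)`.
#' @return A circuit object runnable with [run_circuit()].
#' @export
build_ansatz <- function(x, theta) {
  enc <- amplitude_encode(x)
  n <- enc$n_qubits
  if (length(theta) != 6L * n) stop("theta must have length 6n = ", 6L * n)
  layer_ops <- function(offset) {
    unlist(lapply(seq_len(n) - 1L, function(qb) {
      a <- theta[offset + qb * 3L + 1:3]
      list(unitary_op(gate_rz(a[1L]), targets = qb),
           unitary_op(gate_ry(a[2L]), targets = qb),
           unitary_op(gate_rz(a[3L]), targets = qb))
    }), recursive = FALSE)
  }
  ops <- layer_ops(0L)
  if (n > 1L) {
    ops <- c(ops, lapply(0:(n - 2L), function(i) op_x(i + 1L, controls = i)))
  }
  ops <- c(ops, layer_ops(3L * n))
  qcircuit(n, enc, ops, registers = list(readout = 0L))
}

#' Class probabilities from the qubit-0 readout
#'
#' @param circuit A circuit built by [build_ansatz()] (or any circuit whose
#'   readout qubit is qubit 0).
#' @return `c(p0, p1)`, the probabilities of measuring qubit 0 as 0 / 1;
#'   they sum to 1.
#' @export
readout_probability <- function(circuit) {
  state <- run_circuit(circuit)
  p1 <- measure_probability(state, 0L, 1L)
  c(1 - p1, p1)
}

#' Predict class-1 probabilities with a variational learner
#'
#' @param learner A [variational_learner()].
#' @param X Sample-by-feature matrix (nonnegative, at most `2^n` features).
#' @param shots `NULL` for exact statevector probabilities, or a positive
#'   shot count for sampled estimates.
#' @param seed Seed for shot sampling.
#' @return Vector of `Pr(y = 1)` estimates, one per row of `X`.
#' @export
predict_varqc <- function(learner, X, shots = NULL, seed = NULL) {
  n <- learner$n_qubits
  p <- varqc_probs(learner$theta, n, encode_columns(X, n))
  if (is.null(shots)) return(p)
  vapply(seq_along(p), function(i) {
    sample_shots(p[i], shots, if (is.null(seed)) NULL else derive_seed(seed, i)) / shots
  }, numeric(1))
}

#' Binary cross-entropy loss
#'
#' @param p Predicted `Pr(y = 1)` per sample, clipped to
#'   `[1e-12, 1 - 1e-12]` before the logarithms.
#' @param y Binary labels.
#' @return Mean of `-(y log p + (1 - y) log(1 - p))`.
#' @export
bce_loss <- function(p, y) {
  if (length(p) != length(y)) stop("length mismatch between p and y")
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  mean(-(y * log(p) + (1 - y) * log(1 - p)))
}

## d(BCE)/d(p_i), with the same clipping as bce_loss
bce_dp <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  ((p - y) / (p * (1 - p))) / length(p)
}

## soft-vote ensemble machinery over a 6n x K parameter matrix ---------------

ensemble_probs <- function(thetas, n, Psi, chain) {
  P <- vapply(seq_len(ncol(thetas)),
              function(k) varqc_probs(thetas[, k], n, Psi, chain),
              numeric(ncol(Psi)))
  matrix(P, nrow = ncol(Psi))   # samples x learners
}

## gradient of the soft-vote BCE w.r.t. every entry of thetas (parameter shift)
ensemble_gradient <- function(thetas, n, Psi, y, chain) {
  K <- ncol(thetas)
  P <- ensemble_probs(thetas, n, Psi, chain)
  pbar <- rowMeans(P)
  dLdp <- bce_dp(pbar, y)
  G <- matrix(0, nrow = nrow(thetas), ncol = K)
  for (k in seq_len(K)) {
    for (j in seq_len(nrow(thetas))) {
      tp <- thetas[, k]; tp[j] <- tp[j] + pi / 2
      tm <- thetas[, k]; tm[j] <- tm[j] - pi / 2
      dp <- (varqc_probs(tp, n, Psi, chain) - varqc_probs(tm, n, Psi, chain)) / 2
      G[j, k] <- sum(dLdp * dp) / K
    }
  }
  G
}

#' Parameter-shift gradient of the cross-entropy loss
#'
#' Exact analytic gradient of the binary cross entropy of a single learner
#' on a batch, obtained from circuit evaluations at each angle shifted by
#' `+/- pi/2` and the classical chain rule through the loss.
#'
#' @param learner A [variational_learner()].
#' @param X Batch feature matrix.
#' @param y Batch labels.
#' @return Gradient vector of length `6n`.
#' @export
parameter_shift_gradient <- function(learner, X, y) {
  n <- learner$n_qubits
  as.vector(ensemble_gradient(matrix(learner$theta, ncol = 1L), n,
                              encode_columns(X, n), y, cnot_chain_perm(n)))
}

## Adam step on a flattened parameter vector; state carries m, v, t
adam_step <- function(theta, grad, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(theta = theta - lr * mhat / (sqrt(vhat) + eps), state = state)
}

## core mini-batch Adam trainer shared by single learners and soft-vote
## ensembles: thetas is 6n x K, the loss is the BCE of the mean prediction.
train_ensemble_core <- function(thetas, n, X, y, learning_rate, batch_size,
                                epochs, seed) {
  X <- as.matrix(X)
  if (nrow(X) == 0L) stop("empty training data")
  chain <- cnot_chain_perm(n)
  Psi_all <- encode_columns(X, n)
  npar <- length(thetas)
  state <- list(m = numeric(npar), v = numeric(npar), t = 0L)
  trace <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- with_seed(derive_seed(seed, 7L, ep), sample(nrow(X)))
    batches <- split(ord, ceiling(seq_along(ord) / batch_size))
    for (b in batches) {
      G <- ensemble_gradient(thetas, n, Psi_all[, b, drop = FALSE], y[b], chain)
      upd <- adam_step(as.vector(thetas), as.vector(G), state, learning_rate)
      thetas <- matrix(upd$theta, nrow = nrow(thetas))
      state <- upd$state
    }
    trace[ep] <- bce_loss(rowMeans(ensemble_probs(thetas, n, Psi_all, chain)), y)
  }
  list(thetas = thetas, loss_trace = trace)
}

#' Train a single variational learner
#'
#' Mini-batch gradient descent with Adam (`beta1 = 0.9`, `beta2 = 0.999`,
#' `eps = 1e-8`) on binary cross entropy; batches are drawn without
#' replacement each epoch under a seeded shuffle.
#'
#' @param learner A [variational_learner()].
#' @param X Training feature matrix.
#' @param y Binary labels.
#' @param learning_rate Adam learning rate.
#' @param batch_size Mini-batch size.
#' @param epochs Number of passes over the data (default 30).
#' @param seed Seed controlling the batch shuffles.
#' @return The trained learner, with the per-epoch training loss attached as
#'   `loss_trace`.
#' @export
train_learner <- function(learner, X, y, learning_rate = 0.1, batch_size = 4L,
                          epochs = 30L, seed = 1L) {
  fit <- train_ensemble_core(matrix(learner$theta, ncol = 1L),
                             learner$n_qubits, X, y,
                             learning_rate, batch_size, epochs, seed)
  learner$theta <- as.vector(fit$thetas)
  learner$loss_trace <- fit$loss_trace
  learner
}

#' The full variational hyperparameter grid
#'
#' Three Adam learning rates x five batch sizes x seven ensemble sizes
#' (105 configurations).
#'
#' @return A data.frame with columns learning_rate, batch_size, n_learners.
#' @export
default_variational_grid <- function() {
  expand.grid(learning_rate = c(1e-3, 1e-2, 1e-1),
              batch_size = c(1L, 2L, 4L, 8L, 16L),
              n_learners = 1:7, KEEP.OUT.ATTRS = FALSE)
}

## stratified fold assignment (1..k per sample)
stratified_folds <- function(y, k, seed = 1L) {
  if (k < 2L) stop("need at least 2 folds")
  if (min(table(y)) < k) stop("fold count exceeds the smallest class")
  fold <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Cross-validated grid search over soft-voting ensembles
#'
#' For every configuration, trains a soft-voting ensemble on each of `folds`
#' stratified training folds and records the median validation accuracy;
#' configurations are returned ranked by it (descending).
#'
#' @param X Feature matrix; `y` binary labels.
#' @param y Binary labels.
#' @param grid Data.frame with columns learning_rate, batch_size,
#'   n_learners (default: [default_variational_grid()]).
#' @param folds Number of cross-validation folds (default 4).
#' @param epochs Training epochs per fit.
#' @param seed Seed controlling folds, initializations and shuffles.
#' @return The grid with columns `median_val_accuracy` and `rank` added,
#'   sorted best-first.
#' @export
grid_search <- function(X, y, grid = default_variational_grid(), folds = 4L,
                        epochs = 30L, seed = 1L) {
  if (nrow(grid) == 0L) stop("empty grid")
  X <- as.matrix(X)
  fold <- stratified_folds(y, folds, seed = derive_seed(seed, 11L))
  grid$median_val_accuracy <- vapply(seq_len(nrow(grid)), function(g) {
    accs <- vapply(seq_len(folds), function(f) {
      tr <- fold != f
      ens <- soft_vote_fit(X[tr, , drop = FALSE], y[tr],
                           n_learners = grid$n_learners[g],
                           learning_rate = grid$learning_rate[g],
                           batch_size = grid$batch_size[g],
                           epochs = epochs, seed = derive_seed(seed, g, f))
      mean(classify(soft_vote_predict(ens, X[!tr, , drop = FALSE])) == y[!tr])
    }, numeric(1))
    stats::median(accs)
  }, numeric(1))
  grid$rank <- rank(-grid$median_val_accuracy, ties.method = "first")
  grid[order(grid$rank), ]
}
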