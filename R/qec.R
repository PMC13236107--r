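# Quantum ensemble cosine classifier (QEC): d control qubits put 2^d
# transformations of the encoded training set into superposition; the
# cosine-classifier interference block then acts on sample slot 0, and the
# single ancilla measurement returns the average prediction over all 2^d
# trajectories. The QECRU variant replaces the random sample-slot SWAPs with
# Haar-random unitaries on the joint data register.

#' Configuration of an ensemble cosine classifier
#'
#' @param d Number of control qubits (ensemble size `2^d`).
#' @param n_train Training samples encoded per circuit.
#' @param n_feature Features per sample (padded to a power of two).
#' @param n_swap Number of random sample-slot SWAPs composed into each
#'   transformation (swap variant).
#' @param shots Shot count for finite sampling (default 8192).
#' @param variant `"swap"` for random slot permutations, `"haar"` for
#'   Haar-random unitaries on the joint data register (QECRU).
#' @param seed Integer seed from which the 2d random transformations are
#'   drawn (fixed per configuration, so circuit and trajectory oracle see
#'   identical unitaries).
#' @return Object of class `qec_config`.
#' @export
qec_config <- function(d, n_train, n_feature, n_swap = 1L, shots = 8192L,
                       variant = c("swap", "haar"), seed = 1L) {
  variant <- match.arg(variant)
  d <- as.integer(d); n_train <- as.integer(n_train)
  n_feature <- as.integer(n_feature); n_swap <- as.integer(n_swap)
  if (d < 1L) stop("d must be >= 1")
  if (n_train < 1L) stop("n_train must be >= 1")
  if (n_feature < 1L || n_swap < 1L) stop("n_feature and n_swap must be positive")
  cfg <- structure(list(d = d, n_train = n_train, n_feature = n_feature,
                        n_swap = n_swap, shots = as.integer(shots),
                        variant = variant, seed = as.integer(seed)),
                   class = "qec_config")
  if (variant == "haar" && qec_data_qubits(cfg) > 12L) {
    stop("resource error: Haar transformations capped at 12 data qubits, got ",
         qec_data_qubits(cfg))
  }
  cfg
}

qec_feature_qubits <- function(cfg) as.integer(log2(next_pow2(max(2L, cfg$n_feature))))
qec_data_qubits <- function(cfg) cfg$n_train * qec_feature_qubits(cfg)
qec_train_register_qubits <- function(cfg) qec_data_qubits(cfg) + cfg$n_train

#' Circuit width of an ensemble cosine classifier
#'
#' Width = `n_train * log2(f)` data qubits + `n_train` basis-encoded label
#' qubits + `log2(f)` test qubits + `d` control qubits + 1 prediction
#' ancilla. It scales logarithmically with the feature count and linearly
#' with the training sample count and the control register size.
#'
#' @param cfg A [qec_config()].
#' @return Total qubit count.
#' @export
qec_width <- function(cfg) {
  stopifnot(inherits(cfg, "qec_config"))
  q <- qec_feature_qubits(cfg)
  cfg$n_train * q + cfg$n_train + q + cfg$d + 1L
}

#' Parameter grid of the ensemble cosine classifiers
#'
#' Enumerates the benchmark configuration grid (`d` in 1..3, `n_swap` in
#' {1,2,4}, `n_feature` in {2,4,8}; `n_train` in {2,4,8} for the swap
#' variant, {2,4} for the Haar variant) together with each circuit's width.
#'
#' @param variant `"swap"` or `"haar"`.
#' @return A data.frame with columns d, n_train, n_swap, n_feature, width.
#' @export
qec_parameter_grid <- function(variant = c("swap", "haar")) {
  variant <- match.arg(variant)
  n_train <- if (variant == "swap") c(2L, 4L, 8L) else c(2L, 4L)
  g <- expand.grid(d = 1:3, n_train = n_train, n_swap = c(1L, 2L, 4L),
                   n_feature = c(2L, 4L, 8L), KEEP.OUT.ATTRS = FALSE)
  g$width <- vapply(seq_len(nrow(g)), function(i) {
    q <- as.integer(log2(next_pow2(max(2L, g$n_feature[i]))))
    g$n_train[i] * q + g$n_train[i] + q + g$d[i] + 1L
  }, integer(1))
  g
}

## qubit-permutation -> basis permutation over m qubits (0-based)
qubit_perm_to_basis_perm <- function(sigma) {
  m <- length(sigma)
  if (m > 20L) stop("resource error: permutation register too large")
  k <- 0:(2^m - 1)
  out <- numeric(2^m)
  for (qb in seq_len(m)) {
    out <- out + (bitwAnd(k, bitwShiftL(1L, qb - 1L)) > 0L) * 2^sigma[qb]
  }
  as.integer(out)
}

## basis permutation for swapping sample slots a and b (0-based slots)
slot_swap_perm <- function(n_train, q, a, b) {
  sigma <- 0:(n_train * q + n_train - 1L)
  sigma[(a * q + 1L):(a * q + q)] <- (b * q):(b * q + q - 1L)
  sigma[(b * q + 1L):(b * q + q)] <- (a * q):(a * q + q - 1L)
  sigma[n_train * q + a + 1L] <- n_train * q + b
  sigma[n_train * q + b + 1L] <- n_train * q + a
  qubit_perm_to_basis_perm(sigma)
}

#' Sample one random slot-swap transformation
#'
#' Composes `n_swap` SWAPs of uniformly chosen sample-slot pairs; each SWAP
#' exchanges a pair's data subregisters together with their label qubits, so
#' the result is a basis permutation (hence unitary) on the train register.
#'
#' @param cfg A [qec_config()] with `variant = "swap"` and `n_train >= 2`.
#' @param seed Optional seed for the pair draws.
#' @return A [unitary_op()] (permutation form) targeting the train register.
#' @export
sample_swap_transformation <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "qec_config"))
  if (cfg$variant != "swap") stop("swap transformations require variant = 'swap'")
  if (cfg$n_train < 2L) stop("slot swaps need at least two training samples")
  perm <- if (is.null(seed)) sample_swap_perm_raw(cfg) else {
    with_seed(seed, sample_swap_perm_raw(cfg))
  }
  unitary_op(perm = perm, targets = 0:(qec_train_register_qubits(cfg) - 1L))
}

sample_swap_perm_raw <- function(cfg) {
  q <- qec_feature_qubits(cfg)
  nt <- cfg$n_train
  cur <- 0:(2^qec_train_register_qubits(cfg) - 1L)
  for (s in seq_len(cfg$n_swap)) {
    pair <- sample(nt, 2L)  # uniform unordered pair, with replacement across draws
    p <- slot_swap_perm(nt, q, pair[1L] - 1L, pair[2L] - 1L)
    cur <- p[cur + 1L]
  }
  as.integer(cur)
}

## the 2d raw transformations of a config, deterministically from cfg$seed.
## swap variant: basis-permutation vectors; haar variant: dense matrices.
qec_transformations <- function(cfg) {
  with_seed(derive_seed(cfg$seed, 101L), {
    lapply(seq_len(cfg$d), function(i) {
      lapply(1:2, function(j) {
        if (cfg$variant == "swap") sample_swap_perm_raw(cfg)
        else sample_haar_unitary(qec_data_qubits(cfg))
      })
    })
  })
}

qec_check_inputs <- function(cfg, x_train, y_train, x_test) {
  x_train <- as.matrix(x_train)
  if (nrow(x_train) != cfg$n_train) {
    stop("need exactly n_train = ", cfg$n_train, " training samples")
  }
  if (length(y_train) != cfg$n_train) stop("y_train length mismatch")
  if (!all(y_train %in% c(0L, 1L))) stop("labels must be binary")
  if (ncol(x_train) > 2^qec_feature_qubits(cfg)) stop("too many features for config")
  if (length(x_test) != ncol(x_train)) stop("x_test feature length mismatch")
  x_train
}

#' Build the ensemble cosine-classifier circuit
#'
#' State preparation (amplitude-encoded data slots, basis-encoded labels,
#' encoded test register, Walsh-Hadamard on the control register), sampling
#' in superposition (per control qubit i: controlled-U(i,1) on control 1,
#' X, controlled-U(i,2), X), then the cosine-classifier interference block
#' between sample slot 0 and the test register with slot 0's label qubit
#' controlling the final flip of the prediction ancilla.
#'
#' @param cfg A [qec_config()].
#' @param x_train `n_train x f` matrix of training features in `[0, 1]`.
#' @param y_train Binary labels, one per training sample.
#' @param x_test Test feature vector.
#' @return A circuit object runnable with [run_circuit()].
#' @export
build_qec_circuit <- function(cfg, x_train, y_train, x_test) {
  x_train <- qec_check_inputs(cfg, x_train, y_train, x_test)
  q <- qec_feature_qubits(cfg)
  nt <- cfg$n_train
  n <- qec_width(cfg)
  check_sim_width(n)

  data_qubits <- 0:(nt * q - 1L)
  label_qubits <- (nt * q):(nt * q + nt - 1L)
  test_qubits <- (nt * q + nt):(nt * q + nt + q - 1L)
  ctrl_qubits <- (nt * q + nt + q):(nt * q + nt + q + cfg$d - 1L)
  anc <- n - 1L

  enc <- function(v) {
    s <- amplitude_encode(v)
    if (s$n_qubits != q) {  # pad up to the configured register size
      s <- statevector(c(s$amplitudes, rep(0, 2^q - length(s$amplitudes))))
    }
    s$amplitudes
  }
  parts <- c(lapply(seq_len(nt), function(s) enc(x_train[s, ])),
             lapply(seq_len(nt), function(s) if (y_train[s] == 1L) c(0, 1) else c(1, 0)),
             list(enc(x_test)),
             rep(list(c(1, 0)), cfg$d),
             list(c(1, 0)))
  init <- statevector(kron_le(parts))

  tf <- qec_transformations(cfg)
  tf_targets <- if (cfg$variant == "swap") {
    0:(qec_train_register_qubits(cfg) - 1L)
  } else {
    data_qubits
  }
  as_op <- function(raw, ctrl) {
    if (cfg$variant == "swap") unitary_op(perm = raw, targets = tf_targets, controls = ctrl)
    else unitary_op(matrix = raw, targets = tf_targets, controls = ctrl)
  }

  ops <- lapply(ctrl_qubits, op_h)
  for (i in seq_len(cfg$d)) {
    ci <- ctrl_qubits[i]
    ops <- c(ops, list(as_op(tf[[i]][[1L]], ci), op_x(ci),
                       as_op(tf[[i]][[2L]], ci), op_x(ci)))
  }
  ops <- c(ops,
           list(op_h(anc)),
           lapply(seq_len(q) - 1L, function(k) op_swap(k, test_qubits[k + 1L], controls = anc)),
           list(op_h(anc)),
           list(op_x(anc, controls = label_qubits[1L])))

  qcircuit(n, init, ops,
           registers = list(data = data_qubits, labels = label_qubits,
                            test = test_qubits, control = ctrl_qubits,
                            ancilla = anc))
}

#' Ensemble cosine-classifier prediction
#'
#' Runs the QEC (or QECRU) circuit and measures the prediction ancilla. The
#' exact statevector value is the arithmetic mean over the `2^d` trajectory
#' probabilities (see [enumerate_trajectories()]).
#'
#' @inheritParams build_qec_circuit
#' @param shots `NULL` for the exact probability, or a positive shot count.
#' @param seed Seed for shot sampling.
#' @return Estimated `Pr(y_hat = 1)` in `[0, 1]`.
#' @export
predict_qec <- function(cfg, x_train, y_train, x_test, shots = NULL, seed = NULL) {
  circ <- build_qec_circuit(cfg, x_train, y_train, x_test)
  p <- measure_probability(run_circuit(circ), circ$registers$ancilla, 1L)
  if (is.null(shots)) return(p)
  sample_shots(p, shots, seed) / shots
}

#' @rdname predict_qec
#' @export
predict_qecru <- function(cfg, x_train, y_train, x_test, shots = NULL, seed = NULL) {
  stopifnot(inherits(cfg, "qec_config"))
  if (cfg$variant != "haar") stop("predict_qecru requires variant = 'haar'")
  predict_qec(cfg, x_train, y_train, x_test, shots = shots, seed = seed)
}

#' Classical trajectory enumeration (oracle)
#'
#' Classically composes, for each of the `2^d` control bitstrings, the
#' selected transformation product, applies it to the encoded train-register
#' state by direct permutation/matrix algebra (no circuit simulation), and
#' evaluates the swap-test readout on sample slot 0: the probability equals
#' `1/2 + D^2/2` against the slot-0 sample when that slot holds a product
#' state, and more generally the swap-test POVM applied to the reduced
#' slot-0 data + label state.
#'
#' @inheritParams build_qec_circuit
#' @return Numeric vector of `2^d` per-trajectory probabilities; their mean
#'   is the exact circuit prediction.
#' @export
enumerate_trajectories <- function(cfg, x_train, y_train, x_test) {
  x_train <- qec_check_inputs(cfg, x_train, y_train, x_test)
  q <- qec_feature_qubits(cfg)
  nt <- cfg$n_train
  tf <- qec_transformations(cfg)

  enc <- function(v) {
    s <- amplitude_encode(v)$amplitudes
    c(s, rep(0, 2^q - length(s)))
  }
  data0 <- kron_le(lapply(seq_len(nt), function(s) enc(x_train[s, ])))
  labels0 <- kron_le(lapply(seq_len(nt), function(s) {
    if (y_train[s] == 1L) c(0, 1) else c(1, 0)
  }))
  t_amp <- enc(x_test)

  n_env <- nt * q + nt - q             # train-register qubits above slot 0's data
  label0_bit <- 2^(q * (nt - 1L))      # slot-0 label position within the environment
  env_idx <- 0:(2^n_env - 1L)
  l1 <- bitwAnd(env_idx, label0_bit) > 0L

  branch_prob <- function(psi) {
    M <- matrix(psi, nrow = 2^q)
    s <- as.vector(crossprod(Conj(t_amp), M))   # overlap with the test state per env config
    w <- colSums(Mod(M)^2)
    sum((w[l1] + Mod(s[l1])^2) / 2) + sum((w[!l1] - Mod(s[!l1])^2) / 2)
  }

  psi0_full <- kron_le(list(data0, labels0))
  vapply(0:(2^cfg$d - 1L), function(b) {
    sel <- function(i) if (bitwAnd(b, bitwShiftL(1L, i - 1L)) > 0L) 1L else 2L
    if (cfg$variant == "swap") {
      cur <- 0:(length(psi0_full) - 1L)
      for (i in seq_len(cfg$d)) cur <- tf[[i]][[sel(i)]][cur + 1L]
      psi <- psi0_full
      psi[cur + 1L] <- psi0_full
    } else {
      U <- diag(2^qec_data_qubits(cfg))
      for (i in seq_len(cfg$d)) U <- tf[[i]][[sel(i)]] %*% U
      psi <- kron_le(list(as.vector(U %*% data0), labels0))
    }
    branch_prob(psi)
  }, numeric(1))
}
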