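# Quantum cosine classifier (QCC): the swap-test weak learner. A single
# training sample and a test sample are amplitude-encoded, interfered through
# an ancilla-controlled SWAP, and the training label conditionally flips the
# ancilla so that Pr(ancilla = 1) = Pr(y_test = 1).

#' Cosine similarity of two nonnegative feature vectors
#'
#' @param a,b Nonnegative numeric vectors of equal length, each with at least
#'   one nonzero entry.
#' @return `<a, b> / (|a| |b|)`, in `[0, 1]` for nonnegative inputs (1 for
#'   parallel vectors, 0 for orthogonal ones).
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  if (any(a < 0) || any(b < 0)) stop("features must be nonnegative")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("zero vector has no direction")
  sum(a * b) / (na * nb)
}

#' Match probability of the cosine classifier
#'
#' Closed form of the swap-test readout: the probability that the test sample
#' shares the training sample's label is `1/2 + D^2/2`, where `D` is the
#' cosine similarity between the two samples.
#'
#' @param D Cosine similarity in `[0, 1]`.
#' @return Probability in `[1/2, 1]`.
#' @export
analytic_probability <- function(D) {
  if (any(D < -1e-12) || any(D > 1 + 1e-12)) stop("D must lie in [0, 1]")
  D <- pmin(pmax(D, 0), 1)
  0.5 + D^2 / 2
}

#' A single cosine-classifier instance
#'
#' @param x_train Training feature vector in `[0, 1]^f` (nonzero).
#' @param y_train Binary training label.
#' @param x_test Test feature vector of the same length.
#' @param shots Positive shot count for finite sampling (default 8192).
#' @return Object of class `qcc_instance`.
#' @export
qcc_instance <- function(x_train, y_train, x_test, shots = 8192L) {
  if (length(x_train) != length(x_test)) stop("feature lengths differ")
  if (!y_train %in% c(0L, 1L)) stop("y_train must be 0 or 1")
  if (sum(x_train) == 0 || sum(x_test) == 0) stop("feature vectors must be nonzero")
  structure(list(x_train = x_train, y_train = as.integer(y_train),
                 x_test = x_test, shots = as.integer(shots)),
            class = "qcc_instance")
}

#' Width of a cosine-classifier circuit
#'
#' @param n_feature Number of features (padded to the next power of two).
#' @return Qubit count `2 log2(f) + 2`: train register, one label qubit, test
#'   register, one prediction ancilla. Two features need four qubits.
#' @export
qcc_width <- function(n_feature) {
  q <- as.integer(log2(next_pow2(max(2L, n_feature))))
  2L * q + 2L
}

#' Build the cosine-classifier circuit
#'
#' Registers (little-endian, low qubits first): train data (`q` qubits),
#' label (1, basis-encoded), test data (`q`), prediction ancilla (1).
#' Gates: Hadamard on the ancilla, qubit-wise ancilla-controlled SWAP between
#' the train and test registers, Hadamard on the ancilla, then a CNOT from
#' the label qubit onto the ancilla.
#'
#' @param inst A [qcc_instance()].
#' @return A circuit object runnable with [run_circuit()].
#' @export
build_qcc_circuit <- function(inst) {
  stopifnot(inherits(inst, "qcc_instance"))
  train <- amplitude_encode(inst$x_train)
  test <- amplitude_encode(inst$x_test)
  q <- train$n_qubits
  n <- 2L * q + 2L
  check_sim_width(n)
  label_q <- q
  test_q <- (q + 1L):(2L * q)
  anc <- 2L * q + 1L
  label_state <- if (inst$y_train == 1L) c(0, 1) else c(1, 0)
  init <- statevector(kron_le(list(train$amplitudes, label_state,
                                   test$amplitudes, c(1, 0))))
  ops <- c(
    list(op_h(anc)),
    lapply(seq_len(q) - 1L, function(k) op_swap(k, test_q[k + 1L], controls = anc)),
    list(op_h(anc)),
    list(op_x(anc, controls = label_q))
  )
  qcircuit(n, init, ops,
           registers = list(train = 0:(q - 1L), label = label_q,
                            test = test_q, ancilla = anc))
}

#' Cosine-classifier prediction
#'
#' Runs the swap-test circuit and reads the prediction ancilla. The exact
#' statevector value equals `1/2 + D^2/2` when `y_train = 1` and
#' `1/2 - D^2/2` when `y_train = 0`; with finite `shots`, the estimate is the
#' observed fraction of 1-outcomes.
#'
#' @param inst A [qcc_instance()].
#' @param shots `NULL` for the exact statevector probability, or a positive
#'   shot count.
#' @param seed Seed for shot sampling.
#' @return Estimated `Pr(y_hat = 1)`.
#' @export
predict_qcc <- function(inst, shots = NULL, seed = NULL) {
  circ <- build_qcc_circuit(inst)
  p <- measure_probability(run_circuit(circ), circ$registers$ancilla, 1L)
  if (is.null(shots)) return(p)
  sample_shots(p, shots, seed) / shots
}

#' Threshold a class-1 probability into a label
#'
#' @param p Probability in `[0, 1]`.
#' @return 1 if `p >= 0.5` (ties go to class 1), else 0.
#' @export
classify <- function(p) {
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  as.integer(p >= 0.5)
}
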