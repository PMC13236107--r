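# Dense statevector engine. Qubit ordering is little-endian throughout the
# package: qubit 0 is the least significant bit of the amplitude index.

#' Quantum state vector
#'
#' Construct a normalized state over `n` qubits from a vector of complex
#' amplitudes of length `2^n` (little-endian: qubit 0 is the least significant
#' bit of the amplitude index).
#'
#' @param amplitudes Complex (or numeric) vector whose length is a power of
#'   two. Must have unit norm up to small numerical error; it is renormalized
#'   exactly on construction.
#' @param n_qubits Optional expected qubit count, checked against the length.
#' @return An object of class `statevector` with elements `amplitudes` and
#'   `n_qubits`.
#' @export
statevector <- function(amplitudes, n_qubits = NULL) {
  len <- length(amplitudes)
  if (len < 1L) stop("empty amplitude vector")
  n <- as.integer(round(log2(len)))
  if (2^n != len) stop("amplitude length must be a power of two, got ", len)
  if (!is.null(n_qubits) && as.integer(n_qubits) != n) {
    stop("length ", len, " does not match n_qubits = ", n_qubits)
  }
  nrm <- sqrt(sum(Mod(amplitudes)^2))
  if (abs(nrm - 1) > 1e-8) stop("state is not normalized (norm = ", format(nrm), ")")
  structure(list(amplitudes = as.complex(amplitudes) / nrm, n_qubits = n),
            class = "statevector")
}

#' @export
print.statevector <- function(x, ...) {
  cat("<statevector>", x$n_qubits, "qubits,", length(x$amplitudes), "amplitudes\n")
  invisible(x)
}

next_pow2 <- function(k) {
  p <- 1L
  while (p < k) p <- p * 2L
  p
}

#' Amplitude encoding of a classical feature vector
#'
#' Maps a nonnegative feature vector onto the amplitudes of a quantum state.
#' Vectors whose length is not a power of two are zero-padded up to the next
#' power of two *before* normalization.
#'
#' @param x Nonnegative numeric vector with at least one nonzero entry
#'   (features are expected min-max scaled to `[0, 1]`).
#' @return A [statevector()] on `log2` of the padded length qubits.
#' @export
amplitude_encode <- function(x) {
  if (!is.numeric(x) || length(x) == 0L) stop("x must be a nonempty numeric vector")
  if (any(x < 0)) stop("amplitude encoding requires nonnegative features")
  nrm <- sqrt(sum(x^2))
  if (nrm == 0) stop("cannot amplitude-encode the all-zero vector")
  len <- next_pow2(max(2L, length(x)))
  padded <- c(x, rep(0, len - length(x)))
  statevector(padded / nrm)
}

## offsets of each index pattern over the given (0-based) qubit positions
bit_offsets <- function(qubits) {
  m <- length(qubits)
  if (m == 0L) return(0)
  j <- 0:(2^m - 1)
  off <- numeric(2^m)
  for (k in seq_len(m)) {
    off <- off + (bitwAnd(j, bitwShiftL(1L, k - 1L)) > 0L) * 2^qubits[k]
  }
  off
}

is_unitary_matrix <- function(M, tol = 1e-9) {
  d <- nrow(M)
  if (d != ncol(M)) return(FALSE)
  if (d <= 512L) {
    return(max(Mod(crossprod(Conj(M), M) - diag(d))) < tol)
  }
  # large matrices: sampled column check (unit norms + pairwise orthogonality)
  cols <- unique(c(1L, d, round(seq(1, d, length.out = 16L))))
  S <- M[, cols, drop = FALSE]
  G <- crossprod(Conj(S), S)
  max(Mod(G - diag(length(cols)))) < tol
}

#' Unitary operation on a subset of qubits
#'
#' Wraps either a dense unitary matrix or a basis permutation acting on
#' `targets`, optionally conditioned on every qubit in `controls` being 1.
#' Target order is little-endian within the operator: `targets[1]` is the
#' least significant bit of the operator's own index space.
#'
#' @param matrix Complex square matrix of dimension `2^length(targets)`;
#'   must be unitary. Mutually exclusive with `perm`.
#' @param targets Integer vector of distinct 0-based qubit indices.
#' @param controls Optional 0-based control qubit indices (disjoint from
#'   `targets`).
#' @param perm Optional 0-based permutation of `0:(2^m - 1)` mapping input
#'   basis index `k` to output index `perm[k + 1]` (used for permutation
#'   gates such as X, SWAP and sample-slot shuffles without materializing
#'   a dense matrix).
#' @return An object of class `unitary_op`.
#' @export
unitary_op <- function(matrix = NULL, targets, controls = integer(0), perm = NULL) {
  targets <- as.integer(targets)
  controls <- as.integer(controls)
  if (anyDuplicated(targets)) stop("duplicate target qubits")
  if (length(intersect(targets, controls))) stop("controls overlap targets")
  m <- length(targets)
  if (is.null(matrix) == is.null(perm)) stop("supply exactly one of matrix or perm")
  if (!is.null(matrix)) {
    if (nrow(matrix) != 2^m) stop("matrix dimension does not match targets")
    if (!is_unitary_matrix(matrix)) stop("matrix is not unitary")
    matrix <- `dim<-`(as.complex(matrix), dim(matrix))
  } else {
    perm <- as.integer(perm)
    if (length(perm) != 2^m || !setequal(perm, 0:(2^m - 1))) {
      stop("perm must be a permutation of 0:(2^m - 1)")
    }
  }
  structure(list(matrix = matrix, perm = perm, targets = targets,
                 controls = controls),
            class = "unitary_op")
}

#' Apply a unitary operation to a state
#'
#' @param state A [statevector()].
#' @param op A [unitary_op()] whose target/control indices lie inside the
#'   register.
#' @return The evolved [statevector()]; the norm is preserved to within
#'   `1e-10` per application.
#' @export
sv_apply <- function(state, op) {
  stopifnot(inherits(state, "statevector"), inherits(op, "unitary_op"))
  n <- state$n_qubits
  tq <- op$targets
  cq <- op$controls
  if (length(c(tq, cq)) && max(c(tq, cq)) >= n) stop("qubit index outside register")
  if (any(c(tq, cq) < 0)) stop("negative qubit index")
  rest <- setdiff(0:(n - 1L), c(tq, cq))
  offs_t <- bit_offsets(tq)
  offs_r <- bit_offsets(rest) + sum(2^cq) * (length(cq) > 0)
  if (length(cq) == 0L) offs_r <- bit_offsets(rest)
  idx <- outer(offs_t, offs_r, `+`) + 1
  a <- state$amplitudes
  A <- matrix(a[idx], nrow = length(offs_t))
  if (!is.null(op$perm)) {
    B <- A
    B[op$perm + 1L, ] <- A
  } else {
    B <- op$matrix %*% A
  }
  a[idx] <- B
  state$amplitudes <- a
  state
}

#' Probability of a single-qubit measurement outcome
#'
#' @param state A [statevector()].
#' @param qubit 0-based qubit index.
#' @param outcome 0 or 1.
#' @return The Born-rule probability in `[0, 1]`; outcomes 0 and 1 sum to 1.
#' @export
measure_probability <- function(state, qubit, outcome) {
  stopifnot(inherits(state, "statevector"))
  qubit <- as.integer(qubit)
  if (qubit < 0L || qubit >= state$n_qubits) stop("invalid qubit index")
  if (!outcome %in% c(0L, 1L)) stop("outcome must be 0 or 1")
  idx <- 0:(length(state$amplitudes) - 1L)
  bit <- bitwAnd(idx, bitwShiftL(1L, qubit)) > 0L
  sum(Mod(state$amplitudes[if (outcome == 1L) bit else !bit])^2)
}

#' Finite-shot sampling of a Bernoulli outcome
#'
#' @param p Success probability in `[0, 1]`.
#' @param shots Positive number of repetitions.
#' @param seed Optional integer seed; sampling is reproducible under a fixed
#'   seed and leaves the global RNG state untouched.
#' @return Observed count of successes (a binomial draw).
#' @export
sample_shots <- function(p, shots, seed = NULL) {
  if (!is.numeric(p) || p < -1e-12 || p > 1 + 1e-12) stop("p must lie in [0, 1]")
  p <- min(max(p, 0), 1)
  shots <- as.integer(shots)
  if (is.na(shots) || shots <= 0L) stop("shots must be a positive integer")
  draw <- function() stats::rbinom(1L, shots, p)
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Sample a Haar-random unitary matrix
#'
#' Draws from the unitarily invariant (Haar) measure on `U(2^n)`: a standard
#' complex Gaussian matrix is QR-decomposed and the orthogonal factor is
#' rescaled column-wise by the phases of the diagonal of the triangular
#' factor.
#'
#' @param n_qubits Number of qubits (matrix dimension `2^n_qubits`); capped
#'   at 12 qubits.
#' @param seed Optional integer seed for reproducible draws.
#' @return A complex unitary matrix of dimension `2^n_qubits`.
#' @export
sample_haar_unitary <- function(n_qubits, seed = NULL) {
  n_qubits <- as.integer(n_qubits)
  if (is.na(n_qubits) || n_qubits < 1L) stop("n_qubits must be >= 1")
  if (n_qubits > 12L) {
    stop("resource error: Haar sampling capped at 12 qubits (dimension 4096)")
  }
  d <- 2L^n_qubits
  draw <- function() {
    Z <- matrix(complex(real = stats::rnorm(d * d), imaginary = stats::rnorm(d * d)),
                nrow = d) / sqrt(2)
    dec <- qr(Z)
    Q <- qr.Q(dec)
    r <- diag(qr.R(dec))
    ph <- r / Mod(r)
    sweep(Q, 2L, ph, `*`)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

## --- elementary gates -------------------------------------------------------

gate_h <- function() matrix(c(1, 1, 1, -1), 2L) / sqrt(2)
gate_x <- function() matrix(c(0, 1, 1, 0), 2L)
gate_rz <- function(a) diag(c(exp(-1i * a / 2), exp(1i * a / 2)))
gate_ry <- function(a) matrix(c(cos(a / 2), sin(a / 2), -sin(a / 2), cos(a / 2)), 2L)
perm_swap2 <- function() c(0L, 2L, 1L, 3L)  # SWAP of two qubits as a basis permutation

op_h <- function(q) unitary_op(gate_h(), targets = q)
op_x <- function(q, controls = integer(0)) {
  unitary_op(perm = c(1L, 0L), targets = q, controls = controls)
}
op_swap <- function(q1, q2, controls = integer(0)) {
  unitary_op(perm = perm_swap2(), targets = c(q1, q2), controls = controls)
}

## --- circuits ---------------------------------------------------------------

#' @noRd
qcircuit <- function(n_qubits, init, ops, registers = list()) {
  structure(list(n_qubits = as.integer(n_qubits), init = init, ops = ops,
                 registers = registers),
            class = "qcircuit")
}

#' @export
print.qcircuit <- function(x, ...) {
  cat("<qcircuit>", x$n_qubits, "qubits,", length(x$ops), "ops\n")
  if (length(x$registers)) {
    for (nm in names(x$registers)) {
      cat("  ", nm, ": q", paste(x$registers[[nm]], collapse = ","), "\n", sep = "")
    }
  }
  invisible(x)
}

#' Run a circuit on the statevector simulator
#'
#' @param circuit A circuit object (initial product state plus an ordered
#'   list of [unitary_op()] gates).
#' @return The final [statevector()].
#' @export
run_circuit <- function(circuit) {
  stopifnot(inherits(circuit, "qcircuit"))
  state <- circuit$init
  for (op in circuit$ops) state <- sv_apply(state, op)
  state
}

## kron of per-register states listed from qubit 0 upwards (little-endian)
kron_le <- function(parts) {
  Reduce(function(a, b) kronecker(b, a), parts)
}

sim_qubit_cap <- function() 24L

check_sim_width <- function(n_qubits) {
  if (n_qubits > sim_qubit_cap()) {
    stop("resource error: ", n_qubits, " qubits exceeds the ",
         sim_qubit_cap(), "-qubit statevector budget")
  }
  invisible(n_qubits)
}
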