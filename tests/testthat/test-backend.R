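test_that("amplitude encoding normalizes, pads, and rejects bad input", {
  expect_equal(amplitude_encode(c(1, 0))$amplitudes, as.complex(c(1, 0)))
  expect_equal(amplitude_encode(c(3, 4))$amplitudes, as.complex(c(0.6, 0.8)))

  enc <- amplitude_encode(c(1, 1, 1))  # padded before normalization
  expect_equal(enc$n_qubits, 2L)
  expect_equal(enc$amplitudes, as.complex(c(1, 1, 1, 0) / sqrt(3)))

  expect_error(amplitude_encode(c(0, 0)), "all-zero")
  expect_error(amplitude_encode(c(-1, 2)), "nonnegative")
  expect_error(statevector(c(1, 0, 0)), "power of two")
})

test_that("gate application matches basic circuit identities", {
  zero <- statevector(c(1, 0))
  expect_equal(sv_apply(zero, unitary_op(gate_x(), targets = 0L))$amplitudes,
               as.complex(c(0, 1)))

  # identity leaves any state unchanged
  st <- statevector(c(1, 2, 3, 4) / sqrt(30))
  id <- unitary_op(diag(4) + 0i, targets = 0:1)
  expect_equal(sv_apply(st, id)$amplitudes, st$amplitudes)

  # |+>|0> --CNOT(0->1)--> Bell state (qubit 0 is the low index bit)
  plus0 <- statevector(c(1, 1, 0, 0) / sqrt(2))
  bell <- sv_apply(plus0, op_x(1L, controls = 0L))
  expect_equal(bell$amplitudes, as.complex(c(1, 0, 0, 1) / sqrt(2)))

  expect_error(unitary_op(matrix(c(1, 1, 0, 1), 2), targets = 0L), "unitary")
})

test_that("norm is conserved under random gate applications", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(2:4, 1)
    amps <- complex(real = rnorm(2^n), imaginary = rnorm(2^n))
    st <- statevector(amps / sqrt(sum(Mod(amps)^2)))
    m <- sample(1:2, 1)
    tq <- sample(0:(n - 1), m)
    U <- sample_haar_unitary(m)
    out <- sv_apply(st, unitary_op(U, targets = tq))
    expect_lt(abs(sum(Mod(out$amplitudes)^2) - 1), 1e-10)
  }
})

test_that("measurement probabilities follow the Born rule and sum to one", {
  one <- statevector(c(0, 1))
  expect_equal(measure_probability(one, 0L, 1L), 1.0)

  bell <- statevector(c(1, 0, 0, 1) / sqrt(2))
  expect_equal(measure_probability(bell, 1L, 0L), 0.5)

  unif <- statevector(rep(0.5, 4))
  expect_equal(measure_probability(unif, 0L, 1L), 0.5)

  set.seed(7)
  amps <- complex(real = rnorm(8), imaginary = rnorm(8))
  st <- statevector(amps / sqrt(sum(Mod(amps)^2)))
  for (q in 0:2) {
    expect_lt(abs(measure_probability(st, q, 0L) +
                  measure_probability(st, q, 1L) - 1), 1e-10)
  }
  expect_error(measure_probability(st, 5L, 0L), "invalid qubit")
})

test_that("shot sampling is a reproducible binomial draw", {
  expect_equal(sample_shots(1.0, 8192L), 8192L)
  expect_equal(sample_shots(0.0, 8192L), 0L)
  expect_identical(sample_shots(0.37, 4096L, seed = 5L),
                   sample_shots(0.37, 4096L, seed = 5L))
  expect_lt(abs(sample_shots(0.5, 8192L, seed = 9L) - 4096),
            3 * sqrt(8192 * 0.25))
  expect_error(sample_shots(0.5, 0L), "positive")
  expect_error(sample_shots(1.5, 10L), "\\[0, 1\\]")
})

test_that("Haar sampling is unitary, seeded, invariant in first moment", {
  U <- sample_haar_unitary(1, seed = 3L)
  expect_lt(max(Mod(crossprod(Conj(U), U) - diag(2))), 1e-10)
  expect_identical(sample_haar_unitary(2, seed = 8L),
                   sample_haar_unitary(2, seed = 8L))

  # E|U_ij|^2 = 1/dim, and the first moment is invariant under a fixed
  # left rotation (Haar invariance)
  set.seed(21)
  draws <- replicate(1000, sample_haar_unitary(2), simplify = FALSE)
  m <- mean(vapply(draws, function(u) Mod(u[1, 1])^2, numeric(1)))
  se <- sqrt(stats::var(vapply(draws, function(u) Mod(u[1, 1])^2, numeric(1))) / 1000)
  expect_lt(abs(m - 0.25), 3 * se)
  V <- sample_haar_unitary(2, seed = 99L)
  mv <- mean(vapply(draws, function(u) Mod((V %*% u)[1, 1])^2, numeric(1)))
  expect_lt(abs(mv - 0.25), 4 * se)

  expect_error(sample_haar_unitary(13), "resource")
})
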