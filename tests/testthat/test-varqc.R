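test_that("the learner carries 6n parameters and the matching ansatz", {
  for (n in 1:3) {
    expect_equal(n_params(variational_learner(n)), 6L * n)
  }
  expect_error(variational_learner(2, theta = numeric(5)), "6 \\* n_qubits")

  # 2 features -> 1 qubit, 6 parameters, no CNOTs
  circ1 <- build_ansatz(c(0.4, 0.8), rep(0.1, 6))
  expect_equal(circ1$n_qubits, 1L)
  expect_length(circ1$ops, 6L)

  # 8 features -> 3 qubits, 18 parameters, 2 CNOTs in the chain
  circ3 <- build_ansatz(runif(8), rep(0.1, 18))
  expect_equal(circ3$n_qubits, 3L)
  expect_length(circ3$ops, 18L + 2L)
  expect_error(build_ansatz(runif(8), rep(0.1, 6)), "6n")
})

test_that("zero rotations reduce the ansatz to encoding plus the CNOT chain", {
  # one qubit: no CNOTs, so the output state is exactly the encoded input
  x1 <- c(0.6, 0.8)
  st1 <- run_circuit(build_ansatz(x1, rep(0, 6)))
  expect_equal(st1$amplitudes, amplitude_encode(x1)$amplitudes)

  # two qubits: only CNOT(0 -> 1) remains, which permutes amplitudes 1 <-> 3
  x <- c(0.3, 0.5, 0.2, 0.7)
  st <- run_circuit(build_ansatz(x, rep(0, 12)))
  enc <- amplitude_encode(x)$amplitudes
  expect_equal(st$amplitudes, enc[c(1, 4, 3, 2)])
  # the chain maps odd amplitudes to odd ones, so the readout is unchanged
  p <- readout_probability(build_ansatz(x, rep(0, 12)))
  expect_lt(abs(sum(p) - 1), 1e-10)
  expect_equal(p[2], Re(sum(enc[c(2, 4)]^2)), tolerance = 1e-10)
})

test_that("readout probabilities for basis and superposition inputs", {
  expect_equal(readout_probability(build_ansatz(c(1, 0), rep(0, 6))), c(1, 0))
  expect_equal(readout_probability(build_ansatz(c(1, 1), rep(0, 6))),
               c(0.5, 0.5))
})

test_that("binary cross entropy matches direct substitution", {
  expect_lt(bce_loss(c(1, 0), c(1, 0)), 1e-10)
  expect_equal(bce_loss(c(0.5, 0.5, 0.5), c(1, 0, 1)), log(2))
  expect_equal(bce_loss(c(0.9, 0.2), c(1, 0)), -(log(0.9) + log(0.8)) / 2)
  expect_error(bce_loss(c(0.5), c(1, 0)), "length mismatch")
})

test_that("parameter-shift gradients match central finite differences", {
  set.seed(77)
  for (trial in 1:5) {
    n <- sample(1:2, 1)
    learner <- variational_learner(n, seed = 200L + trial)
    X <- matrix(runif(3 * 2^n), nrow = 3)
    y <- sample(c(0L, 1L), 3, replace = TRUE)
    g <- parameter_shift_gradient(learner, X, y)
    expect_length(g, 6L * n)
    h <- 1e-4
    fd <- vapply(seq_along(learner$theta), function(j) {
      lp <- learner; lp$theta[j] <- lp$theta[j] + h
      lm <- learner; lm$theta[j] <- lm$theta[j] - h
      (bce_loss(predict_varqc(lp, X), y) - bce_loss(predict_varqc(lm, X), y)) / (2 * h)
    }, numeric(1))
    expect_lt(max(abs(g - fd)), 1e-5)
  }
})

test_that("training reduces the loss and learns separable blobs", {
  blobs <- separable_blobs()
  learner <- variational_learner(1, seed = 5L)
  fit <- train_learner(learner, blobs$X, blobs$y, learning_rate = 0.1,
                       batch_size = 8L, epochs = 15L, seed = 2L)
  init_loss <- bce_loss(predict_varqc(learner, blobs$X), blobs$y)
  expect_lt(fit$loss_trace[length(fit$loss_trace)], init_loss)
  acc <- mean(classify(predict_varqc(fit, blobs$X)) == blobs$y)
  expect_gt(acc, 0.7)
})

test_that("training is bit-reproducible under a fixed seed", {
  blobs <- separable_blobs()
  run <- function() {
    train_learner(variational_learner(1, seed = 3L),
                  blobs$X[1:40, ], blobs$y[1:40],
                  learning_rate = 0.1, batch_size = 4L, epochs = 5L,
                  seed = 9L)
  }
  a <- run(); b <- run()
  expect_identical(a$theta, b$theta)
  expect_identical(a$loss_trace, b$loss_trace)
})

test_that("the hyperparameter grid enumerates 105 configurations", {
  grid <- default_variational_grid()
  expect_equal(nrow(grid), 3L * 5L * 7L)
  expect_setequal(unique(grid$learning_rate), c(1e-3, 1e-2, 1e-1))
  expect_setequal(unique(grid$batch_size), c(1L, 2L, 4L, 8L, 16L))
  expect_setequal(unique(grid$n_learners), 1:7)
})

test_that("grid search ranks configurations by median validation accuracy", {
  blobs <- separable_blobs()
  grid <- data.frame(learning_rate = c(0.1, 1e-4), batch_size = 8L,
                     n_learners = 1L)
  out <- grid_search(blobs$X, blobs$y, grid, folds = 4L, epochs = 8L, seed = 6L)
  expect_equal(nrow(out), 2L)
  expect_equal(out$rank, 1:2)
  expect_true(all(out$median_val_accuracy >= 0 & out$median_val_accuracy <= 1))
  # the realistic learning rate must beat the vanishing one
  expect_equal(out$learning_rate[1], 0.1)
  expect_error(grid_search(blobs$X, blobs$y, grid[0, ]), "empty grid")
})
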