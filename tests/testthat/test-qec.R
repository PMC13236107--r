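test_that("the width law reproduces the hardware configurations and grid extrema", {
  w <- function(n_train, n_feature, d) {
    qec_width(qec_config(d = d, n_train = n_train, n_feature = n_feature))
  }
  expect_equal(w(2, 2, 1), 7L)
  expect_equal(w(8, 32, 2), 56L)
  expect_equal(w(8, 16, 2), 47L)
  expect_equal(w(4, 8, 3), 23L)

  expect_equal(min(qec_parameter_grid("swap")$width), 7L)
  expect_equal(max(qec_parameter_grid("haar")$width), 23L)
  expect_equal(nrow(qec_parameter_grid("swap")), 3L * 3L * 3L * 3L)
})

test_that("slot-swap transformations are label-respecting permutations", {
  cfg <- qec_config(d = 1, n_train = 2, n_feature = 2, n_swap = 1, seed = 5L)
  op <- sample_swap_transformation(cfg, seed = 2L)
  expect_null(op$matrix)
  expect_setequal(op$perm, 0:15)  # train register: 2 data qubits + 2 label qubits

  # with n_train = 2 the only pair is (0, 1): the op must exchange the two
  # sample slots including their label qubits
  st <- statevector(kron_le(list(c(1, 0), c(0, 1), c(0, 1), c(1, 0))))
  out <- sv_apply(st, op)
  swapped <- statevector(kron_le(list(c(0, 1), c(1, 0), c(1, 0), c(0, 1))))
  expect_equal(out$amplitudes, swapped$amplitudes)

  # SWAP^2 = identity: applying the transposition twice restores the state
  set.seed(3)
  amps <- complex(real = rnorm(16), imaginary = rnorm(16))
  rnd <- statevector(amps / sqrt(sum(Mod(amps)^2)))
  expect_equal(sv_apply(sv_apply(rnd, op), op)$amplitudes, rnd$amplitudes)

  expect_error(sample_swap_transformation(
    qec_config(d = 1, n_train = 1, n_feature = 2)), "at least two")
})

test_that("trajectory enumeration returns 2^d branch probabilities", {
  set.seed(8)
  X <- matrix(runif(8), nrow = 4); y <- c(0L, 1L, 1L, 0L); xt <- runif(2)
  for (d in 1:3) {
    cfg <- qec_config(d = d, n_train = 4, n_feature = 2, n_swap = 2, seed = d)
    tr <- enumerate_trajectories(cfg, X, y, xt)
    expect_length(tr, 2^d)
    expect_true(all(tr >= 0 & tr <= 1))
  }
})

test_that("swap-variant branches equal the per-sample closed form", {
  # every trajectory moves one complete training sample into slot 0, so each
  # branch probability must equal the cosine closed form for some sample
  set.seed(14)
  cfg <- qec_config(d = 2, n_train = 4, n_feature = 4, n_swap = 3, seed = 77L)
  inst <- random_qec_instance(cfg)
  branch <- enumerate_trajectories(cfg, inst$X, inst$y, inst$x_test)
  per_sample <- vapply(seq_len(cfg$n_train), function(s) {
    D <- cosine_similarity(inst$X[s, ], inst$x_test)
    if (inst$y[s] == 1L) analytic_probability(D) else 1 - analytic_probability(D)
  }, numeric(1))
  for (p in branch) expect_lt(min(abs(p - per_sample)), 1e-10)
})

test_that("circuit predictions equal the mean of enumerated trajectories", {
  set.seed(19)
  grid <- simulable_qec_grid(max_width = 12L)
  pick <- grid[sample(nrow(grid), 12), ]
  for (i in seq_len(nrow(pick))) {
    cfg <- qec_config(d = pick$d[i], n_train = pick$n_train[i],
                      n_feature = pick$n_feature[i], n_swap = pick$n_swap[i],
                      variant = as.character(pick$variant[i]),
                      seed = 300L + i)
    inst <- random_qec_instance(cfg)
    p <- predict_qec(cfg, inst$X, inst$y, inst$x_test)
    tr <- enumerate_trajectories(cfg, inst$X, inst$y, inst$x_test)
    expect_lt(abs(p - mean(tr)), 1e-8)
    expect_true(p >= 0 && p <= 1)
  }
})

test_that("duplicated training samples degenerate to the single-classifier value", {
  x <- c(0.7, 0.2); xt <- c(0.5, 0.9)
  X <- rbind(x, x); y <- c(1L, 1L)
  for (variant in c("swap", "haar")) {
    cfg <- qec_config(d = 2, n_train = 2, n_feature = 2, variant = variant,
                      seed = 4L)
    p_ens <- predict_qec(cfg, X, y, xt)
    p_single <- predict_qcc(qcc_instance(x, 1L, xt))
    if (variant == "swap") {
      expect_lt(abs(p_ens - p_single), 1e-10)
      expect_lt(diff(range(enumerate_trajectories(cfg, X, y, xt))), 1e-10)
    } else {
      # Haar rotations scramble even identical samples; only the contract
      # bounds hold
      expect_true(p_ens >= 0 && p_ens <= 1)
    }
  }
})

test_that("Haar-variant predictions are reproducible under a fixed config seed", {
  cfg <- qec_config(d = 1, n_train = 2, n_feature = 2, variant = "haar",
                    seed = 123L)
  set.seed(55)
  inst <- random_qec_instance(cfg)
  expect_identical(predict_qecru(cfg, inst$X, inst$y, inst$x_test),
                   predict_qecru(cfg, inst$X, inst$y, inst$x_test))
  expect_error(qec_config(d = 1, n_train = 8, n_feature = 8192,
                          variant = "haar"), "resource")
})
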