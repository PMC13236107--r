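test_that("soft voting averages member probabilities", {
  l1 <- variational_learner(1, seed = 1L)
  l2 <- variational_learner(1, seed = 2L)
  X <- matrix(runif(10), ncol = 2)

  # K copies of one learner equal the learner exactly
  copies <- vq_ensemble(list(l1, l1, l1), kind = "soft_vote")
  expect_equal(soft_vote_predict(copies, X), predict_varqc(l1, X))

  # two distinct learners: the plain mean
  pair <- vq_ensemble(list(l1, l2), kind = "soft_vote")
  expect_equal(soft_vote_predict(pair, X),
               (predict_varqc(l1, X) + predict_varqc(l2, X)) / 2)
  expect_error(vq_ensemble(list(), kind = "soft_vote"), "at least one")
})

test_that("joint instantiation width is learners times qubits", {
  mk <- function(n, k) {
    vq_ensemble(lapply(seq_len(k), function(i) variational_learner(n, seed = i)),
                kind = "soft_vote")
  }
  expect_equal(instantiate_joint(mk(3, 4)), 12L)
  expect_equal(instantiate_joint(mk(2, 1)), 2L)
  expect_equal(instantiate_joint(mk(1, 4)), 4L)
  mixed <- vq_ensemble(list(variational_learner(1), variational_learner(2)),
                       kind = "soft_vote")
  expect_error(instantiate_joint(mixed), "equal width")
})

test_that("bagging partitions are disjoint, covering, and near-equal", {
  expect_equal(lengths(partition_indices(80, 4, seed = 1)), rep(20L, 4),
               ignore_attr = TRUE)
  expect_equal(unname(lengths(partition_indices(10, 3, seed = 1))), c(4L, 3L, 3L))
  expect_equal(lengths(partition_indices(12, 1, seed = 1)), 12L,
               ignore_attr = TRUE)
  for (case in list(c(17, 5), c(30, 7), c(9, 9))) {
    parts <- partition_indices(case[1], case[2], seed = 3)
    all_idx <- unlist(parts)
    expect_equal(sort(all_idx), seq_len(case[1]))  # disjoint union covers
    expect_lte(diff(range(lengths(parts))), 1)
  }
  expect_error(partition_indices(3, 5), "cannot partition")
})

test_that("bagged learners each see only their subset and predict jointly", {
  blobs <- separable_blobs()
  ens <- bagging_fit(blobs$X, blobs$y, k = 4, epochs = 8L, seed = 2L)
  expect_length(ens$learners, 4L)
  expect_equal(sort(unlist(ens$partition)), 1:100)
  p <- predict(ens, blobs$X)
  expect_true(all(p >= 0 & p <= 1))
  expect_gt(mean(classify(p) == blobs$y), 0.6)
})

test_that("boosting keeps a valid weight vector and upweights mistakes", {
  blobs <- separable_blobs()
  N <- 60L
  X <- blobs$X[1:N, ]; y <- blobs$y[1:N]
  ens <- suppressWarnings(boosting_fit(X, y, k = 3, epochs = 8L, seed = 4L))
  expect_equal(ens$weight_history[[1]], rep(1 / N, N))
  for (w in ens$weight_history) {
    expect_lt(abs(sum(w) - 1), 1e-10)
    expect_true(all(w > 0))
  }
  # after round 1 misclassified samples gained weight, correct ones lost it
  if (length(ens$weight_history) > 1) {
    miss <- classify(predict_varqc(ens$learners[[1]], X)) != y
    if (any(miss) && any(!miss)) {
      expect_true(all(ens$weight_history[[2]][miss] > 1 / N))
      expect_true(all(ens$weight_history[[2]][!miss] < 1 / N))
    }
  }
})

test_that("a trained soft-vote ensemble beats an untrained learner on blobs", {
  wins <- 0L
  for (s in 1:3) {
    blobs <- separable_blobs(seed = 100L + s)
    tr <- 1:80; te <- 81:100
    ens <- soft_vote_fit(blobs$X[tr, ], blobs$y[tr], n_learners = 3,
                         learning_rate = 0.1, batch_size = 8L, epochs = 10L,
                         seed = s)
    acc_ens <- mean(classify(soft_vote_predict(ens, blobs$X[te, ])) == blobs$y[te])
    rand <- variational_learner(1, seed = 900L + s)
    acc_rand <- mean(classify(predict_varqc(rand, blobs$X[te, ])) == blobs$y[te])
    if (acc_ens >= acc_rand) wins <- wins + 1L
  }
  expect_gte(wins, 2L)
})
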