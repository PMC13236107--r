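test_that("Brier score matches direct substitution", {
  expect_equal(brier_score(c(1, 0, 1), c(1, 0, 1)), 0)
  expect_equal(brier_score(rep(0.5, 4), c(1, 0, 1, 0)), 0.25)
  expect_equal(brier_score(c(0.9, 0.2), c(1, 0)), 0.025)
  expect_error(brier_score(c(0.5), c(1, 0)), "length mismatch")
  expect_error(brier_score(c(1.5), c(1)), "\\[0, 1\\]")
})

test_that("weighted F1 matches contingency arithmetic", {
  expect_equal(weighted_f1(c(1, 0, 1, 0), c(1, 0, 1, 0)), 1.0)
  # all predicted one class on balanced truth: 0.5 * 2/3 + 0.5 * 0
  expect_equal(weighted_f1(c(1, 1, 0, 0), c(1, 1, 1, 1)), 1 / 3)
  expect_equal(weighted_f1(c(1, 1, 0, 0), c(1, 0, 0, 0)), 11 / 15)
  expect_error(weighted_f1(integer(0), integer(0)), "empty")
})

test_that("weighted F1 agrees with an independent per-class computation", {
  f1_oracle <- function(y_true, y_pred) {
    out <- 0
    for (cls in sort(unique(y_true))) {
      tp <- sum(y_pred == cls & y_true == cls)
      prec <- if (sum(y_pred == cls) == 0) 0 else tp / sum(y_pred == cls)
      rec <- if (sum(y_true == cls) == 0) 0 else tp / sum(y_true == cls)
      f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
      out <- out + sum(y_true == cls) / length(y_true) * f1
    }
    out
  }
  set.seed(9)
  for (i in 1:50) {
    n <- sample(5:40, 1)
    yt <- sample(c(0L, 1L), n, replace = TRUE)
    yp <- sample(c(0L, 1L), n, replace = TRUE)
    if (length(unique(yt)) < 2) yt[1] <- 1L - yt[1]
    expect_equal(weighted_f1(yt, yp), f1_oracle(yt, yp))
  }
})

test_that("split aggregation reports means, standard errors, and max-mean", {
  one <- metric_record("a", 1, c(1L, 0L), c(0.9, 0.2))
  agg1 <- aggregate_splits(one)
  expect_equal(agg1$mean_accuracy, 1)
  expect_equal(agg1$se_accuracy, 0)

  recs <- rbind(
    data.frame(classifier = "a", split = 1:3, accuracy = c(0.5, 0.6, 0.7),
               weighted_f1 = 0.5, brier = 0.2, single_class = FALSE),
    data.frame(classifier = "b", split = 1:3, accuracy = c(0.7, 0.7, 0.7),
               weighted_f1 = 0.6, brier = 0.1, single_class = FALSE))
  agg <- aggregate_splits(recs)
  a <- agg[agg$classifier == "a", ]
  expect_equal(a$mean_accuracy, 0.6)
  expect_equal(a$se_accuracy, sd(c(0.5, 0.6, 0.7)) / sqrt(3))
  best <- aggregate_splits(recs, metric = "accuracy", max_mean = TRUE)
  expect_equal(best$classifier, "b")
  expect_equal(best$mean_accuracy, 0.7)
})

test_that("the paired one-sided t-test matches the closed form", {
  mk <- function(v) data.frame(classifier = "x", split = seq_along(v),
                               accuracy = v, weighted_f1 = v, brier = 1 - v,
                               single_class = FALSE)
  expect_equal(compare_classifiers(mk(c(0.5, 0.6)), mk(c(0.5, 0.6))), 0.5)
  expect_equal(compare_classifiers(mk(c(0.6, 0.7)), mk(c(0.5, 0.6))), 0)
  expect_equal(compare_classifiers(mk(c(0.5, 0.6)), mk(c(0.6, 0.7))), 1)

  a <- c(0.72, 0.64, 0.81, 0.58, 0.69)
  b <- c(0.61, 0.66, 0.70, 0.52, 0.60)
  d <- a - b
  t_stat <- mean(d) / (sd(d) / sqrt(5))
  p_closed <- 1 - pt(t_stat, df = 4)
  expect_equal(compare_classifiers(mk(a), mk(b), metric = "weighted_f1"),
               p_closed, tolerance = 1e-10)
  expect_error(compare_classifiers(mk(a), mk(b)[1:3, ]), "paired")
})

test_that("single-class pathology is flagged per split", {
  expect_true(detect_single_class(rep(1L, 10)))
  expect_false(detect_single_class(c(1L, 0L, 1L)))
  set.seed(6)
  flags <- vapply(1:10, function(s) {
    preds <- sample(c(0L, 1L), 12, replace = TRUE, prob = c(0.05, 0.95))
    detect_single_class(preds)
  }, logical(1))
  set.seed(6)
  direct <- vapply(1:10, function(s) {
    preds <- sample(c(0L, 1L), 12, replace = TRUE, prob = c(0.05, 0.95))
    length(unique(preds)) == 1L
  }, logical(1))
  expect_identical(flags, direct)
})
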