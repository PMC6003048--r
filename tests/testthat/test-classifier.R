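test_that("per-recording feature is the mean of per-channel entropies", {
  ## staircase channels with barcodes known by construction:
  ## signal (0, 5, 2, 5) has minima 0 and 2; bars [0, Inf) -> [0, 6), [2, 5)
  y1 <- c(0, 5, 2, 5)
  o1 <- oracle_entropy(c(0, 2), c(Inf, 5), max_filter = 5)
  ## signal (1, 4, 0, 4, 2, 4): minima 1, 0, 2 -> [0, 5), [1, 4), [2, 4)
  y2 <- c(1, 4, 0, 4, 2, 4)
  o2 <- oracle_entropy(c(0, 1, 2), c(Inf, 4, 4), max_filter = 4)
  rec1 <- make_recording(matrix(y1, ncol = 1))
  rec2 <- make_recording(matrix(y2, ncol = 1))
  expect_equal(extract_feature(rec1)$mean, o1$H_norm, tolerance = 1e-12)
  expect_equal(extract_feature(rec2)$mean, o2$H_norm, tolerance = 1e-12)

  ## mean over channels; extending y1 by a repeat of its first two samples
  ## keeps both channels the same length
  both <- make_recording(cbind(c(y1, y1[1:2]), y2))
  fv <- extract_feature(both)
  expect_equal(fv$mean, mean(fv$per_channel))
  expect_length(fv$per_channel, 2L)

  ## constant channel: its only positive bar has length 1, so the
  ## normalization is undefined -> channel-indexed error
  bad <- make_recording(cbind(y2, rep(1, 6)))
  expect_error(extract_feature(bad), "channel 2",
               class = "toposeize_normalization_error")
})

test_that("threshold fit is Youden-optimal, direction-aware and degenerate-safe", {
  f <- c(0.1, 0.2, 0.8, 0.9)
  lab <- c("healthy", "healthy", "epileptic", "epileptic")
  m <- fit_ltc(f, lab)
  expect_gt(m$threshold, 0.2)
  expect_lt(m$threshold, 0.8)
  expect_equal(m$threshold, 0.5)  # midpoint convention
  expect_identical(m$direction, "greater")
  expect_identical(predict(m, c(0.15, 0.85)), c("not_epileptic", "epileptic"))

  ## flipping which side the positives lie on flips the direction
  m2 <- fit_ltc(-f, lab)
  expect_identical(m2$direction, "lesser")
  expect_equal(evaluate_ltc(-f, lab, m2)$auc, evaluate_ltc(f, lab, m)$auc)

  expect_warning(dm <- fit_ltc(rep(0.5, 4), lab),
                 class = "toposeize_degenerate_model")
  expect_true(dm$degenerate)
  expect_error(fit_ltc(1:4, rep("epileptic", 4)), class = "toposeize_training_error")
})

test_that("AUC equals brute-force concordant-pair counting", {
  expect_equal(auc_score(c(1, 2, 3, 4), c(0, 0, 1, 1), positive = "1"), 1)
  expect_equal(auc_score(c(1, 3, 2, 4), c(0, 0, 1, 1), positive = "1"), 0.75)
  set.seed(6)
  for (rep_i in 1:60) {
    n <- sample(4:20, 1)
    scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # force ties
    is_pos <- c(TRUE, FALSE, runif(n - 2) < 0.5)
    expect_equal(auc_score(scores, ifelse(is_pos, "epileptic", "healthy")),
                 oracle_auc(scores, is_pos), tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly increasing transforms", {
  set.seed(16)
  scores <- rnorm(30)
  labs <- ifelse(runif(30) < 0.5, "epileptic", "healthy")
  labs[1:2] <- c("epileptic", "healthy")
  base <- auc_score(scores, labs)
  expect_equal(auc_score(exp(scores), labs), base, tolerance = 1e-12)
  expect_equal(auc_score(scores^3 + 2 * scores, labs), base, tolerance = 1e-12)
})

test_that("evaluation report is internally consistent", {
  set.seed(26)
  f <- c(rnorm(20, 1), rnorm(20, 0))
  lab <- rep(c("epileptic", "healthy"), each = 20)
  m <- fit_ltc(f, lab)
  rep <- evaluate_ltc(f, lab, m)
  expect_identical(sum(rep$confusion), 40L)
  ## ROC is monotone nondecreasing and AUC equals its own trapezoidal area
  expect_true(all(diff(rep$roc$fpr) >= 0))
  expect_true(all(diff(rep$roc$tpr) >= -1e-12))
  trap <- sum(diff(rep$roc$fpr) * (head(rep$roc$tpr, -1) + tail(rep$roc$tpr, -1)) / 2)
  expect_equal(trap, rep$auc, tolerance = 1e-10)
  expect_error(evaluate_ltc(f, rep("epileptic", 40), m),
               class = "toposeize_evaluation_error")
})

test_that("cross-validation splits are stratified, seeded and honest", {
  set.seed(36)
  f <- c(rnorm(20, 2), rnorm(20, 0))
  lab <- rep(c("epileptic", "healthy"), each = 20)
  rep1 <- cross_validate(f, lab, k = 5, seed = 42)
  rep2 <- cross_validate(f, lab, k = 5, seed = 42)
  expect_identical(rep1$split, rep2$split)
  expect_identical(rep1$fold_assignments, rep2$fold_assignments)
  expect_identical(rep1$auc, rep2$auc)
  rep3 <- cross_validate(f, lab, k = 5, seed = 43)
  expect_false(identical(rep1$split, rep3$split))

  ## folds partition the training portion with sizes differing by <= 1
  sizes <- table(rep1$fold_assignments)
  expect_identical(sum(sizes), length(rep1$split$train))
  expect_lte(diff(range(sizes)), 1)
  ## train and test partition the data; stratification: 70% of each class
  expect_identical(sort(c(rep1$split$train, rep1$split$test)), 1:40)
  expect_identical(sum(rep1$split$train <= 20), 14L)
  expect_error(cross_validate(f, lab, k = 15, seed = 1),
               class = "toposeize_config_error")
})

test_that("rank test: identical groups, separated groups, constant shifts", {
  set.seed(46)
  a <- rnorm(25)
  same <- rank_test(a, a)
  expect_gt(same$p_value, 0.9)
  expect_lt(abs(same$shift), 0.2)

  sep <- rank_test(rnorm(30, 100), rnorm(30, 0))
  expect_lt(sep$p_value, 1e-10)

  b <- rnorm(40)
  shifted <- rank_test(b + 3, b)
  expect_equal(shifted$shift, 3, tolerance = 0.5)
  expect_true(shifted$conf_int[1] < 3 && 3 < shifted$conf_int[2])
  expect_error(rank_test(numeric(0), 1:3), class = "toposeize_data_error")
})
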