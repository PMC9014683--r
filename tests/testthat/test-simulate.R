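test_that("the base generator is balanced, seeded and carries the planted signal", {
  d <- generate_base_dataset(n = 40, p = 60, n_informative = 10,
                             effect_size = 1.0, seed = 3)
  expect_equal(sum(d$labels$y), 20L)
  expect_length(d$informative, 10L)
  d2 <- generate_base_dataset(n = 40, p = 60, n_informative = 10,
                              effect_size = 1.0, seed = 3)
  expect_identical(d$X$values, d2$X$values)
  # huge effect on one feature separates the classes linearly
  tiny <- generate_base_dataset(n = 4, p = 2, n_informative = 1,
                                effect_size = 100, seed = 1)
  f1 <- tiny$X$values[, 1]
  expect_gt(min(f1[tiny$labels$y == 1]), max(f1[tiny$labels$y == 0]))
})

test_that("a null effect gives null-calibrated per-feature t-statistics", {
  hits <- 0L
  total <- 0L
  for (s in 1:5) {
    d <- generate_base_dataset(n = 40, p = 400, n_informative = 400,
                               effect_size = 0, seed = s)
    tt <- apply(d$X$values, 2, function(v)
      t.test(v[d$labels$y == 1], v[d$labels$y == 0])$statistic)
    hits <- hits + sum(abs(tt) > 2)
    total <- total + length(tt)
  }
  # P(|t_38| > 2) ~ 0.0525; allow 3 binomial SEs
  expect_lt(abs(hits / total - 0.0525), 3 * sqrt(0.05 * 0.95 / total))
})

test_that("label switching flips exactly floor(fraction*n) seeded samples", {
  d <- generate_base_dataset(n = 200, p = 10, n_informative = 2, seed = 1)
  for (fr in c(0.05, 0.15)) {
    sw <- apply_label_switch(d$labels, fr, seed = 4)
    expect_equal(sum(sw.outlier <- sw$outlier_truth), floor(fr * 200))
    expect_equal(sum(sw$labels$y != d$labels$y), floor(fr * 200))
    expect_true(all(sw$labels$y[sw$outlier_truth] !=
                      d$labels$y[sw$outlier_truth]))
  }
  # involution: switching the same seeded set twice restores the labels
  sw1 <- apply_label_switch(d$labels, 0.1, seed = 8)
  sw2 <- apply_label_switch(sw1$labels, 0.1, seed = 8)
  expect_equal(sw2$labels$y, d$labels$y)
})

test_that("expression shifts touch only the chosen cells at 3 SD", {
  d <- generate_base_dataset(n = 40, p = 200, n_informative = 10, seed = 2)
  sh <- apply_expression_shift(d$X, feature_fraction = 0.15,
                               sample_fraction = 0.05, multiplier = 3,
                               seed = 6)
  expect_length(sh$shifted_features, floor(0.15 * 200))
  expect_equal(sum(sh$outlier_truth), floor(0.05 * 40))
  changed <- which(sh$X$values != d$X$values, arr.ind = TRUE)
  expect_setequal(unique(changed[, 1]), which(sh$outlier_truth))
  expect_setequal(d$X$feature_ids[unique(changed[, 2])], sh$shifted_features)
  # shift magnitude equals 3 * per-feature SD of the uncorrupted matrix
  j <- unique(changed[, 2])[1]
  i <- which(sh$outlier_truth)[1]
  expect_equal(sh$X$values[i, j] - d$X$values[i, j],
               3 * sd(d$X$values[, j]))
  # zero multiplier: matrix untouched, truth still set
  sh0 <- apply_expression_shift(d$X, multiplier = 0, seed = 6)
  expect_identical(sh0$X$values, d$X$values)
  expect_equal(sum(sh0$outlier_truth), floor(0.05 * 40))
})

test_that("scenario wrapper enforces the scenario contracts", {
  s5 <- simulate_scenario("label_switch_5", n = 40, p = 30,
                          n_informative = 6, seed = 1)
  expect_identical(s5$X$values, simulate_scenario("label_switch_5", n = 40,
                                                  p = 30, n_informative = 6,
                                                  seed = 1)$X$values)
  expect_equal(sum(s5$outlier_truth), 2L)  # floor(0.05 * 40)
  expect_equal(sum(s5$y_observed$y != s5$y_true$y), 2L)
  sh <- simulate_scenario("expression_shift", n = 40, p = 30,
                          n_informative = 6, seed = 1)
  expect_equal(sh$y_observed$y, sh$y_true$y)
  expect_false(identical(sh$X$values,
                         simulate_scenario("label_switch_5", n = 40, p = 30,
                                           n_informative = 6,
                                           seed = 1)$X$values))
})

test_that("ROC evaluation matches pair-counting and pROC on random instances", {
  expect_equal(evaluate_roc(c(4, 3, 2, 1), c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  expect_equal(evaluate_roc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0))$auc, 0.75)
  set.seed(17)
  for (rep in 1:25) {
    n <- sample(5:50, 1)
    scores <- sample(round(rnorm(n), 1), n, replace = TRUE)  # force ties
    truth <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(truth) || all(truth)) next
    rc <- evaluate_roc(scores, truth)
    expect_equal(rc$auc, auc_pair_oracle(scores, truth))
    # curve invariants
    expect_true(all(diff(rc$fpr) >= 0) && all(diff(rc$tpr) >= 0))
    expect_equal(c(rc$fpr[1], rc$tpr[1]), c(0, 0))
    expect_equal(c(rc$fpr[length(rc$fpr)], rc$tpr[length(rc$tpr)]), c(1, 1))
    if (requireNamespace("pROC", quietly = TRUE)) {
      pr <- pROC::roc(response = truth, predictor = scores,
                      direction = "<", quiet = TRUE)
      expect_equal(rc$auc, as.numeric(pROC::auc(pr)))
    }
  }
  expect_error(evaluate_roc(1:4, rep(TRUE, 4)), "degenerate")
})

test_that("random scores give AUC 0.5 on average", {
  set.seed(23)
  aucs <- replicate(400, {
    evaluate_roc(rnorm(30), rep(c(TRUE, FALSE), 15))$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.02)
})

test_that("the study table covers every scenario/method pair and is seeded", {
  tab <- run_simulation_study(seeds = 1, scenarios = c("label_switch_5"),
                              n = 40, p = 60, n_informative = 12,
                              effect_size = 1.6, control = fast_control())
  expect_setequal(tab$method, c("sprm", "rskc", "enetlts", "consensus"))
  expect_true(all(tab$auc >= 0 & tab$auc <= 1))
  tab2 <- run_simulation_study(seeds = 1, scenarios = c("label_switch_5"),
                               n = 40, p = 60, n_informative = 12,
                               effect_size = 1.6, control = fast_control())
  expect_equal(tab, tab2)
})
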