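test_that("perfect and null scores bracket the AUC", {
  labels <- rep(c(1L, 0L), each = 50)
  expect_equal(auc_score(labels, labels), 1)
  rep <- evaluate_scores(labels, labels)
  expect_equal(rep$auc, 1)
  expect_equal(rep$accuracy, 1)

  set.seed(1)
  labels2 <- rep(c(1L, 0L), each = 1500)
  rnd <- runif(3000)
  expect_equal(auc_score(rnd, labels2), 0.5, tolerance = 0.03)
})

test_that("confusion metrics match the worked example", {
  # TP=9 FN=1 TN=8 FP=2 at the 0.5 threshold
  scores <- c(rep(0.9, 9), 0.1, rep(0.2, 8), rep(0.8, 2))
  labels <- c(rep(1L, 10), rep(0L, 10))
  rep <- evaluate_scores(scores, labels)
  expect_identical(unname(rep$confusion), c(9L, 2L, 8L, 1L))
  expect_equal(rep$sensitivity, 0.9)
  expect_equal(rep$specificity, 0.8)
  expect_equal(rep$ppv, 9 / 11)
  expect_equal(rep$accuracy, 0.85)
})

test_that("rank AUC equals the ROC trapezoid and matches pROC", {
  skip_if_not_installed("pROC")
  set.seed(2)
  for (i in 1:20) {
    n <- sample(20:100, 1)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    scores <- round(rnorm(n), i %% 3)  # coarse rounding forces ties
    a_rank <- auc_score(scores, labels)
    roc <- roc_points(scores, labels)
    a_trap <- sum(diff(roc$FPR) * (head(roc$TPR, -1) + tail(roc$TPR, -1)) / 2)
    expect_equal(a_rank, a_trap, tolerance = 1e-12)
    a_oracle <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                               direction = "<")))
    expect_equal(a_rank, a_oracle, tolerance = 1e-12)
  }
})

test_that("AUC is invariant under monotone transforms and flips on reversal", {
  set.seed(3)
  labels <- rbinom(80, 1, 0.5)
  scores <- rnorm(80)
  a <- auc_score(scores, labels)
  expect_equal(auc_score(exp(scores), labels), a)
  expect_equal(auc_score(plogis(3 * scores - 1), labels), a)
  expect_equal(auc_score(-scores, labels), 1 - a)
})

test_that("curve endpoints and degenerate guards behave", {
  scores <- c(0.9, 0.8, 0.4, 0.2)
  labels <- c(1L, 0L, 1L, 0L)
  roc <- roc_points(scores, labels)
  expect_equal(unlist(roc[1, ]), c(FPR = 0, TPR = 0))
  expect_equal(unlist(roc[nrow(roc), ]), c(FPR = 1, TPR = 1))
  pr <- pr_points(scores, labels)
  expect_equal(pr$recall[1], 0)
  expect_equal(pr$precision[1], pr$precision[2])

  # all calls negative: PPV undefined, reported as NA
  rep <- evaluate_scores(c(0.1, 0.2, 0.3, 0.4), labels)
  expect_true(is.na(rep$ppv))
  expect_false(is.na(rep$npv))

  expect_error(evaluate_scores(scores, rep(1L, 4)), "both classes")
})

test_that("group_stats matches brute-force moments and Welch p-values", {
  feats <- make_gaussian_features(40, c("A_f1", "B_f1"), informative = "A_f1",
                                  delta = 1.5, seed = 4)
  gs <- group_stats(feats)
  expect_identical(gs$feature, c("A_f1", "B_f1"))
  for (i in seq_len(nrow(gs))) {
    cl <- gs$feature[i]
    expect_equal(gs$septic_mean[i], mean(feats[[cl]][feats$label == 1]))
    expect_equal(gs$control_sd[i], sd(feats[[cl]][feats$label == 0]))
    expect_equal(gs$p_value[i],
                 t.test(feats[[cl]][feats$label == 1],
                        feats[[cl]][feats$label == 0])$p.value)
  }

  # identical groups: p ~ 1; extreme separation: p ~ 0
  same <- feats
  same[same$label == 1, c("A_f1", "B_f1")] <-
    same[same$label == 0, c("A_f1", "B_f1")]
  gs_same <- group_stats(same)
  expect_gt(min(gs_same$p_value), 0.99)

  far <- feats
  far$A_f1 <- far$A_f1 + 10 * far$label
  expect_lt(group_stats(far)$p_value[1], 1e-6)

  expect_error(group_stats(feats[feats$label == 1, ][1, , drop = FALSE]),
               "at least 2")
})

test_that("sweeps return one AUC per swept value", {
  feats4 <- c("MAP_f1", "RR_f1", "RR_f4", "HR_f3")
  one <- sweep_collection_interval(T_values = 4, n_septic = 25, n_control = 25,
                                   family = "LR", feature_names = feats4,
                                   seed = 5)
  expect_identical(nrow(one), 1L)
  expect_true(one$auc >= 0 && one$auc <= 1)

  five <- sweep_prediction_horizon(horizons = 1:5, n_septic = 25,
                                   n_control = 25, family = "LR",
                                   feature_names = feats4, seed = 6)
  expect_identical(nrow(five), 5L)
  expect_identical(five$value, 1:5)
})

test_that("a zero-signal generator yields chance-level AUC", {
  cp <- default_generator_params("control")
  sw <- suppressWarnings(
    sweep_collection_interval(T_values = 8, n_septic = 60, n_control = 60,
                              septic_params = cp, control_params = cp,
                              family = "LR",
                              feature_names = c("MAP_f1", "RR_f1"),
                              seed = 7)
  )
  expect_gt(sw$auc, 0.3)
  expect_lt(sw$auc, 0.7)
})

test_that("compare_feature_sets pairs every family with both feature sets", {
  co <- small_cohort(n = 30, seed = 8)
  cmp <- suppressWarnings(
    compare_feature_sets(co, families = c("LR", "SVM_RBF"), seed = 8)
  )
  expect_identical(nrow(cmp), 4L)
  expect_setequal(unique(cmp$feature_set), c("variability", "baseline"))
  expect_true(all(cmp$auc >= 0 & cmp$auc <= 1))
})
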