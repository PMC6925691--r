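feature_names_20 <- as.vector(outer(VITAL_SIGNS, VARIABILITY_FEATURES,
                                    paste, sep = "_"))

test_that("permutation importance singles out the informative feature", {
  feats <- make_gaussian_features(120, feature_names_20,
                                  informative = "RR_f1", delta = 3, seed = 8)
  cfg <- model_config("LR", seed = 8)
  fit <- suppressWarnings(fit_model(cfg, feats))
  imp <- permutation_importance(fit, feats, n_repeats = 10, seed = 9)
  expect_s3_class(imp, "importance_table")
  expect_equal(max(imp$importance), 100)
  expect_identical(imp$feature[which.max(imp$importance)], "RR_f1")
  # noise features score far below the signal carrier
  expect_lt(sort(imp$importance, decreasing = TRUE)[2], 50)
})

test_that("label-permuted data yields importances near zero", {
  feats <- make_gaussian_features(100, feature_names_20,
                                  informative = "RR_f1", delta = 3, seed = 10)
  set.seed(11)
  feats$label <- sample(feats$label)
  cfg <- model_config("LR", seed = 11)
  fit <- suppressWarnings(fit_model(cfg, feats))
  imp <- permutation_importance(fit, feats, n_repeats = 10, seed = 12)
  expect_lt(max(abs(imp$raw_drop)), 0.15)
})

test_that("duplicated feature columns share importance roughly equally", {
  feats <- make_gaussian_features(150, feature_names_20[1:6],
                                  informative = "MAP_f1", delta = 3, seed = 13)
  feats$MAP_f2 <- feats$MAP_f1  # exact duplicate of the signal column
  cfg <- model_config("SVM_linear", seed = 13)
  fit <- fit_model(cfg, feats)
  imp <- permutation_importance(fit, feats, n_repeats = 15, seed = 14)
  s1 <- imp$importance[imp$feature == "MAP_f1"]
  s2 <- imp$importance[imp$feature == "MAP_f2"]
  expect_gt(s1, 0); expect_gt(s2, 0)
  expect_lt(abs(s1 - s2), 40)
})

test_that("top_k ranks deterministically with lexicographic tie-break", {
  tab <- data.frame(feature = c("C", "A", "B"),
                    importance = c(10, 100, 50))
  expect_identical(top_k(tab, 2), c("A", "B"))
  tied <- data.frame(feature = c("zeta", "beta", "alpha"),
                     importance = c(50, 50, 50))
  expect_identical(top_k(tied, 2), c("alpha", "beta"))
  expect_identical(top_k(tab, 3), c("A", "B", "C"))
  expect_error(top_k(tab, 4), "exceeds")
})

test_that("merge_selections deduplicates with stable order", {
  all_same <- replicate(5, c("RR_f1", "MAP_f1"), simplify = FALSE)
  m <- merge_selections(all_same)
  expect_identical(m$features, c("RR_f1", "MAP_f1"))

  disjoint <- split(feature_names_20[1:10], rep(1:5, each = 2))
  m2 <- merge_selections(disjoint)
  expect_length(m2$features, 10)

  # idempotent and insensitive to within-list duplicates
  m3 <- merge_selections(list(m$features, m$features))
  expect_identical(m3$features, m$features)
  expect_error(merge_selections(list()), "at least one")
})

test_that("selection recovers informative features and nothing else", {
  # with exactly two signal-carrying features, every model's top-2 is
  # exactly that pair and the merged set collapses to it
  pair <- c("RR_f1", "MAP_f1")
  feats2 <- make_gaussian_features(150, feature_names_20,
                                   informative = pair, delta = 3, seed = 14)
  sel2 <- suppressWarnings(
    select_features(feats2, k = 2, n_repeats = 10, seed = 14)
  )
  expect_true(setequal(sel2$features, pair))
  for (fam in MODEL_FAMILIES) {
    expect_true(setequal(sel2$provenance[[fam]], pair), info = fam)
  }

  # with four signal carriers the merged set never strays outside them;
  # how many of the four surface depends on how much the models disagree
  informative <- c("RR_f1", "MAP_f1", "RR_f4", "HR_f3")
  feats <- make_gaussian_features(150, feature_names_20,
                                  informative = informative,
                                  delta = 3, seed = 15)
  sel <- suppressWarnings(
    select_features(feats, k = 2, n_repeats = 10, seed = 15)
  )
  expect_true(all(sel$features %in% informative))
  expect_gte(length(sel$features), 2)
  expect_length(sel$provenance, length(MODEL_FAMILIES))
  for (fam in MODEL_FAMILIES) {
    expect_length(sel$provenance[[fam]], 2)
    expect_true(all(sel$provenance[[fam]] %in% informative), info = fam)
  }
})

test_that("the selection pipeline is deterministic under a fixed seed", {
  feats <- make_gaussian_features(80, feature_names_20[1:8],
                                  informative = "HR_f1", delta = 2, seed = 16)
  s1 <- suppressWarnings(select_features(feats, families = c("LR", "SVM_RBF"),
                                         n_repeats = 5, seed = 20))
  s2 <- suppressWarnings(select_features(feats, families = c("LR", "SVM_RBF"),
                                         n_repeats = 5, seed = 20))
  expect_identical(s1$features, s2$features)
  expect_identical(s1$provenance, s2$provenance)
})
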