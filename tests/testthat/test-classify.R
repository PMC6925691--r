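toy_features <- function(n_per_group, delta, seed, p = 2) {
  make_gaussian_features(n_per_group,
                         paste0("x", seq_len(p)),
                         informative = paste0("x", seq_len(min(p, 2))),
                         delta = delta, seed = seed)
}

test_that("stratified split preserves counts and class ratio exactly", {
  labels <- rep(c(1L, 0L), each = 300)
  sp <- stratified_split(labels, train_frac = 0.75, seed = 1)
  expect_length(sp$train_idx, 450)
  expect_length(sp$test_idx, 150)
  expect_identical(sum(labels[sp$train_idx]), 225L)
  expect_identical(sum(labels[sp$test_idx]), 75L)
  # partition: disjoint and exhaustive
  expect_length(intersect(sp$train_idx, sp$test_idx), 0)
  expect_identical(sort(c(sp$train_idx, sp$test_idx)), seq_along(labels))
  # determinism
  sp2 <- stratified_split(labels, train_frac = 0.75, seed = 1)
  expect_identical(sp, sp2)
  expect_error(stratified_split(rep(1L, 10)), "both classes")
  expect_error(stratified_split(labels, train_frac = 1.2), "between 0 and 1")
})

test_that("tuning returns grid points and respects fold bounds", {
  feats <- toy_features(30, delta = 2, seed = 2)
  cfg <- model_config("SVM_RBF",
                      grid = expand.grid(sigma = 0.5, C = 1),
                      cv_folds = 5, seed = 2)
  tuned <- tune_model(cfg, feats)
  expect_equal(tuned$hyper$sigma, 0.5)
  expect_equal(tuned$hyper$C, 1)

  # empty grid families return their defaults unchanged
  lr <- tune_model(model_config("LR"), feats)
  expect_identical(lr$hyper, default_hyper("LR"))

  cfg10 <- model_config("SVM_RBF", grid = expand.grid(sigma = 0.5, C = 1),
                        cv_folds = 50, seed = 2)
  expect_error(tune_model(cfg10, feats), "cv_folds exceeds")

  # chosen point comes from the grid and carries the best CV AUC
  cfg2 <- model_config("SVM_RBF",
                       grid = expand.grid(sigma = c(0.1, 1), C = c(0.5, 2)),
                       cv_folds = 4, seed = 3)
  tuned2 <- tune_model(cfg2, feats)
  expect_true(tuned2$hyper$sigma %in% c(0.1, 1))
  expect_equal(max(tuned2$cv_table$cv_auc),
               tuned2$cv_table$cv_auc[
                 tuned2$cv_table$sigma == tuned2$hyper$sigma &
                 tuned2$cv_table$C == tuned2$hyper$C])
})

test_that("the reported cross-validation optima are inside default grids", {
  rbf <- default_grid("SVM_RBF")
  expect_true(any(rbf$sigma == 0.440227 & rbf$C == 0.25))
  poly <- default_grid("SVM_poly")
  expect_true(any(poly$degree == 3 & poly$scale == 0.1 & poly$C == 0.25))
  ann <- default_grid("ANN")
  expect_true(any(ann$size == 5 & ann$decay == 0.1))
  expect_identical(nrow(default_grid("LR")), 0L)
  expect_identical(nrow(default_grid("SVM_linear")), 0L)
})

test_that("all five families separate an easy problem and emit probabilities", {
  feats <- toy_features(40, delta = 6, seed = 4)
  sp <- stratified_split(feats, seed = 4)
  train <- feats[sp$train_idx, ]; test <- feats[sp$test_idx, ]
  for (fam in MODEL_FAMILIES) {
    cfg <- model_config(fam, seed = 4)
    fit <- suppressWarnings(fit_model(cfg, train))
    pred <- predict(fit, test)
    expect_true(all(pred$prob >= 0 & pred$prob <= 1), info = fam)
    expect_true(all(pred$class %in% 0:1), info = fam)
    acc <- mean(pred$class == test$label)
    expect_gt(acc, 0.95)
  }
})

test_that("label permutation drives test AUC to chance", {
  feats <- toy_features(60, delta = 4, seed = 5)
  set.seed(6)
  feats$label <- sample(feats$label)
  sp <- stratified_split(feats, seed = 6)
  fit <- suppressWarnings(fit_model(model_config("LR", seed = 6),
                                    feats[sp$train_idx, ]))
  auc <- evaluate_model(fit, feats[sp$test_idx, ])$auc
  expect_gt(auc, 0.3)
  expect_lt(auc, 0.7)
})

test_that("prediction enforces the strict 0.5 threshold and feature match", {
  feats <- toy_features(30, delta = 6, seed = 7)
  fit <- suppressWarnings(fit_model(model_config("LR", seed = 7), feats))
  bad <- feats
  colnames(bad)[colnames(bad) == "x1"] <- "y1"
  expect_error(predict(fit, bad), "missing feature columns")

  # boundary convention via the confusion step: 0.50 is a negative call
  rep <- evaluate_scores(c(0.50, 0.51), c(0L, 1L))
  expect_identical(unname(rep$confusion), c(1L, 0L, 1L, 0L))
  expect_equal(rep$accuracy, 1)
})

test_that("fits are deterministic under a fixed seed", {
  feats <- toy_features(40, delta = 2, seed = 8)
  for (fam in c("SVM_RBF", "ANN")) {
    f1 <- suppressWarnings(fit_model(model_config(fam, seed = 9), feats))
    f2 <- suppressWarnings(fit_model(model_config(fam, seed = 9), feats))
    expect_identical(predict(f1, feats)$prob, predict(f2, feats)$prob,
                     info = fam)
  }
})

test_that("RBF parameterization converters are mutual inverses", {
  s <- 0.440227
  expect_equal(rbf_width_to_sigma(rbf_sigma_to_width(s)), s)
  expect_equal(rbf_sigma_to_width(0.5), 1)
})
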