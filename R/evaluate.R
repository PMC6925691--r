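#' Area under the ROC curve of a score vector
#'
#' Rank-based (Mann-Whitney) AUC with mid-rank handling of tied scores;
#' identical to the trapezoid area over the empirical ROC curve.
#'
#' @param scores Numeric classifier scores (higher = more positive).
#' @param labels 0/1 labels, both classes present.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present to compute AUC")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Empirical ROC curve
#'
#' One point per distinct score threshold (descending), beginning at (0, 0)
#' and ending at (1, 1).
#'
#' @inheritParams auc_score
#' @return data.frame with columns `FPR`, `TPR`.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  # cumulative counts at each distinct threshold
  last_of_tie <- c(diff(s) != 0, TRUE)
  tp <- cumsum(y)[last_of_tie]
  fp <- cumsum(1 - y)[last_of_tie]
  data.frame(FPR = c(0, fp / n0), TPR = c(0, tp / n1))
}

#' Empirical precision-recall curve
#'
#' One point per distinct score threshold (descending). The precision at
#' recall 0 is taken as the precision of the highest-scoring threshold.
#'
#' @inheritParams auc_score
#' @return data.frame with columns `recall`, `precision`.
#' @export
pr_points <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  if (n1 == 0L) stop("no positive examples")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  last_of_tie <- c(diff(s) != 0, TRUE)
  tp <- cumsum(y)[last_of_tie]
  n_pred <- which(last_of_tie)
  recall <- tp / n1
  precision <- tp / n_pred
  data.frame(recall = c(0, recall), precision = c(precision[1], precision))
}

.trapezoid <- function(x, y) {
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Compute a full evaluation report from scores and labels
#'
#' Threshold-free AUC (trapezoid over the empirical ROC; equals the
#' Mann-Whitney statistic with mid-ranks) and PR-AUC, plus the confusion
#' matrix and derived metrics at the classification threshold (strict
#' `score > threshold` means a positive call). PPV/NPV are `NA` when the
#' corresponding call count is zero, never silently 0.
#'
#' @inheritParams auc_score
#' @param threshold Probability threshold for the confusion metrics
#'   (default 0.5).
#' @return A list of class `eval_report`: `auc`, `auc_pr`, `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `accuracy`, `confusion` (TP/FP/TN/FN),
#'   `roc` and `pr` curve data.frames, `n`.
#' @export
evaluate_scores <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  if (length(unique(labels)) < 2L) {
    stop("test set must contain both classes")
  }
  roc <- roc_points(scores, labels)
  pr <- pr_points(scores, labels)
  auc <- .trapezoid(roc$FPR, roc$TPR)
  auc_pr <- .trapezoid(pr$recall, pr$precision)
  pred <- as.integer(scores > threshold)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  tn <- sum(pred == 0L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  structure(
    list(
      auc = auc,
      auc_pr = auc_pr,
      sensitivity = tp / (tp + fn),
      specificity = tn / (tn + fp),
      ppv = if (tp + fp > 0L) tp / (tp + fp) else NA_real_,
      npv = if (tn + fn > 0L) tn / (tn + fn) else NA_real_,
      accuracy = (tp + tn) / length(labels),
      confusion = c(TP = tp, FP = fp, TN = tn, FN = fn),
      threshold = threshold,
      roc = roc,
      pr = pr,
      n = length(labels)
    ),
    class = "eval_report"
  )
}

#' Evaluate a fitted classifier on a test set
#'
#' @param fit A `fit_result` from [fit_model()].
#' @param test Feature data.frame with a `label` column (as produced by
#'   [featurize_cohort()], possibly subset to test rows).
#' @param threshold Classification threshold (default 0.5).
#' @return An `eval_report`; see [evaluate_scores()].
#' @export
evaluate_model <- function(fit, test, threshold = 0.5) {
  pred <- predict(fit, test)
  rep <- evaluate_scores(pred$prob, test$label, threshold = threshold)
  rep$family <- fit$family
  rep
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report>%s n = %d\n",
              if (!is.null(x$family)) paste0(" ", x$family) else "", x$n))
  cat(sprintf("  AUC %.4f | AUC-PR %.4f | accuracy %.4f\n",
              x$auc, x$auc_pr, x$accuracy))
  cat(sprintf("  sens %.4f | spec %.4f | PPV %s | NPV %s\n",
              x$sensitivity, x$specificity,
              ifelse(is.na(x$ppv), "NA", sprintf("%.4f", x$ppv)),
              ifelse(is.na(x$npv), "NA", sprintf("%.4f", x$npv))))
  invisible(x)
}

#' Per-feature group statistics with Welch p-values
#'
#' For every feature column, the mean and standard deviation within the
#' septic (label 1) and control (label 0) groups and the two-sided Welch
#' two-sample t-test p-value, reproducing the structure of the published
#' group-separation table.
#'
#' @param features Feature data.frame with `label` column.
#' @return data.frame: `feature`, `septic_mean`, `septic_sd`, `control_mean`,
#'   `control_sd`, `p_value`.
#' @export
group_stats <- function(features) {
  stopifnot("label" %in% colnames(features))
  cols <- feature_columns(features)
  lab <- features$label
  if (sum(lab == 1L) < 2L || sum(lab == 0L) < 2L) {
    stop("each group needs at least 2 patients for group statistics")
  }
  rows <- lapply(cols, function(cl) {
    xs <- features[[cl]][lab == 1L]
    xc <- features[[cl]][lab == 0L]
    p <- if (stats::sd(xs) == 0 && stats::sd(xc) == 0) {
      if (mean(xs) == mean(xc)) 1 else 0
    } else {
      stats::t.test(xs, xc, var.equal = FALSE)$p.value
    }
    data.frame(feature = cl,
               septic_mean = mean(xs), septic_sd = stats::sd(xs),
               control_mean = mean(xc), control_sd = stats::sd(xc),
               p_value = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Shared engine for the two sweeps: full pipeline per swept value with a
# deterministic per-value seed derived from the master seed.
.sweep_engine <- function(axis, values, T_hours, horizon_hours, n_septic,
                          n_control, septic_params, control_params, family,
                          feature_names, train_frac, seed, tune, cv_folds) {
  set.seed(seed)
  value_seeds <- sample.int(.Machine$integer.max - 1L, length(values))
  aucs <- numeric(length(values))
  for (i in seq_along(values)) {
    Tv <- if (axis == "collection_T") values[i] else T_hours
    hv <- if (axis == "prediction_horizon") values[i] else horizon_hours
    spec <- cohort_spec(n_septic = n_septic, n_control = n_control,
                        T_hours = Tv, horizon_hours = hv,
                        seed = value_seeds[i])
    cohort <- simulate_cohort(spec, septic_params, control_params)
    feats <- featurize_cohort(cohort)
    split <- stratified_split(feats, train_frac = train_frac,
                              seed = value_seeds[i])
    train <- feats[split$train_idx, ]
    test <- feats[split$test_idx, ]
    if (is.null(feature_names)) {
      sel <- select_features(train, seed = value_seeds[i])
      use <- sel$features
    } else {
      use <- feature_names
    }
    cfg <- model_config(family, cv_folds = cv_folds, seed = value_seeds[i])
    hyper <- if (tune) tune_model(cfg, train, feature_names = use)$hyper
             else default_hyper(family)
    fit <- fit_model(cfg, train, feature_names = use, hyper = hyper)
    aucs[i] <- evaluate_model(fit, test)$auc
  }
  structure(
    data.frame(axis = axis, value = values, auc = aucs, family = family,
               stringsAsFactors = FALSE),
    class = c("sweep_result", "data.frame")
  )
}

#' Sweep the data-collection interval
#'
#' Runs the full pipeline (simulate, extract at each collection interval `T`,
#' optionally select, train, evaluate) once per `T` value and reports the
#' test AUC per value. Because septic instability ramps up toward `T0`,
#' longer collection intervals accumulate more separating signal.
#'
#' @param T_values Collection intervals in hours (default 1:8).
#' @param horizon_hours Fixed prediction horizon (default 4).
#' @param n_septic,n_control Cohort sizes per swept value.
#' @param septic_params,control_params Generator parameters.
#' @param family Model family (see [MODEL_FAMILIES]); default `"SVM_RBF"`.
#' @param feature_names Features to model on; `NULL` runs the importance
#'   based selection per swept value (slower).
#' @param train_frac Training fraction (default 0.75).
#' @param seed Master seed; per-value seeds are derived from it.
#' @param tune Cross-validate hyperparameters per value (default FALSE: the
#'   printed optimum defaults are used).
#' @param cv_folds Folds when tuning.
#' @return A `sweep_result` data.frame: `axis`, `value`, `auc`, `family`.
#' @export
sweep_collection_interval <- function(T_values = 1:8, horizon_hours = 4,
                                      n_septic = 150, n_control = 150,
                                      septic_params = default_generator_params("septic"),
                                      control_params = default_generator_params("control"),
                                      family = "SVM_RBF",
                                      feature_names = NULL,
                                      train_frac = 0.75, seed = 1L,
                                      tune = FALSE, cv_folds = 10L) {
  .sweep_engine("collection_T", T_values, NA, horizon_hours, n_septic,
                n_control, septic_params, control_params, family,
                feature_names, train_frac, seed, tune, cv_folds)
}

#' Sweep the prediction horizon
#'
#' As [sweep_collection_interval()], but varying the gap between the
#' prediction moment and `T0` at a fixed collection interval. Windows pushed
#' further from `T0` overlap the pre-onset instability ramp less, so the
#' septic signal dilutes and AUC falls at long horizons.
#'
#' @param horizons Horizon values in hours (default 1:5).
#' @param T_hours Fixed collection interval (default 8).
#' @inheritParams sweep_collection_interval
#' @return A `sweep_result` data.frame.
#' @export
sweep_prediction_horizon <- function(horizons = 1:5, T_hours = 8,
                                     n_septic = 150, n_control = 150,
                                     septic_params = default_generator_params("septic"),
                                     control_params = default_generator_params("control"),
                                     family = "SVM_RBF",
                                     feature_names = NULL,
                                     train_frac = 0.75, seed = 1L,
                                     tune = FALSE, cv_folds = 10L) {
  .sweep_engine("prediction_horizon", horizons, T_hours, NA, n_septic,
                n_control, septic_params, control_params, family,
                feature_names, train_frac, seed, tune, cv_folds)
}

#' Compare variability features against descriptive baseline features
#'
#' Extracts both feature sets from the same simulated windows, trains each
#' requested model family on each set with an identical stratified split,
#' and returns the paired test metrics side by side.
#'
#' @param cohort A `vital_cohort`.
#' @param families Model families to compare (default all five).
#' @param feature_names Optional restriction of the variability features used
#'   (`NULL` = all 20); baseline models always use their 20 descriptive
#'   features.
#' @param train_frac,seed,tune,cv_folds As in [sweep_collection_interval()].
#' @return data.frame with one row per family and feature set: `family`,
#'   `feature_set`, `auc`, `auc_pr`, `accuracy`, `sensitivity`, `specificity`,
#'   `ppv`, `npv`.
#' @export
compare_feature_sets <- function(cohort, families = MODEL_FAMILIES,
                                 feature_names = NULL, train_frac = 0.75,
                                 seed = 1L, tune = FALSE, cv_folds = 10L) {
  fv <- featurize_cohort(cohort, feature_set = "variability")
  fb <- featurize_cohort(cohort, feature_set = "baseline")
  split <- stratified_split(fv, train_frac = train_frac, seed = seed)
  rows <- list()
  for (fam in families) {
    for (fs in c("variability", "baseline")) {
      feats <- if (fs == "variability") fv else fb
      use <- if (fs == "variability" && !is.null(feature_names)) {
        feature_names
      } else {
        feature_columns(feats)
      }
      cfg <- model_config(fam, cv_folds = cv_folds, seed = seed)
      train <- feats[split$train_idx, ]
      test <- feats[split$test_idx, ]
      hyper <- if (tune) tune_model(cfg, train, feature_names = use)$hyper
               else default_hyper(fam)
      fit <- fit_model(cfg, train, feature_names = use, hyper = hyper)
      ev <- evaluate_model(fit, test)
      rows[[paste(fam, fs)]] <- data.frame(
        family = fam, feature_set = fs, auc = ev$auc, auc_pr = ev$auc_pr,
        accuracy = ev$accuracy, sensitivity = ev$sensitivity,
        specificity = ev$specificity, ppv = ev$ppv, npv = ev$npv,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out
}
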