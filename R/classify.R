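#' Supported classifier families
#'
#' Logistic regression, support vector machines with linear / radial-basis /
#' polynomial kernels, and a single-hidden-layer neural network.
#'
#' @export
MODEL_FAMILIES <- c("LR", "SVM_linear", "SVM_RBF", "SVM_poly", "ANN")

#' Convert between RBF kernel parameterizations
#'
#' Kernel-machine toolkits parameterize the Gaussian kernel either as
#' `K = exp(-sigma * r^2)` (the `sigma` used throughout this package and in
#' the printed optimum `sigma = 0.440227`) or as a bandwidth
#' `K = exp(-r^2 / (2 * s^2))`. These helpers map between the two.
#'
#' @param sigma Rate-form parameter.
#' @param width Bandwidth-form parameter `s`.
#' @return The equivalent parameter in the other form.
#' @export
rbf_sigma_to_width <- function(sigma) 1 / sqrt(2 * sigma)

#' @rdname rbf_sigma_to_width
#' @export
rbf_width_to_sigma <- function(width) 1 / (2 * width^2)

#' Default hyperparameter grid per family
#'
#' The grids bracket the cross-validation optima reported for this method
#' (RBF `sigma = 0.440227`, `C = 0.25`; polynomial degree 3, scale 0.1,
#' `C = 0.25`; 5 hidden units with decay 0.1). Logistic regression and the
#' linear-kernel SVM have no tunable parameters.
#'
#' @param family One of [MODEL_FAMILIES].
#' @return data.frame grid (possibly 0 rows).
#' @export
default_grid <- function(family) {
  family <- match.arg(family, MODEL_FAMILIES)
  switch(family,
    LR = data.frame(),
    SVM_linear = data.frame(),
    SVM_RBF = expand.grid(sigma = c(0.1, 0.25, 0.440227, 1, 2),
                          C = c(0.25, 0.5, 1, 2)),
    SVM_poly = expand.grid(degree = c(2, 3), scale = c(0.01, 0.1, 1),
                           C = c(0.25, 0.5, 1, 2)),
    ANN = expand.grid(size = c(3, 5, 7), decay = c(0.01, 0.1, 0.5))
  )
}

#' Default (reported-optimum) hyperparameters per family
#'
#' Used when fitting without cross-validated tuning.
#'
#' @param family One of [MODEL_FAMILIES].
#' @return Named list of hyperparameters (empty for LR / linear SVM).
#' @export
default_hyper <- function(family) {
  family <- match.arg(family, MODEL_FAMILIES)
  switch(family,
    LR = list(),
    SVM_linear = list(C = 1),
    SVM_RBF = list(sigma = 0.440227, C = 0.25),
    SVM_poly = list(degree = 3, scale = 0.1, C = 0.25),
    ANN = list(size = 5, decay = 0.1)
  )
}

#' Model configuration
#'
#' @param family One of [MODEL_FAMILIES].
#' @param grid Hyperparameter grid for [tune_model()]; defaults to
#'   [default_grid()].
#' @param cv_folds Stratified cross-validation folds for tuning (default 10).
#' @param seed Seed for fold assignment and stochastic fits.
#' @return A list of class `model_config`.
#' @export
model_config <- function(family, grid = default_grid(family), cv_folds = 10L,
                         seed = 1L) {
  family <- match.arg(family, MODEL_FAMILIES)
  structure(
    list(family = family, grid = grid, cv_folds = as.integer(cv_folds),
         seed = as.integer(seed)),
    class = "model_config"
  )
}

#' Stratified train/test split
#'
#' Splits per class so the class ratio is preserved exactly when the counts
#' divide evenly (a balanced 600-record cohort at 75% yields exactly
#' 450 training and 150 test records, 1:1 in both).
#'
#' @param features Feature data.frame with a `label` column (or a bare 0/1
#'   label vector).
#' @param train_frac Training fraction in (0, 1), default 0.75.
#' @param seed RNG seed.
#' @return A list of class `split_result`: integer `train_idx`, `test_idx`.
#' @export
stratified_split <- function(features, train_frac = 0.75, seed = 1L) {
  labels <- if (is.data.frame(features)) features$label else as.integer(features)
  if (!(train_frac > 0 && train_frac < 1)) {
    stop("train_frac must be strictly between 0 and 1")
  }
  if (length(unique(labels)) < 2L) {
    stop("both classes must be present for a stratified split")
  }
  set.seed(seed)
  train_idx <- integer(0)
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    n_train <- round(train_frac * length(idx))
    train_idx <- c(train_idx, sample(idx, n_train))
  }
  train_idx <- sort(train_idx)
  structure(
    list(train_idx = train_idx,
         test_idx = setdiff(seq_along(labels), train_idx),
         train_frac = train_frac, seed = seed),
    class = "split_result"
  )
}

# Stratified fold assignment for cross-validation.
.cv_fold_ids <- function(labels, k, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

.as_matrix <- function(features, feature_names) {
  missing <- setdiff(feature_names, colnames(features))
  if (length(missing)) {
    stop("missing feature columns: ", paste(missing, collapse = ", "))
  }
  as.matrix(features[, feature_names, drop = FALSE])
}

# Raw estimator fit on an already standardized matrix.
.fit_engine <- function(family, x, y, hyper, seed) {
  set.seed(seed)  # kernlab Platt fit and nnet initialization are stochastic
  yf <- factor(y, levels = c(0L, 1L))
  if (family == "LR") {
    df <- data.frame(y = y, x)
    stats::glm(y ~ ., data = df, family = stats::binomial())
  } else if (family == "SVM_linear") {
    kernlab::ksvm(x, yf, type = "C-svc", kernel = "vanilladot",
                  kpar = list(), C = if (is.null(hyper$C)) 1 else hyper$C,
                  prob.model = TRUE, scaled = FALSE)
  } else if (family == "SVM_RBF") {
    kernlab::ksvm(x, yf, type = "C-svc", kernel = "rbfdot",
                  kpar = list(sigma = hyper$sigma), C = hyper$C,
                  prob.model = TRUE, scaled = FALSE)
  } else if (family == "SVM_poly") {
    kernlab::ksvm(x, yf, type = "C-svc", kernel = "polydot",
                  kpar = list(degree = hyper$degree, scale = hyper$scale,
                              offset = 1), C = hyper$C,
                  prob.model = TRUE, scaled = FALSE)
  } else if (family == "ANN") {
    nnet::nnet(x, y, size = hyper$size, decay = hyper$decay,
               maxit = 500, trace = FALSE, entropy = TRUE)
  } else stop("unknown family ", family)
}

.predict_engine <- function(family, model, x) {
  if (family == "LR") {
    p <- stats::predict(model, newdata = data.frame(x), type = "response")
  } else if (family %in% c("SVM_linear", "SVM_RBF", "SVM_poly")) {
    p <- kernlab::predict(model, x, type = "probabilities")[, "1", drop = TRUE]
  } else {
    p <- as.numeric(stats::predict(model, x))
  }
  pmin(pmax(as.numeric(p), 0), 1)
}

#' Tune hyperparameters by stratified cross-validation
#'
#' Evaluates every grid point by mean out-of-fold AUC and returns the
#' maximizer. The grid is pre-ordered by increasing model complexity
#' (cost `C`, then kernel/architecture parameters), so exact ties resolve to
#' the least complex point. Families with empty grids return their defaults
#' unchanged.
#'
#' @param config A [model_config()].
#' @param train Training feature data.frame with `label`.
#' @param feature_names Feature columns to use (default: all).
#' @return list with `hyper` (chosen hyperparameters), `cv_table` (grid with
#'   mean fold AUC) and `family`.
#' @export
tune_model <- function(config, train, feature_names = feature_columns(train)) {
  stopifnot(inherits(config, "model_config"))
  grid <- config$grid
  if (nrow(grid) == 0L) {
    return(list(hyper = default_hyper(config$family), cv_table = NULL,
                family = config$family))
  }
  labels <- train$label
  k <- config$cv_folds
  if (k > min(table(labels))) {
    stop("cv_folds exceeds the smallest class count in the training set")
  }
  complexity_cols <- intersect(c("C", "sigma", "degree", "scale", "size",
                                 "decay"), colnames(grid))
  grid <- grid[do.call(order, grid[complexity_cols]), , drop = FALSE]
  x_all <- .as_matrix(train, feature_names)
  fold <- .cv_fold_ids(labels, k, config$seed)
  mean_auc <- numeric(nrow(grid))
  for (gi in seq_len(nrow(grid))) {
    hyper <- as.list(grid[gi, , drop = FALSE])
    fold_auc <- numeric(k)
    for (f in seq_len(k)) {
      tr <- fold != f
      mu <- colMeans(x_all[tr, , drop = FALSE])
      sdv <- apply(x_all[tr, , drop = FALSE], 2, stats::sd)
      sdv[sdv == 0] <- 1
      xs_tr <- scale(x_all[tr, , drop = FALSE], mu, sdv)
      xs_te <- scale(x_all[!tr, , drop = FALSE], mu, sdv)
      m <- .fit_engine(config$family, xs_tr, labels[tr], hyper,
                       seed = config$seed + 1000L * gi + f)
      p <- .predict_engine(config$family, m, xs_te)
      fold_auc[f] <- auc_score(p, labels[!tr])
    }
    mean_auc[gi] <- mean(fold_auc)
  }
  best <- which.max(mean_auc)  # first maximum = least complex on ties
  cv_table <- cbind(grid, cv_auc = mean_auc)
  list(hyper = as.list(grid[best, , drop = FALSE]), cv_table = cv_table,
       family = config$family)
}

#' Fit a classifier on a training set
#'
#' Standardizes the features with training-set means and standard deviations,
#' fits the requested estimator, and returns a predictor producing sepsis
#' probabilities in `[0, 1]` (SVM margins are mapped through a fitted sigmoid;
#' logistic regression and the network output probabilities natively).
#'
#' @param config A [model_config()].
#' @param train Training feature data.frame with `label`.
#' @param feature_names Feature columns to use (default: all).
#' @param hyper Hyperparameters; defaults to [default_hyper()] for the family
#'   (pass the result of [tune_model()] to use tuned values).
#' @return A list of class `fit_result`.
#' @export
fit_model <- function(config, train, feature_names = feature_columns(train),
                      hyper = NULL) {
  stopifnot(inherits(config, "model_config"))
  if (is.null(hyper)) hyper <- default_hyper(config$family)
  labels <- as.integer(train$label)
  if (length(unique(labels)) < 2L) stop("training set must contain both classes")
  x <- .as_matrix(train, feature_names)
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[sdv == 0] <- 1
  xs <- scale(x, mu, sdv)
  model <- .fit_engine(config$family, xs, labels, hyper, seed = config$seed)
  structure(
    list(family = config$family, hyper = hyper, model = model,
         center = mu, scale = sdv, feature_names = feature_names,
         seed = config$seed),
    class = "fit_result"
  )
}

#' Predict sepsis probabilities and classes
#'
#' A patient is called septic when the predicted probability strictly
#' exceeds the threshold (a probability of exactly 0.5 is a negative call).
#'
#' @param object A `fit_result`.
#' @param newdata Feature data.frame containing the training feature columns.
#' @param threshold Classification threshold (default 0.5).
#' @param ... Unused.
#' @return data.frame with columns `prob` and `class`.
#' @export
predict.fit_result <- function(object, newdata, threshold = 0.5, ...) {
  x <- .as_matrix(newdata, object$feature_names)
  xs <- scale(x, object$center, object$scale)
  p <- .predict_engine(object$family, object$model, xs)
  data.frame(prob = p, class = as.integer(p > threshold))
}

#' @export
print.fit_result <- function(x, ...) {
  hp <- if (length(x$hyper)) {
    paste(names(x$hyper), unlist(x$hyper), sep = "=", collapse = ", ")
  } else "none"
  cat(sprintf("<fit_result> %s (%d features), hyperparameters: %s\n",
              x$family, length(x$feature_names), hp))
  invisible(x)
}
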