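# Classifier arm: stratified 80/20 split, exhaustive grid search with
# stratified 5-fold cross-validation over random forests (ranger) and
# gradient boosting (xgboost), and the six-metric evaluation report.

#' Train/test split specification
#'
#' @param test_fraction Fraction of samples held out for testing.
#' @param stratified Preserve class proportions (within one sample per
#'   class) in both parts.
#' @param seed Integer seed; identical seeds give identical membership.
#' @return Object of class \code{split_spec}.
#' @export
split_spec <- function(test_fraction = 0.20, stratified = TRUE, seed = 1L) {
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("test_fraction must lie strictly between 0 and 1")
  }
  structure(list(test_fraction = test_fraction, stratified = stratified,
                 seed = as.integer(seed)),
            class = "split_spec")
}

#' Split features and labels into train and test sets
#'
#' @param features Samples x features matrix.
#' @param labels Class vector aligned with rows.
#' @param spec A \code{\link{split_spec}}.
#' @return List with \code{train} and \code{test}, each holding \code{x},
#'   \code{y} and \code{idx} (row indices into the input).
#' @export
train_test_split <- function(features, labels, spec) {
  stopifnot(inherits(spec, "split_spec"))
  features <- as.matrix(features)
  if (nrow(features) != length(labels)) stop("labels must align with rows")
  classes <- unique(as.character(labels))
  if (length(classes) < 2) stop("both classes must be present")
  set.seed(spec$seed)
  n <- nrow(features)
  if (spec$stratified) {
    test_idx <- integer(0)
    for (cl in sort(classes)) {
      rows <- which(as.character(labels) == cl)
      n_test <- round(spec$test_fraction * length(rows))
      if (n_test < 1 || n_test >= length(rows)) {
        stop(sprintf("class '%s' too small to stratify", cl))
      }
      test_idx <- c(test_idx, sample(rows, n_test))
    }
    test_idx <- sort(test_idx)
  } else {
    test_idx <- sort(sample.int(n, round(spec$test_fraction * n)))
  }
  train_idx <- setdiff(seq_len(n), test_idx)
  list(train = list(x = features[train_idx, , drop = FALSE],
                    y = labels[train_idx], idx = train_idx),
       test = list(x = features[test_idx, , drop = FALSE],
                   y = labels[test_idx], idx = test_idx))
}

#' Hyperparameter grid specification
#'
#' Default grids: forests tune \code{num_trees} in \{200, 500\} and
#' \code{max_depth} in \{0 (unlimited), 10\}; boosting tunes
#' \code{max_depth} in \{3, 6\} and \code{eta} in \{0.1, 0.3\} at 200
#' rounds.
#'
#' @param model_name \code{"random_forest"} or \code{"xgboost"}.
#' @param grid Named list of parameter value vectors; \code{NULL} uses the
#'   default grid for the model.
#' @param cv_folds Number of cross-validation folds (at least 2).
#' @param scoring CV selection metric; \code{"accuracy"}.
#' @return Object of class \code{grid_spec}.
#' @export
grid_spec <- function(model_name = c("random_forest", "xgboost"),
                      grid = NULL, cv_folds = 5, scoring = "accuracy") {
  model_name <- match.arg(model_name)
  if (cv_folds < 2) stop("cv_folds must be at least 2")
  if (scoring != "accuracy") stop("only accuracy scoring is provided")
  if (is.null(grid)) {
    grid <- switch(model_name,
      random_forest = list(num_trees = c(200, 500), max_depth = c(0, 10)),
      xgboost = list(num_trees = 200, max_depth = c(3, 6),
                     eta = c(0.1, 0.3)))
  }
  if (length(grid) == 0) stop("grid must be non-empty")
  structure(list(model_name = model_name, grid = grid,
                 cv_folds = as.integer(cv_folds), scoring = scoring),
            class = "grid_spec")
}

# fit one parameter setting; y is a factor with two levels, second level =
# positive class (xgboost label 1)
fit_one_model <- function(model_name, params, x, y, seed) {
  if (model_name == "random_forest") {
    set.seed(seed)
    fit <- ranger::ranger(
      x = x, y = y,
      num.trees = params$num_trees,
      max.depth = params$max_depth,
      probability = TRUE,
      importance = "impurity",
      num.threads = 1,
      seed = seed)
    fit
  } else {
    dtrain <- xgboost::xgb.DMatrix(data = x,
                                   label = as.numeric(y == levels(y)[2]))
    xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    max_depth = params$max_depth, eta = params$eta,
                    nthread = 1, seed = seed),
      data = dtrain, nrounds = params$num_trees, verbose = 0)
  }
}

# positive-class probability from either backend
predict_prob <- function(model_name, fit, x, positive_level) {
  if (model_name == "random_forest") {
    p <- stats::predict(fit, data = x, num.threads = 1)$predictions
    p[, positive_level]
  } else {
    stats::predict(fit, xgboost::xgb.DMatrix(data = x))
  }
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in levels(y)) {
    rows <- which(y == cl)
    fold[rows] <- sample(rep_len(seq_len(k), length(rows)))
  }
  fold
}

#' Grid-search cross-validated model fitting
#'
#' Evaluates every combination in the grid by stratified k-fold
#' cross-validation on the training data only, picks the combination with
#' the highest mean CV score (ties broken by grid order) and refits it on
#' the full training set.
#'
#' @param x Training features (samples x features matrix).
#' @param y Training labels (two classes).
#' @param spec A \code{\link{grid_spec}}.
#' @param seed Integer seed for fold assignment and model fitting.
#' @param positive Positive-class label; defaults to the lexicographically
#'   larger class.
#' @return Object of class \code{fitted_classifier} with the refitted
#'   model, \code{best_params}, the full \code{cv_table} and the label
#'   encoding.
#' @export
grid_search_fit <- function(x, y, spec, seed = 1L, positive = NULL) {
  stopifnot(inherits(spec, "grid_spec"))
  x <- as.matrix(x)
  lev <- sort(unique(as.character(y)))
  if (length(lev) != 2) stop("need exactly two classes")
  if (is.null(positive)) positive <- lev[2]
  if (!positive %in% lev) stop("positive class not present in labels")
  lev <- c(setdiff(lev, positive), positive)  # positive class last
  yf <- factor(as.character(y), levels = lev)

  combos <- expand.grid(spec$grid, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
  set.seed(seed)
  fold <- stratified_folds(yf, spec$cv_folds)
  for (k in seq_len(spec$cv_folds)) {
    held <- yf[fold == k]
    if (length(unique(held)) < 2 || length(held) == 0) {
      stop(sprintf("fold %d is degenerate (single class); use fewer folds", k))
    }
  }

  cv_scores <- numeric(nrow(combos))
  for (i in seq_len(nrow(combos))) {
    params <- as.list(combos[i, , drop = FALSE])
    accs <- numeric(spec$cv_folds)
    for (k in seq_len(spec$cv_folds)) {
      tr <- fold != k
      fit <- fit_one_model(spec$model_name, params,
                           x[tr, , drop = FALSE], yf[tr], seed = seed + k)
      prob <- predict_prob(spec$model_name, fit, x[!tr, , drop = FALSE],
                           positive)
      pred <- ifelse(prob >= 0.5, lev[2], lev[1])
      accs[k] <- mean(pred == as.character(yf[!tr]))
    }
    cv_scores[i] <- mean(accs)
  }
  best <- which.max(cv_scores)  # first maximum = grid order tie-break
  best_params <- as.list(combos[best, , drop = FALSE])
  final <- fit_one_model(spec$model_name, best_params, x, yf, seed = seed)

  cv_table <- cbind(combos, mean_cv_score = cv_scores)
  structure(
    list(model_name = spec$model_name, fit = final,
         best_params = best_params, cv_table = cv_table,
         levels = lev, positive = positive,
         feature_names = colnames(x)),
    class = "fitted_classifier")
}

#' @export
print.fitted_classifier <- function(x, ...) {
  cat(sprintf("fitted_classifier (%s), positive class '%s'\n  best params: %s\n",
              x$model_name, x$positive,
              paste(names(x$best_params), unlist(x$best_params),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Predict class labels
#'
#' @param object A \code{\link{grid_search_fit}} result.
#' @param newdata Samples x features matrix.
#' @param type \code{"class"} or \code{"prob"} (positive-class
#'   probability).
#' @param ... Unused.
#' @return Character vector of classes or numeric probabilities.
#' @export
predict.fitted_classifier <- function(object, newdata, type = "class", ...) {
  newdata <- as.matrix(newdata)
  prob <- predict_prob(object$model_name, object$fit, newdata,
                       object$positive)
  if (type == "prob") return(prob)
  ifelse(prob >= 0.5, object$levels[2], object$levels[1])
}

#' F1 score from precision and recall
#'
#' \eqn{F_1 = 2PR / (P + R)}; \code{NaN} when both are zero.
#'
#' @param precision,recall Values in [0, 1].
#' @return The harmonic mean of precision and recall.
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall > 0,
         2 * precision * recall / (precision + recall), NaN)
}

#' Classification metrics from confusion counts
#'
#' Computes accuracy, precision (PPV), NPV, recall (sensitivity),
#' specificity and F1 from the four confusion counts. Ratios with a zero
#' denominator are reported as \code{NaN} and flagged, never coerced to 0.
#'
#' @param tp,fp,tn,fn Non-negative confusion counts.
#' @return Object of class \code{metrics_report}; a list with the six
#'   metrics, the counts and \code{undefined}, the names of any metrics
#'   with zero denominators.
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  n <- tp + fp + tn + fn
  if (n == 0) stop("empty test set")
  safe <- function(num, den) if (den > 0) num / den else NaN
  precision <- safe(tp, tp + fp)
  npv <- safe(tn, tn + fn)
  recall <- safe(tp, tp + fn)
  specificity <- safe(tn, tn + fp)
  out <- list(accuracy = (tp + tn) / n,
              precision_ppv = precision, npv = npv,
              recall_sensitivity = recall, specificity = specificity,
              f1 = f1_score(precision, recall),
              counts = c(TP = tp, FP = fp, TN = tn, FN = fn))
  out$undefined <- names(which(vapply(
    out[c("precision_ppv", "npv", "recall_sensitivity", "specificity",
          "f1")],
    function(v) is.nan(v), logical(1))))
  structure(out, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "accuracy %.4f | precision %.4f | NPV %.4f | recall %.4f | specificity %.4f | F1 %.4f\n",
    x$accuracy, x$precision_ppv, x$npv, x$recall_sensitivity,
    x$specificity, x$f1))
  invisible(x)
}

#' Evaluate a fitted classifier on a test set
#'
#' @param model A \code{\link{grid_search_fit}} result.
#' @param x_test,y_test Test features and labels.
#' @param positive Positive-class label; defaults to the model's.
#' @return List with \code{confusion} (named TP/FP/TN/FN vector) and
#'   \code{metrics} (a \code{\link{confusion_metrics}} report, augmented
#'   with \code{wall_time_s} and \code{dataset_shape}).
#' @export
evaluate_model <- function(model, x_test, y_test, positive = NULL) {
  stopifnot(inherits(model, "fitted_classifier"))
  if (length(y_test) == 0) stop("empty test set")
  if (is.null(positive)) positive <- model$positive
  t0 <- proc.time()[["elapsed"]]
  pred <- predict(model, x_test)
  elapsed <- proc.time()[["elapsed"]] - t0
  y <- as.character(y_test)
  tp <- sum(pred == positive & y == positive)
  fp <- sum(pred == positive & y != positive)
  tn <- sum(pred != positive & y != positive)
  fn <- sum(pred != positive & y == positive)
  metrics <- confusion_metrics(tp, fp, tn, fn)
  metrics$wall_time_s <- elapsed
  metrics$dataset_shape <- c(rows = nrow(as.matrix(x_test)),
                             cols = ncol(as.matrix(x_test)))
  list(confusion = c(TP = tp, FP = fp, TN = tn, FN = fn),
       metrics = metrics)
}
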