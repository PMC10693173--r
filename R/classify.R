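# Ensemble classification of daily activity levels on
# {sedentary, LPA, MPA, VPA, steps}: stratified splitting, grid-search
# tuning with k-fold cross-validation, the metric suite (accuracy,
# macro precision/recall/specificity/F1, multiclass MCC), a majority-class
# baseline, and the incremental last-week protocol.

.FEATURES <- c("sedentary", "lpa", "mpa", "vpa", "steps")

#' Stratified train/validation/test split
#'
#' Indices are partitioned per class by largest-remainder apportionment of
#' the ratios, so per-class proportions are preserved within rounding in
#' each part; deterministic under `seed`.
#'
#' @param labels Class label vector.
#' @param ratios Part fractions summing to 1 (default 60:20:20).
#' @param seed RNG seed.
#' @return List of integer index vectors `train`, `validation`, `test`.
#' @export
stratified_split <- function(labels, ratios = c(0.6, 0.2, 0.2), seed = 1L) {
  stopifnot(abs(sum(ratios) - 1) < 1e-8, length(ratios) == 3)
  counts <- table(labels)
  if (any(counts < length(ratios)))
    stop("every class needs at least as many members as parts")
  local_seed(seed, {
    parts <- list(train = integer(), validation = integer(), test = integer())
    for (cls in names(counts)) {
      idx <- sample(which(as.character(labels) == cls))
      alloc <- largest_remainder(ratios, length(idx))
      splits <- split(idx, rep(1:3, alloc))
      for (j in seq_along(parts))
        parts[[j]] <- c(parts[[j]], splits[[as.character(j)]] %||% integer())
    }
    lapply(parts, sort)
  })
}

#' Classifier configuration
#'
#' @param model One of `"random_forest"`, `"bagging"`, `"extra_trees"`,
#'   `"adaboost"`, `"gradient_boosting"`, `"voting"`,
#'   `"dummy_most_frequent"`.
#' @param grid Named list of hyperparameter vectors to search; the
#'   gradient-boosting default is
#'   `list(learning_rate = 0.1, max_depth = 3, n_estimators = 100)`.
#' @param cv_folds Cross-validation folds, k >= 5.
#' @param seed RNG seed.
#' @return Object of class `classifier_config`.
#' @export
classifier_config <- function(model = c("gradient_boosting", "random_forest",
                                        "bagging", "extra_trees", "adaboost",
                                        "voting", "dummy_most_frequent"),
                              grid = NULL, cv_folds = 5L, seed = 1L) {
  model <- match.arg(model)
  if (cv_folds < 5) stop("cv_folds must be >= 5")
  if (is.null(grid)) {
    grid <- switch(model,
      gradient_boosting = list(learning_rate = 0.1, max_depth = 3, n_estimators = 100),
      adaboost = list(n_estimators = 50, max_depth = 1),
      dummy_most_frequent = list(),
      list(n_estimators = 100))
  }
  structure(list(model = model, grid = grid, cv_folds = as.integer(cv_folds),
                 seed = as.integer(seed)), class = "classifier_config")
}

# Fit one model with fixed hyperparameters.  `y` must be a factor whose
# levels cover all classes.
.fit_model <- function(model, x, y, params, seed = 1L) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  lev <- levels(y)
  n_est <- params$n_estimators %||% 100
  fit <- local_seed(seed, switch(model,
    random_forest = randomForest::randomForest(x, y, ntree = n_est),
    bagging = randomForest::randomForest(x, y, ntree = n_est, mtry = ncol(x)),
    extra_trees = ranger::ranger(
      y = y, x = as.data.frame(x), num.trees = n_est,
      splitrule = "extratrees", num.random.splits = 1,
      replace = FALSE, sample.fraction = 1, seed = seed),
    gradient_boosting = xgboost::xgboost(
      x, y, nrounds = n_est,
      learning_rate = params$learning_rate %||% 0.1,
      max_depth = params$max_depth %||% 3,
      nthreads = 1, verbosity = 0, seed = seed),
    adaboost = .fit_adaboost(x, y, n_est, params$max_depth %||% 1),
    voting = lapply(c("random_forest", "extra_trees", "gradient_boosting"),
                    function(m) .fit_model(m, x, y, params, seed)),
    dummy_most_frequent = list(majority = lev[which.max(table(y))]),
    stop("unknown model: ", model)))
  structure(list(model = model, fit = fit, levels = lev,
                 features = colnames(x)), class = "stepcoach_fit")
}

# Multiclass AdaBoost (SAMME) over shallow rpart trees.
.fit_adaboost <- function(x, y, n_estimators, max_depth) {
  n <- nrow(x); K <- nlevels(y)
  w <- rep(1 / n, n)
  learners <- list(); alphas <- numeric()
  df <- data.frame(y = y, x)
  for (m in seq_len(n_estimators)) {
    tree <- rpart::rpart(y ~ ., data = df, weights = w,
                         control = rpart::rpart.control(
                           maxdepth = max_depth, cp = 0, minsplit = 2,
                           xval = 0))
    pred <- predict(tree, df, type = "class")
    err <- sum(w * (pred != y)) / sum(w)
    if (err >= 1 - 1 / K) break
    if (err <= 1e-10) { learners <- c(learners, list(tree)); alphas <- c(alphas, 10); break }
    a <- log((1 - err) / err) + log(K - 1)
    learners <- c(learners, list(tree)); alphas <- c(alphas, a)
    w <- w * exp(a * (pred != y))
    w <- w / sum(w)
  }
  list(learners = learners, alphas = alphas, levels = levels(y))
}

.predict_adaboost <- function(fit, x) {
  df <- data.frame(x)
  K <- length(fit$levels)
  votes <- matrix(0, nrow(df), K, dimnames = list(NULL, fit$levels))
  for (m in seq_along(fit$learners)) {
    pred <- predict(fit$learners[[m]], df, type = "class")
    votes[cbind(seq_len(nrow(df)), as.integer(pred))] <-
      votes[cbind(seq_len(nrow(df)), as.integer(pred))] + fit$alphas[m]
  }
  factor(fit$levels[max.col(votes, ties.method = "first")], levels = fit$levels)
}

#' Predict classes from a fitted activity classifier
#'
#' @param object A fit returned by [train_and_tune()] (or internally by the
#'   training helpers).
#' @param newdata Feature matrix or data frame.
#' @param ... Unused.
#' @return Factor of predicted class labels.
#' @export
predict.stepcoach_fit <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  x <- x[, object$features, drop = FALSE]
  lev <- object$levels
  switch(object$model,
    random_forest = ,
    bagging = predict(object$fit, x),
    extra_trees = predict(object$fit, data = as.data.frame(x))$predictions,
    gradient_boosting = factor(as.character(predict(object$fit, x, type = "class")),
                               levels = lev),
    adaboost = .predict_adaboost(object$fit, x),
    voting = {
      preds <- vapply(object$fit, function(f) as.character(predict(f, x)),
                      character(nrow(x)))
      if (is.null(dim(preds))) preds <- matrix(preds, nrow = 1)
      factor(apply(preds, 1, function(r) names(which.max(table(factor(r, levels = lev))))),
             levels = lev)
    },
    dummy_most_frequent = factor(rep(object$fit$majority, nrow(x)), levels = lev))
}

#' Grid-search tuning with k-fold cross-validation
#'
#' Each grid point is scored by `cv_folds`-fold cross-validated accuracy on
#' the training part; the best point (ties to the first) is refit on the
#' full training part.  Validation data, if supplied, is scored with the
#' returned fit for reporting.
#'
#' @param config A [classifier_config()].
#' @param train_x,train_y Training features and labels.
#' @param validation_x,validation_y Optional validation part.
#' @return List with `fit`, `best_params`, `cv_results` (one row per grid
#'   point) and `validation_accuracy` (percent, or `NA`).
#' @export
train_and_tune <- function(config, train_x, train_y,
                           validation_x = NULL, validation_y = NULL) {
  stopifnot(inherits(config, "classifier_config"))
  y <- factor(train_y)
  grid <- config$grid
  if (!length(grid)) {
    if (config$model != "dummy_most_frequent")
      warning("empty grid; fitting with defaults")
    grid_df <- data.frame(row.names = 1)
  } else grid_df <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  cv_acc <- numeric(nrow(grid_df))
  if (nrow(grid_df) > 1) {
    folds <- local_seed(config$seed,
                        sample(rep_len(seq_len(config$cv_folds), length(y))))
    for (g in seq_len(nrow(grid_df))) {
      params <- as.list(grid_df[g, , drop = FALSE])
      acc <- vapply(seq_len(config$cv_folds), function(f) {
        tr <- folds != f
        if (nlevels(droplevels(y[tr])) < 2) return(NA_real_)
        fit <- .fit_model(config$model, train_x[tr, , drop = FALSE], y[tr],
                          params, seed = config$seed + f)
        mean(predict(fit, train_x[!tr, , drop = FALSE]) == y[!tr])
      }, numeric(1))
      cv_acc[g] <- mean(acc, na.rm = TRUE)
    }
    best <- which.max(cv_acc)
  } else best <- 1L
  best_params <- if (ncol(grid_df)) as.list(grid_df[best, , drop = FALSE]) else list()
  fit <- .fit_model(config$model, train_x, y, best_params, seed = config$seed)
  val_acc <- NA_real_
  if (!is.null(validation_x) && !is.null(validation_y))
    val_acc <- 100 * mean(predict(fit, validation_x) ==
                            factor(validation_y, levels = levels(y)))
  list(fit = fit, best_params = best_params,
       cv_results = cbind(grid_df, cv_accuracy = 100 * cv_acc),
       validation_accuracy = val_acc)
}

#' Classification metrics from a confusion matrix
#'
#' Rows are actual classes, columns predicted.  Precision, recall,
#' specificity and F1 are computed one-vs-rest per class and macro-averaged
#' over classes with positive support (classes without support are skipped
#' with a warning); MCC uses the standard multiclass generalization of the
#' binary `(TP*TN - FP*FN)` form.  All values are on the 0-100 scale.
#'
#' @param confusion Square contingency matrix of counts.
#' @return List with `accuracy`, `precision`, `recall`, `specificity`,
#'   `f1`, `mcc`, `confusion`.
#' @export
classification_metrics <- function(confusion) {
  cm <- as.matrix(confusion)
  stopifnot(nrow(cm) == ncol(cm))
  n <- sum(cm)
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  tn <- n - tp - fn - fp
  support <- rowSums(cm) > 0
  if (!all(support)) warning("classes without test support are skipped in macro averages")
  safe <- function(num, den) ifelse(den > 0, num / den, 0)
  prec <- safe(tp, tp + fp); rec <- safe(tp, tp + fn)
  spec <- safe(tn, tn + fp)
  f1 <- safe(2 * prec * rec, prec + rec)
  # multiclass MCC from the full confusion matrix
  s <- n; c_ <- sum(tp)
  pk <- colSums(cm); tk <- rowSums(cm)
  den <- sqrt((s^2 - sum(pk^2)) * (s^2 - sum(tk^2)))
  mcc <- if (den == 0) 0 else (c_ * s - sum(pk * tk)) / den
  list(accuracy = 100 * sum(tp) / n,
       precision = 100 * mean(prec[support]),
       recall = 100 * mean(rec[support]),
       specificity = 100 * mean(spec[support]),
       f1 = 100 * mean(f1[support]),
       mcc = 100 * mcc,
       confusion = cm)
}

#' Evaluate a fitted classifier on a test part
#'
#' @param fit A fit from [train_and_tune()]`$fit`.
#' @param test_x,test_y Test features and labels.
#' @return A [classification_metrics()] report.
#' @export
evaluate_classifier <- function(fit, test_x, test_y) {
  lev <- fit$levels
  pred <- predict(fit, test_x)
  truth <- factor(as.character(test_y), levels = lev)
  if (anyNA(truth)) stop("test labels outside the training classes")
  classification_metrics(table(actual = truth, predicted = pred))
}

#' Incremental last-week activity-level prediction
#'
#' Splits a participant's `n` labeled days into the first `n - 7` days for
#' initial training and the final week for testing: for each of the last 7
#' days the model is retrained on all preceding days, the day's level is
#' predicted from `(sedentary, lpa, mpa, vpa, steps)`, and the true label is
#' appended before moving on (incremental learning).  A single-class history
#' short-circuits to that class.
#'
#' @param labeled_days Data frame with feature columns `sedentary`, `lpa`,
#'   `mpa`, `vpa`, `steps` (or the `*_min` daily-summary names) and a label
#'   column `activity_level` or `label`; at least 14 rows.
#' @param config A [classifier_config()] (default gradient boosting with
#'   the standard grid point).
#' @return List with `predicted_levels`, `predicted_scores`,
#'   `actual_levels`, `actual_scores`, `agreement` (0-7), and
#'   `score_difference` = sum(actual) - sum(predicted).
#' @export
incremental_weekly_predict <- function(labeled_days,
                                       config = classifier_config("gradient_boosting")) {
  df <- labeled_days
  ren <- c(sedentary_min = "sedentary", lpa_min = "lpa", mpa_min = "mpa",
           vpa_min = "vpa")
  for (old in names(ren))
    if (old %in% names(df) && !(ren[[old]] %in% names(df)))
      names(df)[names(df) == old] <- ren[[old]]
  lab_col <- intersect(c("activity_level", "label"), names(df))[1]
  if (is.na(lab_col)) stop("no label column (`activity_level` or `label`)")
  n <- nrow(df)
  if (n < 14) stop("need at least 14 days of history")
  x <- as.matrix(df[, .FEATURES])
  y <- df[[lab_col]]
  lev <- sort(unique(as.character(y)))
  preds <- integer(7)
  for (i in seq_len(7)) {
    day <- n - 7 + i
    hist_y <- factor(as.character(y[1:(day - 1)]), levels = lev)
    if (nlevels(droplevels(hist_y)) == 1) {
      preds[i] <- as.integer(as.character(droplevels(hist_y)[1]))
    } else {
      fit <- .fit_model(config$model, x[1:(day - 1), , drop = FALSE], hist_y,
                        config$grid, seed = config$seed)
      preds[i] <- as.integer(as.character(predict(fit, x[day, , drop = FALSE])[1]))
    }
  }
  actual <- as.integer(y[(n - 6):n])
  list(predicted_levels = preds, predicted_scores = preds,
       actual_levels = actual, actual_scores = actual,
       agreement = sum(preds == actual),
       score_difference = sum(actual) - sum(preds))
}
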