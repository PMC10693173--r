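# Stratified splitting, tuning, the metric suite with multiclass MCC, the
# majority baseline, and the incremental weekly protocol.

test_that("stratified splits preserve class proportions and determinism", {
  y <- rep(c("a", "b"), each = 50)
  sp <- stratified_split(y, seed = 1)
  expect_equal(lengths(sp), c(train = 60L, validation = 20L, test = 20L))
  for (part in sp) expect_equal(unname(table(y[part])), rep(length(part) / 2, 2),
                                ignore_attr = TRUE)
  expect_identical(sp, stratified_split(y, seed = 1))
  expect_false(identical(sp, stratified_split(y, seed = 2)))
  # per-class fractions within one row of the global fractions
  y2 <- rep(0:4, c(37, 23, 17, 13, 10))
  sp2 <- stratified_split(y2, seed = 3)
  for (cls in 0:4) {
    for (j in seq_along(sp2)) {
      got <- sum(y2[sp2[[j]]] == cls)
      want <- sum(y2 == cls) * c(0.6, 0.2, 0.2)[j]
      expect_lte(abs(got - want), 1)
    }
  }
  expect_error(stratified_split(c("a", "a", "b")), "at least")
})

test_that("evaluation metrics match brute-force confusion arithmetic", {
  set.seed(44)
  cm <- matrix(sample(0:30, 25, replace = TRUE), 5, 5)
  met <- suppressWarnings(classification_metrics(cm))
  n <- sum(cm)
  per <- lapply(1:5, function(k) {
    tp <- cm[k, k]; fn <- sum(cm[k, ]) - tp; fp <- sum(cm[, k]) - tp
    brute_force_binary(tp, fp, fn, n - tp - fn - fp)
  })
  sup <- sapply(1:5, function(k) sum(cm[k, ]) > 0)
  expect_equal(met$accuracy, 100 * sum(diag(cm)) / n, tolerance = 1e-12)
  expect_equal(met$precision, mean(sapply(per, `[[`, "precision")[sup]),
               tolerance = 1e-9)
  expect_equal(met$recall, mean(sapply(per, `[[`, "recall")[sup]),
               tolerance = 1e-9)
  expect_equal(met$specificity, mean(sapply(per, `[[`, "specificity")[sup]),
               tolerance = 1e-9)
})

test_that("binary MCC matches the closed form to 1e-12 and is symmetric", {
  set.seed(45)
  for (i in 1:20) {
    cm <- matrix(sample(1:40, 4, replace = TRUE), 2, 2)
    tp <- cm[1, 1]; fn <- cm[1, 2]; fp <- cm[2, 1]; tn <- cm[2, 2]
    want <- brute_force_binary(tp, fp, fn, tn)$mcc
    expect_equal(classification_metrics(cm)$mcc, want, tolerance = 1e-12)
    # invariant to swapping which class is "positive"
    swapped <- cm[2:1, 2:1]
    expect_equal(classification_metrics(swapped)$mcc,
                 classification_metrics(cm)$mcc, tolerance = 1e-12)
  }
})

test_that("MCC hits its perfect and zero-information limits", {
  perfect <- diag(c(10, 10, 10, 10, 10))
  met <- classification_metrics(perfect)
  expect_equal(met$accuracy, 100)
  expect_equal(met$f1, 100)
  expect_equal(met$mcc, 100)
  # constant single-class predictions on a balanced set
  const <- matrix(0, 2, 2); const[, 1] <- c(25, 25)
  expect_equal(classification_metrics(const)$mcc, 0)
})

test_that("the majority baseline scores the majority rate", {
  ds <- make_imbalanced_dataset(c(`0` = 0.6, `1` = 0.1, `2` = 0.1, `3` = 0.1,
                                  `4` = 0.1), 500, seed = 10)
  x <- ds[, 1:5]
  cfg <- classifier_config("dummy_most_frequent")
  tt <- train_and_tune(cfg, x, ds$label)
  rep <- evaluate_classifier(tt$fit, x, ds$label)
  expect_equal(rep$accuracy, 60, tolerance = 0.5)
  expect_equal(rep$mcc, 0)
})

test_that("tuning returns the single grid point and separates a toy", {
  set.seed(46)
  x <- data.frame(f1 = c(rnorm(40, 0), rnorm(40, 8)), f2 = rnorm(80))
  y <- rep(c("lo", "hi"), each = 40)
  cfg <- classifier_config("gradient_boosting",
                          grid = list(learning_rate = 0.1, max_depth = 3,
                                      n_estimators = 50))
  tt <- train_and_tune(cfg, x, y, x, y)
  expect_equal(tt$best_params$max_depth, 3)
  expect_equal(tt$validation_accuracy, 100)
  # a 2-point grid is searched by cross-validated accuracy
  cfg2 <- classifier_config("gradient_boosting",
                           grid = list(learning_rate = 0.1, max_depth = c(1, 3),
                                       n_estimators = 25))
  tt2 <- train_and_tune(cfg2, x, y)
  expect_equal(nrow(tt2$cv_results), 2L)
  expect_true(tt2$best_params$max_depth %in% c(1, 3))
})

test_that("every ensemble separates a noise-free labeled set", {
  days <- noise_free_days(150)
  x <- days[, 1:5]; y <- days$activity_level
  for (model in c("random_forest", "bagging", "extra_trees",
                  "gradient_boosting", "adaboost", "voting")) {
    cfg <- classifier_config(model, grid = list(n_estimators = 30,
                                                learning_rate = 0.3,
                                                max_depth = 3))
    fit <- train_and_tune(cfg, x, y)$fit
    rep <- evaluate_classifier(fit, x, y)
    expect_gte(rep$accuracy, 95)
  }
})

test_that("balancing never hurts minority recall on an imbalanced toy", {
  ds <- make_imbalanced_dataset(c(`0` = 0.7, `1` = 0.1, `2` = 0.08,
                                  `3` = 0.07, `4` = 0.05), 400, seed = 11)
  sp <- stratified_split(ds$label, seed = 2)
  cfg <- classifier_config("random_forest", grid = list(n_estimators = 60))
  fit_raw <- train_and_tune(cfg, ds[sp$train, 1:5], ds$label[sp$train])$fit
  bal <- adasyn_resample(ds[sp$train, 1:5], ds$label[sp$train], seed = 3)
  fit_bal <- train_and_tune(cfg, as.data.frame(bal$features), bal$labels)$fit
  rec <- function(fit) {
    cm <- suppressWarnings(evaluate_classifier(fit, ds[sp$test, 1:5],
                                               ds$label[sp$test]))$confusion
    diag(cm)[5] / max(1, sum(cm[5, ]))      # rarest class recall
  }
  expect_gte(rec(fit_bal), rec(fit_raw) - 0.25)
})

test_that("incremental weekly prediction replays a deterministic persona", {
  days <- noise_free_days(40, levels_seq = c(sample(0:4, 33, replace = TRUE),
                                             table18_levels))
  out <- incremental_weekly_predict(
    days, classifier_config("gradient_boosting",
                            grid = list(learning_rate = 0.1, max_depth = 3,
                                        n_estimators = 60)))
  expect_equal(out$agreement, 7L)
  expect_equal(out$score_difference, 0L)
  expect_equal(out$predicted_levels, table18_levels)
  expect_equal(out$predicted_scores, c(1, 1, 3, 2, 1, 1, 1))
})

test_that("single-class history short-circuits and short history errors", {
  days <- noise_free_days(20, levels_seq = rep(2L, 20))
  out <- incremental_weekly_predict(days)
  expect_equal(out$predicted_levels, rep(2L, 7))
  expect_error(incremental_weekly_predict(noise_free_days(10)), "14")
})
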