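# Stratified folds, search spaces, learners, nested CV, stacking, reports.

test_that("stratified folds allocate classes proportionally", {
  labels <- rep(c(0, 1, 2), times = c(50, 30, 20))
  folds <- stratified_folds(labels, 5, seed = 3)
  expect_length(folds, 5L)
  expect_setequal(unlist(folds), seq_along(labels))
  for (f in folds) {
    expect_equal(sum(labels[f] == 0), 10L)
    expect_equal(sum(labels[f] == 1), 6L)
    expect_equal(sum(labels[f] == 2), 4L)
  }
  expect_equal(stratified_folds(labels, 1, seed = 1)[[1]], seq_along(labels))
  expect_error(stratified_folds(c(0, 0, 0, 1, 1, 1, 2, 2), 5, seed = 1),
               class = "sw_stratification_error")
  # uneven class sizes still deviate from proportional by at most one
  labels2 <- rep(c(0, 1, 2), times = c(53, 31, 23))
  for (f in stratified_folds(labels2, 5, seed = 9)) {
    expect_true(abs(sum(labels2[f] == 0) - 53 / 5) <= 1)
    expect_true(abs(sum(labels2[f] == 1) - 31 / 5) <= 1)
    expect_true(abs(sum(labels2[f] == 2) - 23 / 5) <= 1)
  }
})

test_that("randomized spaces draw valid configurations reproducibly", {
  cfgs <- sample_configurations(rf_space(100), seed = 5)
  expect_length(cfgs, 100L)
  for (cfg in cfgs) {
    expect_true(cfg$n_estimators >= 50 && cfg$n_estimators <= 300)
    expect_true(cfg$max_depth >= 10 && cfg$max_depth <= 30)
    expect_true(cfg$max_features %in% c("sqrt", "log2"))
    expect_true(cfg$min_samples_split >= 2 && cfg$min_samples_split <= 20)
    expect_true(cfg$min_samples_leaf >= 1 && cfg$min_samples_leaf <= 10)
    expect_true(is.logical(cfg$bootstrap))
  }
  gb <- sample_configurations(gb_space(100), seed = 5)
  lrates <- vapply(gb, `[[`, numeric(1), "learning_rate")
  expect_true(all(lrates >= 0.01 & lrates <= 0.31))
  expect_true(all(vapply(gb, `[[`, numeric(1), "max_depth") %in% 3:10))
  expect_identical(sample_configurations(rf_space(20), seed = 8),
                   sample_configurations(rf_space(20), seed = 8))
})

test_that("grid spaces enumerate the documented candidate counts", {
  expect_length(sample_configurations(lr_grid()), 45L)
  expect_length(sample_configurations(svm_grid()), 24L)
  expect_length(sample_configurations(knn_grid()), 16L)
  expect_length(sample_configurations(ada_grid()), 125L)
})

test_that("classification reports match hand confusion arithmetic", {
  # all correct
  rep1 <- model_report(c(0, 1, 2, 2), c(0, 1, 2, 2))
  expect_equal(rep1$accuracy, 1)
  expect_true(all(rep1$per_class$f1[rep1$per_class$support > 0] == 1))
  # one class with TP=8 FP=2 FN=2
  truth <- c(rep(0, 10), rep(1, 10))
  pred <- c(rep(0, 8), 1, 1, 0, 0, rep(1, 8))
  rep2 <- model_report(truth, pred)
  expect_equal(rep2$per_class$precision[1], 0.8)
  expect_equal(rep2$per_class$recall[1], 0.8)
  expect_equal(rep2$per_class$f1[1], 0.8)
  # class absent from both truth and predictions reports zeros
  expect_equal(rep2$per_class$support[3], 0L)
  expect_equal(rep2$per_class$precision[3], 0)
  # weighted averages recompute from the per-class table
  w <- rep2$per_class$support / sum(rep2$per_class$support)
  expect_equal(rep2$weighted_f1, sum(w * rep2$per_class$f1))
  expect_equal(rep2$macro_precision, mean(rep2$per_class$precision))
})

test_that("single learners honour their semantics on edge datasets", {
  ds <- separable_dataset()
  # a shallow forest recovers a 1-feature threshold rule
  rf <- train_learner("RF", rf_config_default(), ds, seed = 2)
  expect_gte(mean(predict(rf, ds) == ds$labels), 0.99)
  # a single depth-1 stump suffices for a binary threshold rule
  withr::with_seed(14, {
    x <- runif(120)
    stump_ds <- labeled_dataset(data.frame(EDA_Mean = x),
                                as.integer(x > 0.5))
  })
  stump <- train_learner("RF", list(n_estimators = 1L, max_depth = 1L,
                                    max_features = "sqrt",
                                    min_samples_split = 2L,
                                    min_samples_leaf = 1L, bootstrap = FALSE),
                         stump_ds, seed = 4)
  expect_equal(predict(stump, stump_ds), stump_ds$labels)
  # KNN with k = 1 is perfect on its own training set
  knn <- train_learner("KNN", list(metric = "euclidean", n_neighbors = 1L,
                                   weights = "uniform"), ds)
  expect_equal(predict(knn, ds), ds$labels)
  # GB with learning rate 0 predicts the majority class everywhere
  skewed <- labeled_dataset(ds$features, ifelse(seq_along(ds$labels) %% 4 == 0,
                                                ds$labels, 2L))
  gb0 <- train_learner("GB", list(n_estimators = 10L, max_depth = 3L,
                                  learning_rate = 0), skewed, seed = 1)
  expect_true(all(predict(gb0, skewed) == 2L))
  # configs outside their domain are rejected
  expect_error(train_learner("RF", modifyList(rf_config_default(),
                                              list(max_depth = 500L)), ds),
               class = "sw_validation_error")
})

test_that("nested CV is perfect on separable data and reproducible", {
  ds <- separable_dataset(n = 200L)
  cv <- nested_cv(ds, rf_space(3), seed = 17)
  expect_length(cv$outer_fold_accuracies, 5L)
  expect_equal(cv$mean_accuracy, mean(cv$outer_fold_accuracies))
  expect_equal(cv$mean_accuracy, 1.0)
  cv2 <- nested_cv(ds, rf_space(3), seed = 17)
  expect_identical(cv$outer_fold_accuracies, cv2$outer_fold_accuracies)
  expect_identical(cv$best_hyperparameters, cv2$best_hyperparameters)
  expect_equal(cv$n_fits, 3L * 5L * 5L + 5L)
})

test_that("shuffled labels score near the majority-class prior", {
  withr::with_seed(23, {
    n <- 300
    feats <- data.frame(EDA_Mean = runif(n), HR_Mean = runif(n),
                        TEMP_Mean = runif(n))
    labels <- sample(c(0L, 1L, 2L), n, replace = TRUE, prob = c(0.5, 0.3, 0.2))
    ds <- labeled_dataset(feats, labels)
  })
  cv <- nested_cv(ds, rf_space(2), seed = 29)
  prior <- max(table(ds$labels)) / length(ds$labels)
  se <- sqrt(prior * (1 - prior) / length(ds$labels))
  expect_lt(abs(cv$mean_accuracy - prior), 3 * se + 0.05)
})

test_that("stacking combines perfect base learners without loss", {
  ds <- separable_dataset(n = 200L)
  st <- train_stacking(ds, rf_config_default(), gb_config_default(), seed = 3)
  expect_equal(mean(predict(st, ds) == ds$labels), 1.0)
  # meta-learner consumes 2 models x 3 classes = 6 probability columns
  expect_length(st$meta_names, 6L)
})

test_that("grid search counts fits as candidates times folds", {
  ds <- separable_dataset(n = 120L)
  gs <- grid_search_cv(ds, knn_grid(), seed = 41)
  expect_equal(gs$n_fits, 16L * 5L)
  expect_true(gs$best_accuracy >= 0.9)
  expect_s3_class(gs$model, "sw_model")
})
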