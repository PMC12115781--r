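# MDI importance, correlations, level statistics, summaries, validation.

test_that("MDI concentrates on the only splittable feature", {
  # class is a function of EDA_Mean alone; the other columns are constant
  # and can never be chosen for a split
  withr::with_seed(4, {
    x <- runif(300)
    feats <- data.frame(EDA_Mean = x, HR_Mean = 1, TEMP_Mean = 2)
    ds <- labeled_dataset(feats, as.integer(x > 0.5))
  })
  m <- train_learner("RF", rf_config_default(), ds, seed = 6)
  imp <- mdi_importance(m)
  expect_equal(sum(imp$importance), 1, tolerance = 1e-9)
  expect_equal(imp$importance[imp$feature == "EDA_Mean"], 1, tolerance = 1e-12)
})

test_that("per-node MDI recomputation matches ranger's impurity importance", {
  fx <- small_cohort_fixture()
  ds <- subsample_stratified(fx$dataset, 400, seed = 2)
  cfg <- rf_config_default()
  m <- train_learner("RF", cfg, ds, seed = 44)
  imp <- mdi_importance(m)
  expect_equal(sum(imp$importance), 1, tolerance = 1e-9)
  expect_true(all(imp$importance >= 0))
  ref <- ranger::ranger(
    x = stresswear:::ld_matrix(ds), y = factor(ds$labels),
    num.trees = cfg$n_estimators, mtry = floor(sqrt(ncol(stresswear:::ld_matrix(ds)))),
    max.depth = cfg$max_depth, min.node.size = cfg$min_samples_split,
    min.bucket = cfg$min_samples_leaf, replace = TRUE, sample.fraction = 1,
    probability = TRUE, keep.inbag = TRUE, importance = "impurity",
    num.threads = 1L, seed = 44)
  v <- ref$variable.importance / sum(ref$variable.importance)
  expect_equal(imp$importance[match(names(v), imp$feature)], unname(v),
               tolerance = 1e-9)
})

test_that("GB importance sums to one and rejects non-tree models", {
  ds <- separable_dataset(n = 200L)
  gb <- train_learner("GB", gb_config_default(), ds, seed = 2)
  imp <- mdi_importance(gb)
  expect_equal(sum(imp$importance), 1, tolerance = 1e-9)
  expect_equal(imp$feature[1], "EDA_Mean")
  knn <- train_learner("KNN", list(metric = "euclidean", n_neighbors = 3L,
                                   weights = "uniform"), ds)
  expect_error(mdi_importance(knn), class = "sw_unsupported_model_error")
})

test_that("correlation matrix is symmetric with unit diagonal", {
  withr::with_seed(8, {
    x <- rnorm(50)
    tab <- data.frame(EDA_Mean = x, HR_Mean = -x, TEMP_Mean = rnorm(50),
                      EDA_Std = 1)
  })
  expect_warning(cm <- feature_correlations(tab), "EDA_Std")
  expect_equal(diag(cm), c(EDA_Mean = 1, HR_Mean = 1, TEMP_Mean = 1))
  expect_equal(cm, t(cm))
  expect_equal(cm["EDA_Mean", "HR_Mean"], -1)
})

test_that("level comparisons report Welch t in the level-minus-baseline direction", {
  withr::with_seed(12, {
    base <- data.frame(HR_Mean = rnorm(60, 80, 1), TEMP_Mean = rnorm(60, 31, .1),
                       EDA_Mean = rnorm(60, 1, .1))
    up <- base + 10
    feats <- rbind(base, up, up)
    labels <- rep(c(0L, 1L, 2L), each = 60)
  })
  lt <- level_comparison_tests(feats, labels)
  expect_true(all(lt$tests$t > 20))          # +10 shift, tiny variance
  expect_true(all(lt$tests$significant))
  expect_equal(unname(lt$means["HR_Mean", "level0"]), mean(base$HR_Mean))
  # identical groups: t = 0, p = 1
  same <- rbind(base, base, base)
  lt0 <- level_comparison_tests(same, rep(c(0L, 1L, 2L), each = 60))
  hr_row <- lt0$tests[lt0$tests$metric == "HR_Mean" &
                        grepl("Level 1", lt0$tests$comparison), ]
  expect_equal(hr_row$t, 0)
  expect_equal(hr_row$p, 1)
  # degenerate group
  expect_error(level_comparison_tests(feats[c(1, 61), ], c(0L, 1L)),
               class = "sw_degenerate_group_error")
  # subject-paired variant runs and keeps the sign
  withr::with_seed(15, {
    shift1 <- 8 + rnorm(60); shift2 <- 12 + rnorm(60)
    feats_p <- rbind(base, base + shift1, base + shift2)
  })
  subj <- rep(rep(c("a", "b", "c"), each = 20), 3)
  ltp <- level_comparison_tests(feats_p, labels, paired = TRUE,
                                subject_id = subj)
  expect_true(all(ltp$tests$t > 0))
})

test_that("time-in-level fractions form a probability vector with a strict flag", {
  out <- time_in_levels(c(0, 0, 1, 2), rep("a", 4))
  expect_equal(unlist(out[1, c("f0", "f1", "f2")], use.names = FALSE),
               c(0.5, 0.25, 0.25))
  expect_false(out$flag_high_stress[1])      # exactly 0.25 is not > 0.25
  out2 <- time_in_levels(rep(2, 5), rep("b", 5))
  expect_equal(out2$f2, 1)
  expect_true(out2$flag_high_stress)
  # cohort-wide conservation
  fx <- small_cohort_fixture()
  summ <- time_in_levels(fx$dataset$labels, fx$dataset$subject_id)
  expect_equal(summ$f0 + summ$f1 + summ$f2, rep(1, nrow(summ)))
  # success crosstab appears when flags are supplied
  succ <- stats::setNames(rep(c(TRUE, FALSE), length.out = nrow(summ)),
                          summ$subject)
  summ2 <- time_in_levels(fx$dataset$labels, fx$dataset$subject_id, succ)
  expect_false(is.null(attr(summ2, "crosstab")))
})

test_that("segment validation passes elevated emergencies and fails calm ones", {
  lab <- c(2, 2, 2, 0, 0)
  seg <- c(4, 4, 4, 1, 1)
  out <- segment_validation(lab, seg, rep("a", 5))
  expect_true(out$pass)
  out2 <- segment_validation(c(0, 0, 0, 1), c(4, 4, 4, 1), rep("a", 4))
  expect_false(out2$pass)
  expect_error(segment_validation(c(0, 1), c(1, 2), rep("a", 2)),
               class = "sw_coverage_error")
})
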