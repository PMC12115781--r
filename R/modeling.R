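# Model selection and evaluation: stratified folds, randomized/grid
# hyperparameter search, nested 5-fold cross-validation, stacking, and
# classification reports.
#
# Protocol: hyperparameters of the two base ensembles are searched with a
# randomized strategy (100 candidate draws by default) inside a nested
# stratified 5-fold scheme -- the inner level picks hyperparameters on each
# outer-training part, the outer level measures generalization. Accuracy is
# the selection criterion. Min-max scaling is fit inside each training
# split and applied to the corresponding held-out part, never pooled.

#' Hyperparameter search spaces
#'
#' `rf_space()` and `gb_space()` are randomized spaces (integer ranges
#' sampled uniformly inclusive of both endpoints, the GB learning rate
#' uniform on `[0.01, 0.31]`). The remaining learners use exhaustive grids
#' with 45 (LR), 24 (SVM), 16 (KNN) and 125 (ADA) candidates.
#'
#' @param n_iterations Number of randomized-search draws (default 100).
#' @return A `search_space` object.
#' @export
rf_space <- function(n_iterations = 100L) {
  new_space("RF", "randomized", n_iterations, list(
    n_estimators = c(50L, 300L), max_depth = c(10L, 30L),
    max_features = c("sqrt", "log2"), min_samples_split = c(2L, 20L),
    min_samples_leaf = c(1L, 10L), bootstrap = c(TRUE, FALSE)
  ))
}

#' @rdname rf_space
#' @export
gb_space <- function(n_iterations = 100L) {
  new_space("GB", "randomized", n_iterations, list(
    n_estimators = c(50L, 300L), max_depth = c(3L, 10L),
    learning_rate = c(0.01, 0.31)
  ))
}

#' @rdname rf_space
#' @export
lr_grid <- function() {
  new_space("LR", "grid", NULL, list(
    C = c(0.001, 0.01, 0.1, 1, 10), alpha = c(0, 0.5, 1),
    max_iter = c(100L, 500L, 1000L)
  ))
}

#' @rdname rf_space
#' @export
svm_grid <- function() {
  new_space("SVM", "grid", NULL, list(
    C = c(0.1, 1, 10, 100), gamma = c("scale", "auto", "0.01"),
    kernel = c("radial", "linear")
  ))
}

#' @rdname rf_space
#' @export
knn_grid <- function() {
  new_space("KNN", "grid", NULL, list(
    metric = c("manhattan", "euclidean"), n_neighbors = c(3L, 5L, 7L, 9L),
    weights = c("uniform", "distance")
  ))
}

#' @rdname rf_space
#' @export
ada_grid <- function() {
  new_space("ADA", "grid", NULL, list(
    max_depth = c(1L, 3L, 5L, 7L, 9L),
    learning_rate = c(0.01, 0.05, 0.1, 0.5, 1.0),
    n_estimators = c(50L, 100L, 200L, 300L, 400L)
  ))
}

new_space <- function(learner, type, n_iterations, domains) {
  structure(list(learner = learner, type = type,
                 n_iterations = n_iterations, domains = domains),
            class = "search_space")
}

# Continuous (runif) vs integer-range vs finite-set domains. Randomized
# spaces treat length-2 numeric vectors as ranges; grids treat every domain
# as a finite set.
CONTINUOUS_PARAMS <- "learning_rate"

#' Draw hyperparameter configurations from a search space
#'
#' Randomized spaces yield exactly `n_iterations` configurations (integer
#' ranges uniform inclusive, continuous ranges uniform real, finite sets
#' uniform); grid spaces yield the full cross-product. Reproducible under
#' `seed`.
#'
#' @param space A `search_space`.
#' @param seed Integer seed.
#' @return List of named configuration lists.
#' @export
sample_configurations <- function(space, seed = 1L) {
  stopifnot(inherits(space, "search_space"))
  if (space$type == "grid") {
    g <- expand.grid(space$domains, stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
    return(lapply(seq_len(nrow(g)), function(i) as.list(g[i, , drop = FALSE])))
  }
  with_rng(seed, {
    lapply(seq_len(space$n_iterations), function(i) {
      cfg <- lapply(names(space$domains), function(nm) {
        dom <- space$domains[[nm]]
        if (nm %in% CONTINUOUS_PARAMS && space$learner == "GB")
          stats::runif(1, dom[1L], dom[2L])
        else if (is.integer(dom) && length(dom) == 2L)
          sample(seq.int(dom[1L], dom[2L]), 1L)
        else
          dom[[sample.int(length(dom), 1L)]]
      })
      names(cfg) <- names(space$domains)
      cfg
    })
  })
}

# Feasibility of a configuration for its learner. Deliberately wider than
# the default search domains: degenerate settings (a single stump, one
# neighbour, a zero learning rate) are legal learner parameterizations even
# though no search would draw them.
validate_config <- function(kind, config) {
  rules <- switch(kind,
    RF = list(n_estimators = c(1, Inf), max_depth = c(1, 100),
              max_features = c("sqrt", "log2"), min_samples_split = c(2, Inf),
              min_samples_leaf = c(1, Inf), bootstrap = c(TRUE, FALSE)),
    GB = list(n_estimators = c(1, Inf), max_depth = c(1, 100),
              learning_rate = c(0, Inf)),
    LR = list(C = c(1e-12, Inf), alpha = c(0, 1), max_iter = c(1, Inf)),
    SVM = list(C = c(1e-12, Inf), gamma = NULL,
               kernel = c("radial", "linear")),
    KNN = list(metric = c("manhattan", "euclidean"), n_neighbors = c(1, Inf),
               weights = c("uniform", "distance")),
    ADA = list(max_depth = c(1, 30), learning_rate = c(0, Inf),
               n_estimators = c(1, Inf))
  )
  for (nm in names(rules)) {
    v <- config[[nm]]
    if (is.null(v))
      sw_abort(sprintf("%s config lacks parameter %s", kind, nm), "sw_validation_error")
    dom <- rules[[nm]]
    if (is.null(dom)) next                    # free-form (validated at fit)
    ok <- if (is.character(dom)) as.character(v) %in% dom
          else if (is.logical(dom)) is.logical(v)
          else is.numeric(v) && v >= dom[1L] && v <= dom[2L]
    if (!ok)
      sw_abort(sprintf("%s parameter %s = %s outside its domain", kind, nm,
                       format(v)), "sw_validation_error")
  }
  invisible(TRUE)
}

#' Stratified k-fold assignment
#'
#' Partitions indices into k folds whose per-class counts differ from
#' proportional allocation by at most one.
#'
#' @param labels Class vector.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return List of k disjoint index vectors covering all indices.
#' @export
stratified_folds <- function(labels, k, seed = 1L) {
  k <- as.integer(k)
  tab <- table(labels)
  if (any(tab < k))
    sw_abort(sprintf("class %s has %d member(s), fewer than k = %d folds",
                     names(tab)[which.min(tab)], min(tab), k),
             "sw_stratification_error")
  folds <- vector("list", k)
  with_rng(seed, {
    for (cl in names(tab)) {
      idx <- sample(which(as.character(labels) == cl))
      n_c <- length(idx)
      base <- n_c %/% k
      sizes <- rep(base, k)
      extra <- n_c %% k
      if (extra > 0L) sizes[sample.int(k, extra)] <- base + 1L
      at <- cumsum(c(0L, sizes))
      for (f in seq_len(k))
        folds[[f]] <- c(folds[[f]], idx[(at[f] + 1L):at[f + 1L]])
    }
  })
  lapply(folds, sort)
}

# One stratified train/test split (fraction held out).
stratified_split <- function(labels, test_fraction = 0.2, seed = 1L) {
  test <- integer(0)
  with_rng(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      n_test <- max(1L, round(length(idx) * test_fraction))
      test <- c(test, sample(idx, n_test))
    }
  })
  list(train = setdiff(seq_along(labels), test), test = sort(test))
}

# Accuracy of configuration `config` for `kind` under k-fold CV on `ds`,
# scaling inside each training fold. Returns mean fold accuracy.
cv_accuracy <- function(kind, config, ds, folds, seed) {
  accs <- vapply(seq_along(folds), function(f) {
    tr <- ld_subset(ds, setdiff(seq_along(ds$labels), folds[[f]]))
    te <- ld_subset(ds, folds[[f]])
    params <- minmax_fit(tr$features)
    tr$features <- minmax_apply(tr$features, params)
    te$features <- minmax_apply(te$features, params)
    m <- train_learner(kind, config, tr, seed = derive_seed(seed, f))
    mean(predict(m, te) == te$labels)
  }, numeric(1))
  mean(accs)
}

#' Nested stratified 5-fold cross-validation with hyperparameter search
#'
#' For each outer fold, an inner 5-fold cross-validation over the candidate
#' configurations (drawn once from `space`) selects the best hyperparameters
#' on the outer-training part; the winner is refit on the outer-training
#' part and scored on the outer-test part. Scaling is fit inside every
#' training split.
#'
#' @param dataset A `labeled_dataset` (unscaled features).
#' @param space A `search_space`.
#' @param seed Integer master seed.
#' @param outer_k,inner_k Fold counts (default 5 and 5).
#' @return A `cv_result`: outer fold accuracies, their mean, the inner
#'   best-candidate accuracies per fold, chosen hyperparameters per fold,
#'   and the number of model fits performed.
#' @export
nested_cv <- function(dataset, space, seed = 1L, outer_k = 5L, inner_k = 5L) {
  candidates <- sample_configurations(space, seed = derive_seed(seed, 101L))
  outer <- stratified_folds(dataset$labels, outer_k, seed = derive_seed(seed, 1L))
  outer_acc <- numeric(outer_k)
  inner_best <- numeric(outer_k)
  best_cfgs <- vector("list", outer_k)
  n_fits <- 0L
  for (f in seq_len(outer_k)) {
    tr_idx <- setdiff(seq_along(dataset$labels), outer[[f]])
    tr <- ld_subset(dataset, tr_idx)
    te <- ld_subset(dataset, outer[[f]])
    inner_folds <- stratified_folds(tr$labels, inner_k,
                                    seed = derive_seed(seed, 2L, f))
    scores <- vapply(seq_along(candidates), function(ci) {
      cv_accuracy(space$learner, candidates[[ci]], tr, inner_folds,
                  seed = derive_seed(seed, 3L, f, ci))
    }, numeric(1))
    n_fits <- n_fits + length(candidates) * inner_k
    best <- which.max(scores)
    inner_best[f] <- scores[best]
    best_cfgs[[f]] <- candidates[[best]]
    params <- minmax_fit(tr$features)
    tr_s <- tr; tr_s$features <- minmax_apply(tr$features, params)
    te_s <- te; te_s$features <- minmax_apply(te$features, params)
    m <- train_learner(space$learner, candidates[[best]], tr_s,
                       seed = derive_seed(seed, 4L, f))
    n_fits <- n_fits + 1L
    outer_acc[f] <- mean(predict(m, te_s) == te_s$labels)
  }
  structure(list(learner = space$learner,
                 outer_fold_accuracies = outer_acc,
                 mean_accuracy = mean(outer_acc),
                 inner_best_accuracies = inner_best,
                 best_hyperparameters = best_cfgs,
                 n_fits = n_fits, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result:%s> outer accuracies %s; mean %.4f (%d fits)\n",
              x$learner, paste(sprintf("%.3f", x$outer_fold_accuracies),
                               collapse = " "),
              x$mean_accuracy, x$n_fits))
  invisible(x)
}

# Configuration with the best inner-CV score across the outer folds.
best_configuration <- function(cv) {
  cv$best_hyperparameters[[which.max(cv$inner_best_accuracies)]]
}

#' Flat grid search with stratified k-fold cross-validation
#'
#' Scores every candidate of `space` by k-fold CV accuracy (k model fits per
#' candidate) and refits the winner on all of `dataset`.
#'
#' @param dataset A `labeled_dataset` (unscaled features).
#' @param space A `search_space` (typically a grid).
#' @param seed Integer seed.
#' @param k Folds (default 5).
#' @return List with `best_config`, `best_accuracy`, fitted `model`
#'   (trained on all rows, scaled with the full-data scaler), the per-
#'   candidate `scores`, `scaler` parameters, and `n_fits` (candidates x k).
#' @export
grid_search_cv <- function(dataset, space, seed = 1L, k = 5L) {
  candidates <- sample_configurations(space, seed = derive_seed(seed, 201L))
  folds <- stratified_folds(dataset$labels, k, seed = derive_seed(seed, 5L))
  scores <- vapply(seq_along(candidates), function(ci) {
    cv_accuracy(space$learner, candidates[[ci]], dataset, folds,
                seed = derive_seed(seed, 6L, ci))
  }, numeric(1))
  best <- which.max(scores)
  params <- minmax_fit(dataset$features)
  ds_s <- dataset; ds_s$features <- minmax_apply(dataset$features, params)
  model <- train_learner(space$learner, candidates[[best]], ds_s,
                         seed = derive_seed(seed, 7L))
  list(best_config = candidates[[best]], best_accuracy = scores[best],
       model = model, scores = scores, scaler = params,
       n_fits = length(candidates) * k)
}

#' Train a stacking classifier over RF and GB
#'
#' The two base ensembles produce out-of-fold class-probability features via
#' internal stratified 5-fold CV on the training set; a multinomial logistic
#' meta-learner is fit on those features. Prediction applies the meta-
#' learner to the refit base models' probabilities.
#'
#' @param train A `labeled_dataset` (features already scaled).
#' @param rf_config,gb_config Base-learner hyperparameters.
#' @param seed Integer seed.
#' @param k Internal folds for out-of-fold probabilities (default 5).
#' @return A fitted `sw_stacking` model.
#' @export
train_stacking <- function(train, rf_config, gb_config, seed = 1L, k = 5L) {
  folds <- stratified_folds(train$labels, k, seed = derive_seed(seed, 11L))
  classes <- sort(unique(train$labels))
  K <- length(classes)
  meta <- matrix(NA_real_, length(train$labels), 2L * K)
  for (f in seq_along(folds)) {
    tr <- ld_subset(train, setdiff(seq_along(train$labels), folds[[f]]))
    te <- ld_subset(train, folds[[f]])
    rf <- train_learner("RF", rf_config, tr, seed = derive_seed(seed, 12L, f))
    gb <- train_learner("GB", gb_config, tr, seed = derive_seed(seed, 13L, f))
    meta[folds[[f]], seq_len(K)] <- align_proba(predict_proba(rf, te), classes)
    meta[folds[[f]], K + seq_len(K)] <- align_proba(predict_proba(gb, te), classes)
  }
  colnames(meta) <- c(paste0("rf_p", classes), paste0("gb_p", classes))
  mdf <- as.data.frame(meta)
  mdf$.y <- factor(train$labels, levels = classes)
  meta_fit <- nnet::multinom(.y ~ ., data = mdf, trace = FALSE, maxit = 500)
  rf_full <- train_learner("RF", rf_config, train, seed = derive_seed(seed, 14L))
  gb_full <- train_learner("GB", gb_config, train, seed = derive_seed(seed, 15L))
  structure(list(kind = "STACK", rf = rf_full, gb = gb_full,
                 meta = meta_fit, classes = classes,
                 meta_names = colnames(meta),
                 feature_names = rf_full$feature_names, seed = seed),
            class = c("sw_stacking", "sw_model"))
}

align_proba <- function(P, classes) {
  out <- matrix(0, nrow(P), length(classes),
                dimnames = list(NULL, as.character(classes)))
  out[, colnames(P)] <- P
  out
}

#' @export
predict.sw_stacking <- function(object, newdata, ...) {
  meta <- cbind(align_proba(predict_proba(object$rf, newdata), object$classes),
                align_proba(predict_proba(object$gb, newdata), object$classes))
  colnames(meta) <- object$meta_names
  pred <- stats::predict(object$meta, newdata = as.data.frame(meta))
  as.integer(as.character(pred))
}

#' Classification report for a fitted model
#'
#' Per-class precision, recall, F1 and support over classes `{0, 1, 2}`
#' (zero when a denominator is zero), plus accuracy, macro (unweighted) and
#' weighted (support-weighted) averages.
#'
#' @param model A fitted `sw_model`.
#' @param test A non-empty `labeled_dataset` (features on the model's scale).
#' @return A `model_report`.
#' @export
evaluate <- function(model, test) {
  if (length(test$labels) == 0L)
    sw_abort("test set is empty", "sw_validation_error")
  pred <- predict(model, test)
  model_report(test$labels, pred)
}

#' Build a classification report from truth and predictions
#'
#' @param truth,pred Integer class vectors in `{0, 1, 2}`.
#' @param classes Classes to report on (default 0:2).
#' @return A `model_report`: `per_class` data frame, `accuracy`, `macro_*`
#'   and `weighted_*` averages.
#' @export
model_report <- function(truth, pred, classes = 0:2) {
  per <- data.frame(class = classes, precision = 0, recall = 0, f1 = 0,
                    support = 0L)
  for (i in seq_along(classes)) {
    cl <- classes[i]
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    per$support[i] <- tp + fn
    per$precision[i] <- if (tp + fp > 0) tp / (tp + fp) else 0
    per$recall[i] <- if (tp + fn > 0) tp / (tp + fn) else 0
    per$f1[i] <- if (per$precision[i] + per$recall[i] > 0)
      2 * per$precision[i] * per$recall[i] / (per$precision[i] + per$recall[i])
    else 0
  }
  wts <- per$support / max(sum(per$support), 1L)
  structure(list(
    per_class = per,
    accuracy = mean(pred == truth),
    macro_precision = mean(per$precision), macro_recall = mean(per$recall),
    macro_f1 = mean(per$f1),
    weighted_precision = sum(wts * per$precision),
    weighted_recall = sum(wts * per$recall),
    weighted_f1 = sum(wts * per$f1),
    n = length(truth)
  ), class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  cat("Classification report\n")
  df <- x$per_class
  df[2:4] <- lapply(df[2:4], function(v) sprintf("%.4f", v))
  print(df, row.names = FALSE)
  cat(sprintf("accuracy %.4f on %d rows\n", x$accuracy, x$n))
  cat(sprintf("macro    P/R/F1 = %.4f/%.4f/%.4f\n",
              x$macro_precision, x$macro_recall, x$macro_f1))
  cat(sprintf("weighted P/R/F1 = %.4f/%.4f/%.4f\n",
              x$weighted_precision, x$weighted_recall, x$weighted_f1))
  invisible(x)
}
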